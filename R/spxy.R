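#' SPXY train/prediction partitioning
#'
#' Sample-set partitioning based on joint X-Y distances: pairwise
#' Euclidean distances are computed separately in predictor space
#' (`X`) and response space (`y`), each normalized by its maximum, and
#' summed; the greedy max-min rule then selects the training set. The
#' first two selected samples are the pair at maximum joint distance;
#' each subsequent sample maximizes its minimum joint distance to the
#' already-selected set. Ties break to the lowest index.
#'
#' Categorical labels are one-hot encoded before computing the
#' response distance, since species labels are nominal.
#'
#' @param X numeric matrix, samples x variables (or a
#'   [spectrum_set()], in which case its labels are used when `y` is
#'   missing).
#' @param y numeric vector/matrix of responses, or a character/factor
#'   label vector (one-hot encoded internally).
#' @param n_train number of training samples, `2 <= n_train < m`.
#' @return An object of class `spxy_split`: list with
#'   `train_indices` (in selection order), `prediction_indices`, and
#'   `selection_order` (same as `train_indices`, kept explicit for
#'   standard-set prefixes).
#' @export
spxy_split <- function(X, y = NULL, n_train) {
  if (inherits(X, "spectrum_set")) {
    if (is.null(y)) y <- X$labels
    X <- X$spectra
  }
  X <- as.matrix(X)
  m <- nrow(X)
  stopifnot(n_train >= 2, n_train < m)
  Y <- encode_response(y, m)
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(Y))
  mx <- max(dx); my <- max(dy)
  if (mx == 0) {
    warning("all X rows identical; joint distance driven by y only")
    mx <- 1
  }
  if (my == 0) my <- 1   # single-class or constant response
  d <- dx / mx + dy / my
  sel <- integer(n_train)
  # seed pair: maximum joint distance over distinct pairs, lowest
  # indices on ties
  dd <- d
  diag(dd) <- -Inf
  best <- which(dd == max(dd), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  sel[1:2] <- sort(best[1L, ])
  if (max(dd) == 0) warning("duplicate rows: maximum joint distance is 0")
  remaining <- setdiff(seq_len(m), sel[1:2])
  if (n_train > 2) {
    for (t in 3:n_train) {
      mind <- apply(d[remaining, sel[seq_len(t - 1L)], drop = FALSE], 1L, min)
      pick <- remaining[which.max(mind)]   # which.max: first (lowest index) tie
      sel[t] <- pick
      remaining <- setdiff(remaining, pick)
    }
  }
  structure(
    list(train_indices = sel,
         prediction_indices = sort(remaining),
         selection_order = sel),
    class = "spxy_split")
}

encode_response <- function(y, m) {
  if (is.null(y)) stop("a response (labels or numeric y) is required for SPXY")
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    lev <- sort(unique(y))
    Y <- outer(y, lev, "==") * 1
  } else {
    Y <- as.matrix(y)
  }
  if (nrow(Y) != m) stop("response length must match sample count")
  Y
}

#' @export
print.spxy_split <- function(x, ...) {
  cat("<spxy_split>", length(x$train_indices), "train /",
      length(x$prediction_indices), "prediction samples\n")
  invisible(x)
}

#' Select transfer standard samples
#'
#' Returns the first `k` training samples in SPXY selection order: the
#' most jointly spread-out subset of the training set, used as the
#' standard set measured on both instruments. The result is nested —
#' the selection for `k` is a prefix of the selection for `k + 1` — so
#' standard-set size can be grown without remeasuring.
#'
#' @param split an [spxy_split()] result.
#' @param k number of standard samples, `1 <= k <= |train|`.
#' @return Integer vector of `k` sample indices (into the original
#'   data), a subset of `split$train_indices`.
#' @export
select_standard_samples <- function(split, k) {
  stopifnot(inherits(split, "spxy_split"))
  if (k < 1 || k > length(split$selection_order)) {
    stop("k must be between 1 and the training-set size")
  }
  split$selection_order[seq_len(k)]
}
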