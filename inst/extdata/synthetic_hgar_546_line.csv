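"wavelength_nm","intensity"
536,0.12
536.1,0.12
536.2,0.12
536.3,0.12
536.4,0.12
536.5,0.12
536.6,0.12
536.7,0.12
536.8,0.12
536.9,0.12
537,0.12
537.1,0.12
537.2,0.12
537.3,0.12
537.4,0.12
537.5,0.12
537.6,0.12
537.7,0.12
537.8,0.12
537.9,0.12
538,0.12
538.1,0.12
538.2,0.12
538.3,0.12
538.4,0.120001
538.5,0.120001
538.6,0.120001
538.7,0.120002
538.8,0.120002
538.9,0.120003
539,0.120004
539.1,0.120006
539.2,0.120008
539.3,0.120011
539.4,0.120016
539.5,0.120021
539.6,0.120028
539.7,0.120038
539.8,0.120051
539.9,0.120069
540,0.120091
540.1,0.12012
540.2,0.120159
540.3,0.120208
540.4,0.120272
540.5,0.120353
540.6,0.120458
540.7,0.12059
540.8,0.120758
540.9,0.120969
541,0.121233
541.1,0.121563
541.2,0.121973
541.3,0.122479
541.4,0.123102
541.5,0.123866
541.6,0.124797
541.7,0.125926
541.8,0.12729
541.9,0.128931
542,0.130893
542.1,0.13323
542.2,0.136
542.3,0.139267
542.4,0.143103
542.5,0.147585
542.6,0.152795
542.7,0.158823
542.8,0.165763
542.9,0.173714
543,0.182777
543.1,0.193057
543.2,0.204658
543.3,0.217683
543.4,0.232231
543.5,0.248397
543.6,0.266265
543.7,0.285909
543.8,0.307389
543.9,0.330748
544,0.356008
544.1,0.38317
544.2,0.412206
544.3,0.443063
544.4,0.475656
544.5,0.509869
544.6,0.54555
544.7,0.582517
544.8,0.620553
544.9,0.659408
545,0.6988
545.1,0.738422
545.2,0.777939
545.3,0.816998
545.4,0.855228
545.5,0.892249
545.6,0.927677
545.7,0.961129
545.8,0.992232
545.9,1.02063
546,1.045988
546.1,1.068002
546.2,1.086402
546.3,1.10096
546.4,1.111493
546.5,1.117866
546.6,1.12
546.7,1.117866
546.8,1.111493
546.9,1.10096
547,1.086402
547.1,1.068002
547.2,1.045988
547.3,1.02063
547.4,0.992232
547.5,0.961129
547.6,0.927677
547.7,0.892249
547.8,0.855228
547.9,0.816998
548,0.777939
548.1,0.738422
548.2,0.6988
548.3,0.659408
548.4,0.620553
548.5,0.582517
548.6,0.54555
548.7,0.509869
548.8,0.475656
548.9,0.443063
549,0.412206
549.1,0.38317
549.2,0.356008
549.3,0.330748
549.4,0.307389
549.5,0.285909
549.6,0.266265
549.7,0.248397
549.8,0.232231
549.9,0.217683
550,0.204658
550.1,0.193057
550.2,0.182777
550.3,0.173714
550.4,0.165763
550.5,0.158823
550.6,0.152795
550.7,0.147585
550.8,0.143103
550.9,0.139267
551,0.136
551.1,0.13323
551.2,0.130893
551.3,0.128931
551.4,0.12729
551.5,0.125926
551.6,0.124797
551.7,0.123866
551.8,0.123102
551.9,0.122479
552,0.121973
552.1,0.121563
552.2,0.121233
552.3,0.120969
552.4,0.120758
552.5,0.12059
552.6,0.120458
552.7,0.120353
552.8,0.120272
552.9,0.120208
553,0.120159
553.1,0.12012
553.2,0.120091
553.3,0.120069
553.4,0.120051
553.5,0.120038
553.6,0.120028
553.7,0.120021
553.8,0.120016
553.9,0.120011
554,0.120008
554.1,0.120006
554.2,0.120004
554.3,0.120003
554.4,0.120002
554.5,0.120002
554.6,0.120001
554.7,0.120001
554.8,0.120001
554.9,0.12
555,0.12
555.1,0.12
555.2,0.12
555.3,0.12
555.4,0.12
555.5,0.12
555.6,0.12
555.7,0.12
555.8,0.12
555.9,0.12
556,0.12
556.1,0.12
556.2,0.12
556.3,0.12
556.4,0.12
556.5,0.12
556.6,0.12
556.7,0.12
556.8,0.12
556.9,0.12
557,0.12
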