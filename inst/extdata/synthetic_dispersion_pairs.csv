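"pixel","wavelength_nm"
4,795.38588
24,791.36171
44,787.3316
64,783.29553
84,779.2535
104,775.20553
124,771.1516
144,767.09172
164,763.02589
184,758.95411
204,754.87638
224,750.79269
244,746.70305
264,742.60746
284,738.50592
304,734.39842
324,730.28498
344,726.16558
364,722.04023
384,717.90893
404,713.77167
424,709.62847
444,705.47931
464,701.3242
484,697.16314
504,692.99612
524,688.82315
544,684.64424
564,680.45937
584,676.26854
604,672.07177
624,667.86904
644,663.66036
664,659.44573
684,655.22515
704,650.99862
724,646.76613
744,642.52769
764,638.2833
784,634.03296
804,629.77666
824,625.51442
844,621.24622
864,616.97207
884,612.69197
904,608.40591
924,604.11391
944,599.81595
954,597.98271
974,593.69199
994,589.39856
1014,585.10242
1034,580.80356
1054,576.50199
1074,572.19772
1094,567.89073
1114,563.58102
1134,559.26861
1154,554.95348
1174,550.63564
1194,546.31509
1214,541.99183
1234,537.66586
1254,533.33717
1274,529.00577
1294,524.67166
1314,520.33484
1334,515.99531
1354,511.65306
1374,507.3081
1394,502.96043
1414,498.61005
1434,494.25695
1454,489.90115
1474,485.54263
1494,481.1814
1514,476.81746
1534,472.4508
1554,468.08143
1574,463.70936
1594,459.33457
1614,454.95706
1634,450.57685
1654,446.19392
1674,441.80828
1694,437.41993
1714,433.02887
1734,428.6351
1754,424.23861
1774,419.83941
1794,415.4375
1814,411.03288
1834,406.62555
1854,402.2155
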