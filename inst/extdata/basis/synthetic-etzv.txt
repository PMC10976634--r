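# Synthetic even-tempered triple-zeta-quality basis, generated by generate_et_basis(); atomically contracted; NOT a published basis set.
Mg
S
0.02500000 0.0006155170
0.06750000 -0.0020591962
0.18225000 0.0043384686
0.49207500 -0.0076268026
1.32860250 0.0151036530
3.58722675 -0.0012976080
9.68551223 0.4511317602
26.15088301 1.0000000000
70.60738412 0.6717262712
190.63993712 0.2688316750
514.72783024 0.0887639572
1389.76514164 0.0269136947
3752.36588242 0.0077331392
10131.38788255 0.0024850086
27354.74728288 0.0004701443
73857.81766377 0.0003445827
S
0.02500000 -0.0019448089
0.06750000 0.0070183397
0.18225000 -0.0164337972
0.49207500 0.2753238923
1.32860250 1.0000000000
3.58722675 0.5540598643
9.68551223 -0.1981188241
26.15088301 -0.2968435650
70.60738412 -0.1440263332
190.63993712 -0.0520329791
514.72783024 -0.0162227027
1389.76514164 -0.0049024671
3752.36588242 -0.0013778456
10131.38788255 -0.0004492493
27354.74728288 -0.0000831150
73857.81766377 -0.0000619128
S
0.02500000 0.2588043524
0.06750000 1.0000000000
0.18225000 0.4091127611
0.49207500 -0.2552555881
1.32860250 -0.2913610156
3.58722675 -0.1112862242
9.68551223 0.0360417939
26.15088301 0.0539238528
70.60738412 0.0252681743
190.63993712 0.0091479520
514.72783024 0.0028150731
1389.76514164 0.0008591103
3752.36588242 0.0002383252
10131.38788255 0.0000787565
27354.74728288 0.0000143195
73857.81766377 0.0000108103
S
0.02500000 1.0000000000
S
0.06750000 1.0000000000
S
0.18225000 1.0000000000
P
0.05000000 0.0015512054
0.13500000 0.0010872428
0.36450000 0.1696607810
0.98415000 0.8165797575
2.65720500 1.0000000000
7.17445350 0.5968971028
19.37102445 0.2084874041
52.30176602 0.0510077461
141.21476824 0.0109827324
381.27987425 0.0018710891
1029.45566047 0.0004886555
P
0.05000000 1.0000000000
P
0.13500000 1.0000000000
P
0.36450000 1.0000000000
P
0.98415000 1.0000000000
D
0.35000000 1.0000000000
D
0.11000000 1.0000000000
*
Cu
S
0.03200000 0.0000426796
0.08800000 -0.0001415048
0.24200000 0.0002944198
0.66550000 -0.0005160226
1.83012500 0.0006498535
5.03284375 -0.0006356067
13.84032031 -0.0009420752
38.06088086 0.1656961121
104.66742236 0.9987110569
287.83541150 1.0000000000
791.54738162 0.4426623598
2176.75529946 0.1521952813
5986.07707352 0.0438745818
16461.71195218 0.0141943325
45269.70786849 0.0026791371
124491.69663834 0.0018513378
S
0.03200000 -0.0003675145
0.08800000 0.0012521415
0.24200000 -0.0027965185
0.66550000 0.0065846860
1.83012500 -0.0107508520
5.03284375 0.2490931498
13.84032031 1.0000000000
38.06088086 0.1994525026
104.66742236 -0.3400941928
287.83541150 -0.2061388591
791.54738162 -0.0783014354
2176.75529946 -0.0241323829
5986.07707352 -0.0070491432
16461.71195218 -0.0021632368
45269.70786849 -0.0004290506
124491.69663834 -0.0002842247
S
0.03200000 0.0007220347
0.08800000 -0.0015554997
0.24200000 0.0037801349
0.66550000 0.2707086342
1.83012500 1.0000000000
5.03284375 -0.0034170227
13.84032031 -0.6734611389
38.06088086 -0.0758611284
104.66742236 0.1210431465
287.83541150 0.0715569092
791.54738162 0.0258830268
2176.75529946 0.0080953992
5986.07707352 0.0022973601
16461.71195218 0.0007236503
45269.70786849 0.0001386988
124491.69663834 0.0000942789
S
0.03200000 0.5982358651
0.08800000 1.0000000000
0.24200000 0.1398991378
0.66550000 -0.2584568383
1.83012500 -0.3624081149
5.03284375 -0.0035629777
13.84032031 0.1772084561
38.06088086 0.0189248656
104.66742236 -0.0296575258
287.83541150 -0.0174103151
791.54738162 -0.0062766772
2176.75529946 -0.0019618199
5986.07707352 -0.0005562840
16461.71195218 -0.0001752783
45269.70786849 -0.0000335744
124491.69663834 -0.0000228311
S
0.03200000 1.0000000000
S
0.08800000 1.0000000000
S
0.24200000 1.0000000000
P
0.06500000 -0.0014058632
0.17550000 0.0042898991
0.47385000 -0.0083186331
1.27939500 0.0168421606
3.45436650 0.0138208675
9.32678955 0.5861966524
25.18233179 1.0000000000
67.99229582 0.5129562348
183.57919871 0.1489703257
495.66383652 0.0299114816
1338.29235862 0.0081300206
P
0.06500000 0.0007692352
0.17550000 0.0053773275
0.47385000 0.1682240649
1.27939500 0.8987469423
3.45436650 1.0000000000
9.32678955 -0.0471238460
25.18233179 -0.4176116019
67.99229582 -0.1921548797
183.57919871 -0.0545272814
495.66383652 -0.0103642267
1338.29235862 -0.0028855120
P
0.06500000 1.0000000000
P
0.17550000 1.0000000000
D
0.09500000 0.0898642008
0.28500000 0.4476373219
0.85500000 0.8412585260
2.56500000 1.0000000000
7.69500000 0.6204079075
23.08500000 0.1747407502
69.25500000 0.0280275332
207.76500000 0.0035538293
D
0.09500000 1.0000000000
D
0.28500000 1.0000000000
D
0.85500000 1.0000000000
F
1.50000000 1.0000000000
*
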