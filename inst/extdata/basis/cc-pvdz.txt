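# cc-pVDZ correlation-consistent basis (H, C), spherical functions.
H
S
13.0100000 0.0196850
1.96200000 0.1379770
0.44460000 0.4781480
0.12200000 0.5012400
S
0.12200000 1.0000000
P
0.72700000 1.0000000
*
C
S
6665.00000 0.0006920
1000.00000 0.0053290
228.000000 0.0270770
64.7100000 0.1017180
21.0600000 0.2747400
6.45900000 0.4485640
2.06600000 0.2850740
0.58290000 0.0152040
0.18340000 -0.0031910
S
6665.00000 -0.0001460
1000.00000 -0.0011540
228.000000 -0.0057250
64.7100000 -0.0233120
21.0600000 -0.0639550
6.45900000 -0.1499810
2.06600000 -0.1272620
0.58290000 0.5445290
0.18340000 0.5804960
S
0.18340000 1.0000000
P
9.43900000 0.0381090
2.00200000 0.2094800
0.54560000 0.5085570
P
0.15170000 1.0000000
D
0.55000000 1.0000000
*
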