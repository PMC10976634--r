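# STO-3G minimal basis. Each element block: symbol, then shell blocks
# ("S", "P", "D", "SP") with lines "exponent coeff [coeff_p]", ending with "*".
H
S
3.42525091 0.15432897
0.62391373 0.53532814
0.16885540 0.44463454
*
He
S
6.36242139 0.15432897
1.15892300 0.53532814
0.31364979 0.44463454
*
C
S
71.6168370 0.15432897
13.0450960 0.53532814
3.53051220 0.44463454
SP
2.94124940 -0.09996723 0.15591627
0.68348310 0.39951283 0.60768372
0.22228990 0.70011547 0.39195739
*
N
S
99.1061690 0.15432897
18.0523120 0.53532814
4.88566020 0.44463454
SP
3.78045590 -0.09996723 0.15591627
0.87849660 0.39951283 0.60768372
0.28571440 0.70011547 0.39195739
*
O
S
130.7093200 0.15432897
23.8088610 0.53532814
6.44360830 0.44463454
SP
5.03315130 -0.09996723 0.15591627
1.16959610 0.39951283 0.60768372
0.38038900 0.70011547 0.39195739
*
Mg
S
299.2374000 0.15432897
54.5064700 0.53532814
14.7515800 0.44463454
SP
15.1218200 -0.09996723 0.15591627
3.51398700 0.39951283 0.60768372
1.14285700 0.70011547 0.39195739
SP
1.39544800 -0.21962037 0.01058760
0.38932600 0.22559543 0.59516701
0.15238000 0.90039843 0.46200101
*
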