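n_generics,relative_price
0,1.00
1,0.61
2,0.48
3,0.40
4,0.36
5,0.33
6,0.31
8,0.28
10,0.26
15,0.22
20,0.20
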