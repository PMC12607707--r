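index,position_mm
1,500
2,1650
3,2800
4,3950
5,5100
6,6250
7,7400
8,8550
9,9700
10,10850
11,12000
12,13150
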