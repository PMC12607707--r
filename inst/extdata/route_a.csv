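x,y,tier,bypass
5,1,lower,FALSE
12,3,upper,FALSE
20,5,lower,FALSE
28,7,upper,TRUE
36,9,lower,FALSE
44,11,upper,FALSE
52,9,lower,FALSE
60,7,upper,FALSE
68,5,lower,TRUE
76,3,upper,FALSE
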