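index,position_mm
1,500
2,1230
3,1960
4,2690
5,3420
6,4150
7,4880
8,5610
9,6340
10,7070
11,7800
12,8530
13,9260
14,9990
15,10720
16,11450
17,12180
18,12910
19,13640
20,14370
21,15100
22,15830
23,16560
24,17290
25,18020
26,18750
27,19480
28,20210
29,20940
30,21670
31,22400
32,23130
33,23860
34,24590
35,25320
36,26050
37,26780
38,27510
39,28240
40,28970
41,29700
42,30430
43,31160
44,31890
45,32620
46,33350
47,34080
48,34810
49,35540
50,36270
51,37000
52,37730
53,38460
54,39190
55,39920
56,40650
57,41380
58,42110
59,42840
60,43570
61,44300
62,45030
63,45760
64,46490
65,47220
66,47950
67,48680
68,49410
69,50140
70,50870
71,51600
72,52330
73,53060
74,53790
75,54520
76,55250
77,55980
78,56710
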