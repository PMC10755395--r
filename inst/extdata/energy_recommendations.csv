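age_min,age_max,female_kcal,male_kcal
0,1,650,720
2,3,1132,1263
4,6,1380,1520
7,10,1700,1880
11,14,1900,2200
15,17,2000,2500
18,59,1928,2532
60,74,1850,2300
75,120,1750,2100
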