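time_s,intensity
0,5054.84
60,4846.28
120,4756.55
180,4644.66
240,4516.86
300,4381.68
360,4335.38
420,4163.77
480,4144.45
540,3960.76
600,3918.32
660,3863.63
720,3625.73
780,3582.23
840,3503.02
900,3451.56
960,3335.21
1020,3163.4
1080,3097.63
1140,3176.08
1200,3041.4
1260,2915.09
1320,2914.34
1380,2906.82
1440,2873.12
1500,2721.17
1560,2671.11
1620,2555.75
1680,2591.37
1740,2495.8
1800,2489.74
1860,2451.47
1920,2418.02
1980,2307.13
2040,2308.03
2100,2176.93
2160,2173.4
2220,2131.24
2280,2030.51
2340,2091.57
2400,2062.63
2460,2005.38
2520,2016.71
2580,1924.98
2640,1868.04
2700,1909.83
2760,1830.8
2820,1892.72
2880,1790.33
2940,1807.34
3000,1768.38
3060,1699.38
3120,1769.81
3180,1709.32
3240,1664.79
3300,1650.58
3360,1645.72
3420,1601.87
3480,1458.94
3540,1571.09
3600,1526.65
3660,1531
3720,1529.7
3780,1545.82
3840,1444.68
3900,1510.34
3960,1456.65
4020,1470.22
4080,1451.46
4140,1429.87
4200,1346.16
4260,1371.56
4320,1387.81
4380,1312.83
4440,1317.76
4500,1351.58
4560,1348.3
4620,1325.72
4680,1261.66
4740,1243.36
4800,1338.44
4860,1279.14
4920,1263.55
4980,1246.65
5040,1195.47
5100,1259.75
5160,1218.87
5220,1212.78
5280,1250.21
5340,1238.77
5400,1254.83
5460,1173.57
5520,1212.32
5580,1235.84
5640,1129.86
5700,1134.14
5760,1117.78
5820,1099.33
5880,1155.73
5940,1173.66
6000,1190.73
6060,1179.81
6120,1093.36
6180,1203.06
6240,1098.21
6300,1125.01
6360,1099.94
6420,1108.11
6480,1116.82
6540,1110.48
6600,1101.24
6660,1103.22
6720,1076.23
6780,1072.35
6840,1023.04
6900,1071.26
6960,1063.21
7020,1189.04
7080,1023.83
7140,1081.24
7200,1013.52
7260,1012.04
7320,1073.53
7380,1026.43
7440,1064.04
7500,1044.89
7560,1035.44
7620,977.03
7680,1007.12
7740,1061.45
7800,1075.2
7860,1031.06
7920,1049.11
7980,1092.41
8040,1103.54
8100,1000.55
8160,1038.29
8220,1089.63
8280,1021.42
8340,1036.79
8400,1034.17
8460,1000.87
8520,1017.4
8580,1032.86
8640,1016.36
8700,1076.38
8760,1011.56
8820,1012.46
8880,1056.68
8940,985.61
9000,1025.32
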