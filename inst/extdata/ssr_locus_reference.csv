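locus,na,ne,i,ho,he,nei,pic
BLF41,2,1.3478,0.4265,0.0145,0.2590,0.2580,0.3116
BLF4,2,1.1912,0.2979,0.0000,0.1612,0.1605,0.3367
BLF47,2,1.2800,0.3768,0.0000,0.2199,0.2188,0.4619
BLF8,2,1.3081,0.3983,0.0000,0.2373,0.2355,0.4476
BLF9,2,1.1133,0.2095,0.0000,0.1023,0.1017,0.4077
BLF51,2,1.0606,0.1327,0.0000,0.0573,0.0571,0.1771
BLF52,2,1.4764,0.5035,0.0000,0.3245,0.3227,0.5118
BLF58,2,1.0533,0.1205,0.0000,0.0509,0.0506,0.3945
BLF59,2,1.1492,0.2530,0.0000,0.1303,0.1298,0.2898
BLF61,2,1.1995,0.3061,0.0000,0.1669,0.1663,0.2071
BLF21,2,1.0267,0.0701,0.0263,0.0261,0.0260,0.3046
BLF66,2,1.1730,0.2791,0.1603,0.1480,0.1475,0.2882
BLF27,2,1.7676,0.6259,0.0000,0.4366,0.4342,0.5613
BLF79,2,1.9625,0.6836,0.7340,0.4931,0.4904,0.5874
BLF80,2,1.1150,0.2117,0.0000,0.1041,0.1031,0.3843
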