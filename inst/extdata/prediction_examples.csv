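actual_A1,actual_A4,actual_B4,actual_C4,actual_D4,expected_A1,expected_A4,expected_B4,expected_C4,expected_D4
0.1605,0.0566,0.0262,0.0412,0.0576,0.24,0.08,0.08,0,0
0.0009,0.1468,0.1755,0.0317,0.044,0,0,0,0.4,0
0.0045,0.1113,0.0952,0.024,0.0419,0.16,0.08,0,0.16,0
0.3388,0.1398,0.0169,0.051,0.0468,0.16,0.08,0,0,0.16
0.0208,0.125,0.3111,0.2054,0.1481,0.08,0,0,0.08,0.24
0.2196,0.0578,0.0212,0.0427,0.0545,0.24,0,0.08,0,0.08
0.0014,0.1297,0.1619,0.026,0.0443,0.08,0.24,0,0.08,0
0.0067,0.0875,0.058,0.0116,0.0523,0.08,0.16,0.16,0,0
0.0345,0.0798,0.0281,0.0139,0.0425,0,0,0,0.08,0.32
0.0008,0.1492,0.1702,0.0285,0.0462,0,0,0.08,0.32,0
0.0227,0.0912,0.0413,0.0231,0.0424,0.16,0.16,0,0,0.08
0.0077,0.1009,0.074,0.0213,0.0421,0,0,0.16,0,0.24
0.0022,0.1204,0.094,0.0174,0.0465,0,0.24,0,0,0.16
0.0017,0.1287,0.1474,0.0258,0.0438,0,0.32,0,0.08,0
0.1147,0.0658,0.0167,0.0162,0.0393,0.32,0,0.08,0,0
0.0028,0.1242,0.1194,0.0321,0.0417,0,0,0,0.32,0.08
0.0922,0.0716,0.0166,0.0124,0.0395,0.08,0,0.24,0,0.08
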