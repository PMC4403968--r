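scanner,field_strength,metric,mean,sd
A,1.5,ADC,1.1103,0.0214
B,1.5,ADC,1.1116,0.0218
C,3,ADC,1.1064,0.1070
D,1.5,ADC,1.0971,0.0173
E,3,ADC,1.1106,0.0191
F,3,ADC,1.1525,0.0991
G,1.5,ADC,1.1092,0.0914
H,3,ADC,1.1223,0.0325
A,1.5,D,1.1041,0.0275
B,1.5,D,1.1148,0.0258
C,3,D,1.1010,0.0274
D,1.5,D,1.1060,0.0211
E,3,D,1.1218,0.0169
F,3,D,1.2059,0.0930
G,1.5,D,1.1428,0.1147
H,3,D,1.1346,0.0316
A,1.5,f,0.0114,0.0097
B,1.5,f,0.0115,0.0102
C,3,f,0.0181,0.0137
D,1.5,f,0.0081,0.0087
E,3,f,0.0120,0.0141
F,3,f,0.0229,0.0189
G,1.5,f,0.0591,0.0451
H,3,f,0.0110,0.0096
A,1.5,MD,1.1030,0.0177
C,3,MD,1.0966,0.0271
D,1.5,MD,1.0921,0.0176
E,3,MD,1.1191,0.0315
F,3,MD,1.1884,0.0344
G,1.5,MD,1.0989,0.0240
H,3,MD,1.1116,0.0206
A,1.5,FA,0.0226,0.0177
C,3,FA,0.0392,0.0149
D,1.5,FA,0.0240,0.0177
E,3,FA,0.0473,0.0234
F,3,FA,0.0488,0.0247
G,1.5,FA,0.0370,0.0145
H,3,FA,0.0405,0.0180
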