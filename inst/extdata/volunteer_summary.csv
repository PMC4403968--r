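metric,region,mean,sd_inter,sd_volunteer,sd_intra,cv_inter,cv_volunteer,cv_intra,icc_inter,icc_intra
ADC,GM,0.8327,0.0203,0.0246,0.0242,2.4,3.0,2.9,0.41,0.59
ADC,WM,0.7010,0.0210,0.0156,0.0072,3.0,2.2,1.0,0.90,0.10
ADC,cerebellar_cortex,0.8322,0.0914,0.0207,0.0290,11.0,2.5,3.5,0.77,0.23
ADC,cerebellar_wm,0.7244,0.0990,0.0137,0.0429,13.7,1.9,5.9,0.84,0.16
ADC,brain_stem,0.8710,0.1240,NA,0.0679,14.2,NA,7.8,0.91,0.09
ADC,cerebral_wm,0.7346,0.0590,0.0113,0.0190,8.0,1.5,2.6,0.92,0.08
ADC,basal_ganglia,0.7574,0.0590,0.0162,0.0293,10.6,2.1,3.9,0.87,0.13
ADC,thalamus,0.7894,0.0809,0.0200,0.0236,10.2,2.5,3.0,0.40,0.60
ADC,choroid_plexus,1.9049,0.5502,0.0920,0.2103,28.9,4.8,11.0,0.91,0.09
ADC,optic_chiasm,1.4399,0.3212,0.1618,0.3930,22.3,11.2,27.3,0.88,0.12
D,GM,0.7495,0.0207,0.0186,0.0159,2.8,2.5,2.1,0.63,0.37
D,WM,0.6506,0.0249,0.0115,0.0108,3.8,1.8,1.7,0.84,0.16
D,cerebellar_cortex,0.7283,0.0577,0.0139,0.0272,7.9,1.9,3.7,0.82,0.18
D,cerebellar_wm,0.6491,0.0501,0.0083,0.0381,7.7,1.3,5.9,0.63,0.37
D,brain_stem,0.6819,0.0665,NA,0.0505,9.8,NA,7.4,0.63,0.37
D,cerebral_wm,0.7035,0.0294,0.0098,0.0157,4.2,1.4,2.2,0.78,0.22
D,basal_ganglia,0.7184,0.0308,0.0145,0.0209,4.3,2.0,2.9,0.68,0.32
D,thalamus,0.7367,0.0040,0.0178,0.0213,5.4,2.4,2.9,0.78,0.22
D,choroid_plexus,1.8489,0.2281,0.1443,0.2077,12.3,7.8,11.2,0.55,0.45
D,optic_chiasm,0.9730,0.0755,0.0962,0.2815,7.8,9.9,28.9,0.07,0.93
f,GM,0.1005,0.0204,0.0026,0.0111,20.3,2.6,11.1,0.77,0.23
f,WM,0.0799,0.0234,0.0020,0.0047,29.2,2.6,5.8,0.96,0.04
f,cerebellar_cortex,0.1441,0.0244,0.0080,0.0121,16.9,5.6,8.4,0.80,0.20
f,cerebellar_wm,0.0966,0.0136,0.0046,0.0112,14.1,4.8,11.6,0.60,0.40
f,brain_stem,0.1771,0.0249,0.0159,0.0218,14.1,9.0,12.3,0.57,0.43
f,cerebral_wm,0.0832,0.0175,0.0035,0.0060,21.1,4.2,7.2,0.90,0.10
f,basal_ganglia,0.0765,0.0197,0.0056,0.0094,25.7,7.3,12.3,0.81,0.19
f,thalamus,0.1079,0.0316,0.0041,0.0115,29.3,3.8,10.7,0.88,0.12
f,choroid_plexus,0.2949,0.0349,0.0370,0.0546,11.8,12.6,18.5,0.29,0.71
f,optic_chiasm,0.4163,0.1124,0.0660,0.1316,27.0,15.8,31.6,0.42,0.58
MD,GM,0.8490,0.0212,0.0080,0.0202,2.5,0.9,2.4,0.52,0.48
MD,WM,0.6971,0.0111,0.0180,0.0094,1.6,2.6,1.3,0.59,0.41
MD,cerebellar_cortex,0.8506,0.0824,0.0212,0.0446,9.7,2.5,5.2,0.77,0.23
MD,cerebellar_wm,0.7209,0.0523,0.0100,0.0393,7.3,1.4,5.5,0.64,0.36
MD,brain_stem,0.9316,0.0773,0.0293,0.0791,8.3,3.1,8.5,0.49,0.51
MD,cerebral_wm,0.7851,0.0328,0.0142,0.0236,4.2,1.8,3.0,0.66,0.34
MD,basal_ganglia,0.8012,0.0199,0.0150,0.0292,2.5,1.9,3.6,0.32,0.68
MD,thalamus,0.8846,0.0618,0.0394,0.0871,7.0,4.5,9.9,0.33,0.67
MD,choroid_plexus,2.2421,0.3140,0.1241,0.2634,14.0,5.5,11.7,0.59,0.41
MD,optic_chiasm,1.5959,0.2154,0.2592,0.3011,13.5,16.2,18.9,0.34,0.66
FA,GM,0.1726,0.0047,0.0097,0.0128,2.7,5.6,7.4,0.12,0.88
FA,WM,0.4187,0.0083,0.0157,0.0088,2.0,3.8,2.1,0.47,0.53
FA,cerebellar_cortex,0.1991,0.0142,0.0077,0.0201,7.1,3.9,10.1,0.33,0.67
FA,cerebellar_wm,0.3872,0.0253,0.0204,0.0269,6.5,5.3,6.9,0.47,0.33
FA,brain_stem,0.4139,0.0224,0.0157,0.0243,5.4,3.8,5.9,0.46,0.54
FA,cerebral_wm,0.3275,0.0529,0.0102,0.0254,16.1,3.1,7.8,0.81,0.19
FA,basal_ganglia,0.2351,0.0373,0.0159,0.0247,15.8,6.8,10.5,0.69,0.31
FA,thalamus,0.2879,0.0090,0.0151,0.0220,3.1,5.2,7.6,0.14,0.86
FA,choroid_plexus,0.1592,0.0321,NA,0.0420,20.1,NA,26.4,0.37,0.63
FA,optic_chiasm,0.1781,0.0377,NA,0.0857,21.2,NA,48.1,0.16,0.84
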