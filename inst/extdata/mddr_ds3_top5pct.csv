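class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
9249,24.19,28.04,16.23,20.51,21.97,29.63,21.46
12455,10.21,12.55,11.87,8.03,9.26,8.51,9.39
12464,7.2,18.69,22.96,19.8,39.01,18.19,21.69
31281,25.62,27.52,23.9,33.24,40.19,34.95,27.71
43210,10.4,20.38,11.42,14.05,18.61,12.63,13.19
71522,14.1,9.17,12.86,8.5,12.02,13.89,10.92
75721,35.72,27.18,29.72,29.15,27.86,30.79,30.76
78331,14.38,12.25,9.61,9.26,13.75,10.17,9.43
78348,27.14,9.33,7.43,9.72,8.6,10.47,9.01
78351,12.93,16.61,15.03,10.58,12.89,16.7,16.16
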