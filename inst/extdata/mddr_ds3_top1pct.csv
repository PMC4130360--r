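class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
9249,14.64,16.00,10.11,11.71,11.45,15.44,13.6
12455,5.81,7.18,6.81,3.94,4.94,6.27,6.23
12464,3.17,9.40,11.13,9.31,19.62,8.65,11.61
31281,16.38,16.19,12.19,22.29,21.05,17.33,16.48
43210,9.58,9.16,4.6,5.84,10.06,6.98,7.04
71522,7.56,4.36,6.27,3.71,5.38,6.62,5.75
75721,26.91,19.54,22.09,17.8,19.39,22.24,22.33
78331,6.83,5.81,4.16,3.97,6.08,4.55,5.09
78348,12.73,4.70,3.58,4.24,3.27,4.29,3.69
78351,11.05,14.46,12.69,8.32,13.32,15.01,15.49
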