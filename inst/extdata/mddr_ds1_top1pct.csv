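class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
31420,60.93,53.69,26.13,22.06,28.65,34.75,41.8
71523,26.49,26.84,9.61,13.72,14.71,14.29,19.6
37110,20.84,15.52,12.38,9.26,17.99,18.8,18.74
31432,40.71,34.96,15.55,16.52,24.52,22.81,25.75
42731,16.86,16.20,9.63,6.05,8.18,10.08,12.27
6233,8.16,7.30,6.8,7.98,8.8,8.35,9.47
6245,5.75,5.47,4.11,3.66,4.94,5.61,7.21
7701,10.86,7.79,4.62,5.86,7.39,6.75,7.77
6235,7.83,7.43,4.27,6.22,6.91,6.55,8.29
78374,8.03,7.92,13.16,7.81,6.02,8.01,10.64
78331,6.09,5.98,5.13,4.11,6.33,4.94,5.72
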