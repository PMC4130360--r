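class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
31420,82.74,83.45,45.95,45.08,55.41,76.76,80.27
71523,52.92,57.04,19.73,33.38,29.97,33.31,37.92
37110,31.47,33.77,27.99,26.71,34.7,39.96,37.26
31432,74.24,66.27,33.73,39.37,48.29,41.01,51.46
42731,28.84,24.00,19.32,12.91,19.36,20.71,23.2
6233,18.28,14.94,17,20.47,24.07,20,19.92
6245,13.69,13.46,10.08,10.59,11.06,12.65,17.88
7701,24.61,19.92,11.62,13.6,22.34,17.69,18.86
6235,19.35,21.04,13.51,14.71,20.33,17.82,19.21
78374,15.8,13.05,18.1,14.71,11.73,12.59,15.11
78331,13.51,14.25,11.23,9.97,14.35,9.37,10.55
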