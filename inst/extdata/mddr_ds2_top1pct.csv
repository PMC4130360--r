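class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
7707,60.39,60.87,43.69,64.56,63.35,72.52,72.82
7708,68.65,82.90,78,91.03,71.03,97.94,100
31420,64.59,68.56,39.05,37.91,29.61,43.14,49.2
64100,74.27,79.09,46.36,79.27,86.45,86.64,83.55
64200,83.2,67.13,69.68,81.59,83.72,91.14,91.03
64220,49.04,39.02,47.86,47.41,53.48,66.16,82.68
64500,59.66,65.69,46.26,30.94,52.99,78.49,67.9
64300,76.48,30.64,22.72,34.64,52.88,87.36,85.68
65000,80.18,62.14,45.97,65.06,57.88,75.45,70.34
75755,93.72,93.61,86.26,85.62,66.94,92.38,96.45
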