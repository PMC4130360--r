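class,GBMD,SMILE,PCFP,ALOGP,MACCS,EPFP4,CDKFP
7707,71.12,71.41,71.6,75.49,78.2,77.96,75.39
7708,83.42,98.26,90.32,99.74,97.23,100,100
31420,90.5,93.05,55.58,61.15,55.9,81.73,88.81
64100,87.45,89.64,81.64,85.82,98.45,95.64,94.55
64200,96.53,88.24,89.6,95.36,97.87,99.93,99.63
64220,83.63,72.77,67.41,65.27,78.39,99.91,99.82
64500,76.84,93.51,78.89,59.66,85.77,99.84,97.41
64300,90.32,47.92,40.64,56.24,83.12,99.84,99.6
65000,96.12,71.01,71.91,85.5,81.34,86.59,85.43
75755,97.09,97.53,96.81,98.04,86.96,97.8,98.13
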