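dataset,record,tp,fp,fn,acc,se,ppv,f1
labour,r01,640,5,4,98.61,99.38,99.22,99.30
labour,r02,612,5,25,95.33,96.08,99.19,97.61
labour,r03,547,225,169,58.13,76.40,70.85,73.52
labour,r04,671,13,10,96.69,98.53,98.10,98.32
labour,r05,653,7,7,97.90,98.94,98.94,98.94
labour,r06,676,6,8,97.97,98.83,99.12,98.98
labour,r07,619,10,13,96.42,97.94,98.41,98.18
labour,r08,644,0,1,99.84,99.84,100.00,99.92
labour,r09,666,9,8,97.51,98.81,98.67,98.74
labour,r10,627,0,0,100.00,100.00,100.00,100.00
labour,r11,640,10,6,97.56,99.07,98.46,98.77
labour,r12,655,3,2,99.24,99.70,99.54,99.62
pregnancy,r01,3101,19,17,98.85,99.45,99.39,99.42
pregnancy,r02,2684,51,107,94.44,96.17,98.14,97.14
pregnancy,r03,2461,21,96,95.46,96.25,99.15,97.68
pregnancy,r04,2760,6,14,99.28,99.50,99.78,99.64
pregnancy,r05,2762,7,2,99.68,99.93,99.75,99.84
pregnancy,r06,2814,102,65,94.40,97.74,96.50,97.12
pregnancy,r07,2962,117,134,92.19,95.67,96.20,95.94
pregnancy,r08,2864,64,33,96.72,98.86,97.81,98.33
pregnancy,r09,2787,39,29,97.62,98.97,98.62,98.79
pregnancy,r10,2427,175,156,88.00,93.96,93.27,93.62
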