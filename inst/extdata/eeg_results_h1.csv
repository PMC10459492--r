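participant,model,horizon,vaf,rmse
1,LASSO,1,94.75,0.2225
2,LASSO,1,94.06,0.2667
3,LASSO,1,93.21,0.265
4,LASSO,1,86.7,0.3299
5,LASSO,1,93.12,0.2529
6,LASSO,1,94.59,0.2068
7,LASSO,1,95.25,0.2226
8,LASSO,1,91.01,0.2924
9,LASSO,1,92.48,0.2831
10,LASSO,1,95.83,0.2137
1,MLP,1,94.12,0.2392
2,MLP,1,93.58,0.2792
3,MLP,1,91.48,0.2975
4,MLP,1,84.59,0.3565
5,MLP,1,91.86,0.2767
6,MLP,1,93.91,0.2223
7,MLP,1,94.43,0.2672
8,MLP,1,88.51,0.3454
9,MLP,1,91.33,0.3071
10,MLP,1,95.09,0.2485
1,GP,1,88.52,0.3298
2,GP,1,85.74,0.4136
3,GP,1,88.4,0.3466
4,GP,1,79.72,0.4073
5,GP,1,89.39,0.3144
6,GP,1,88.89,0.2963
7,GP,1,91.38,0.3
8,GP,1,84.57,0.3836
9,GP,1,83.97,0.4144
10,GP,1,90.57,0.3216
1,SVR,1,90.96,0.2919
2,SVR,1,88.1,0.3781
3,SVR,1,90.86,0.3073
4,SVR,1,83.04,0.3724
5,SVR,1,91.86,0.2752
6,SVR,1,91.31,0.262
7,SVR,1,92.97,0.2713
8,SVR,1,87.02,0.3514
9,SVR,1,86.67,0.3792
10,SVR,1,92.94,0.2787
1,XGBoost,1,91.77,0.2791
2,XGBoost,1,87.26,0.3909
3,XGBoost,1,89.81,0.3251
4,XGBoost,1,79.45,0.4103
5,XGBoost,1,89.11,0.3183
6,XGBoost,1,90.6,0.2739
7,XGBoost,1,91.75,0.2933
8,XGBoost,1,82.55,0.4083
9,XGBoost,1,85.37,0.3953
10,XGBoost,1,93.69,0.2627
1,JADE-STACK,1,96.12,0.2076
2,JADE-STACK,1,94.48,0.2616
3,JADE-STACK,1,95.04,0.2545
4,JADE-STACK,1,91.59,0.3336
5,JADE-STACK,1,94.96,0.2348
6,JADE-STACK,1,95.99,0.2031
7,JADE-STACK,1,95.39,0.2167
8,JADE-STACK,1,93.1,0.295
9,JADE-STACK,1,92.37,0.2834
10,JADE-STACK,1,95.99,0.2186
1,DE-STACK,1,95.01,0.2122
2,DE-STACK,1,94.21,0.2631
3,DE-STACK,1,93.47,0.2616
4,DE-STACK,1,85.56,0.3433
5,DE-STACK,1,93.24,0.2504
6,DE-STACK,1,94.54,0.2047
7,DE-STACK,1,95.13,0.2215
8,DE-STACK,1,90.19,0.3061
9,DE-STACK,1,91.9,0.2949
10,DE-STACK,1,95.94,0.2128
1,GA-STACK,1,95.28,0.2063
2,GA-STACK,1,94.22,0.2629
3,GA-STACK,1,94.01,0.2505
4,GA-STACK,1,86.61,0.3309
5,GA-STACK,1,94.06,0.2347
6,GA-STACK,1,94.55,0.2043
7,GA-STACK,1,95.34,0.2169
8,GA-STACK,1,90.95,0.2939
9,GA-STACK,1,92.33,0.2864
10,GA-STACK,1,95.95,0.2129
1,PSO-STACK,1,95.34,0.2051
2,PSO-STACK,1,94.25,0.2625
3,PSO-STACK,1,93.9,0.2525
4,PSO-STACK,1,85.18,0.348
5,PSO-STACK,1,94.09,0.234
6,PSO-STACK,1,94.58,0.2035
7,PSO-STACK,1,95.04,0.2247
8,PSO-STACK,1,88.64,0.3293
9,PSO-STACK,1,92.44,0.2841
10,PSO-STACK,1,95.93,0.2126
1,NARMAX-HNN,1,94.37,
2,NARMAX-HNN,1,92.83,
3,NARMAX-HNN,1,90.95,
4,NARMAX-HNN,1,91.02,
5,NARMAX-HNN,1,92.58,
6,NARMAX-HNN,1,93.76,
7,NARMAX-HNN,1,93.08,
8,NARMAX-HNN,1,90.23,
9,NARMAX-HNN,1,90.36,
10,NARMAX-HNN,1,94.15,
1,NARMAX-P,1,95.52,
2,NARMAX-P,1,94.74,
3,NARMAX-P,1,92.95,
4,NARMAX-P,1,91.94,
5,NARMAX-P,1,94.04,
6,NARMAX-P,1,93.72,
7,NARMAX-P,1,95.73,
8,NARMAX-P,1,91.9,
9,NARMAX-P,1,92.24,
10,NARMAX-P,1,96.28,
1,Volterra_1,1,38.37,
2,Volterra_1,1,29.12,
3,Volterra_1,1,32.18,
4,Volterra_1,1,28.1,
5,Volterra_1,1,53.74,
6,Volterra_1,1,61.07,
7,Volterra_1,1,54.3,
8,Volterra_1,1,39.95,
9,Volterra_1,1,26.35,
10,Volterra_1,1,65.19,
1,Volterra_2,1,45,
2,Volterra_2,1,34,
3,Volterra_2,1,40,
4,Volterra_2,1,50,
5,Volterra_2,1,56,
6,Volterra_2,1,46,
7,Volterra_2,1,60,
8,Volterra_2,1,51,
9,Volterra_2,1,36,
10,Volterra_2,1,44,
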