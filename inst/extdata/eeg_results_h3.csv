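participant,model,horizon,vaf,rmse
1,LASSO,3,77.62,0.4605
2,LASSO,3,61.16,0.6822
3,LASSO,3,61.39,0.6319
4,LASSO,3,53.62,0.6173
5,LASSO,3,67.66,0.5485
6,LASSO,3,72.1,0.47
7,LASSO,3,76.2,0.4985
8,LASSO,3,59.55,0.6207
9,LASSO,3,63.69,0.6232
10,LASSO,3,73.92,0.5348
1,MLP,3,70.97,0.546
2,MLP,3,65.57,0.6467
3,MLP,3,47.2,0.743
4,MLP,3,46.84,0.6698
5,MLP,3,60.96,0.6118
6,MLP,3,68.02,0.519
7,MLP,3,67.53,0.666
8,MLP,3,43.11,0.7953
9,MLP,3,57.4,0.6775
10,MLP,3,66.34,0.6664
1,GP,3,66.39,0.5626
2,GP,3,52.82,0.753
3,GP,3,66.02,0.5953
4,GP,3,48,0.6528
5,GP,3,65.26,0.5699
6,GP,3,63.12,0.5411
7,GP,3,70.85,0.5515
8,GP,3,52.03,0.6779
9,GP,3,53.12,0.7086
10,GP,3,67.07,0.6008
1,SVR,3,67.95,0.5514
2,SVR,3,52.85,0.7531
3,SVR,3,66.43,0.5908
4,SVR,3,49.96,0.6415
5,SVR,3,67.05,0.5538
6,SVR,3,65.5,0.5223
7,SVR,3,72.1,0.5402
8,SVR,3,53.03,0.6685
9,SVR,3,54.3,0.7034
10,SVR,3,67.69,0.5955
1,XGBoost,3,66.12,0.5654
2,XGBoost,3,50.13,0.776
3,XGBoost,3,70.08,0.5578
4,XGBoost,3,37.54,0.7169
5,XGBoost,3,55.64,0.6426
6,XGBoost,3,59.68,0.5706
7,XGBoost,3,71.49,0.5454
8,XGBoost,3,46.7,0.7168
9,XGBoost,3,55.09,0.6932
10,XGBoost,3,74.32,0.5304
1,JADE-STACK,3,77.59,0.4655
2,JADE-STACK,3,63.77,0.6589
3,JADE-STACK,3,64.92,0.6023
4,JADE-STACK,3,52.37,0.6252
5,JADE-STACK,3,69.51,0.5327
6,JADE-STACK,3,72.55,0.4656
7,JADE-STACK,3,76.74,0.493
8,JADE-STACK,3,61.08,0.6085
9,JADE-STACK,3,63.47,0.629
10,JADE-STACK,3,73.03,0.5445
1,DE-STACK,3,73.81,0.3618
2,DE-STACK,3,63.82,0.6584
3,DE-STACK,3,61.14,0.6342
4,DE-STACK,3,47.47,0.6571
5,DE-STACK,3,66.8,0.5564
6,DE-STACK,3,72.85,0.4633
7,DE-STACK,3,75.07,0.5106
8,DE-STACK,3,55.87,0.6486
9,DE-STACK,3,65.61,0.6108
10,DE-STACK,3,73.84,0.5353
1,GA-STACK,3,77.81,0.461
2,GA-STACK,3,62.98,0.6662
3,GA-STACK,3,65.78,0.5949
4,GA-STACK,3,53.68,0.6194
5,GA-STACK,3,69.34,0.534
6,GA-STACK,3,72.98,0.462
7,GA-STACK,3,67.53,0.4843
8,GA-STACK,3,58.56,0.6283
9,GA-STACK,3,62.9,0.6334
10,GA-STACK,3,73.65,0.5379
1,PSO-STACK,3,78.28,0.4577
2,PSO-STACK,3,63.35,0.6638
3,PSO-STACK,3,65.63,0.5961
4,PSO-STACK,3,48.71,0.6479
5,PSO-STACK,3,69.48,0.5333
6,PSO-STACK,3,73.81,0.4555
7,PSO-STACK,3,73.54,0.5274
8,PSO-STACK,3,55.45,0.651
9,PSO-STACK,3,63.33,0.6289
10,PSO-STACK,3,73.71,0.5363
1,NARMAX-HNN,3,63.44,
2,NARMAX-HNN,3,56.85,
3,NARMAX-HNN,3,67.16,
4,NARMAX-HNN,3,74.89,
5,NARMAX-HNN,3,82.31,
6,NARMAX-HNN,3,75.55,
7,NARMAX-HNN,3,74.32,
8,NARMAX-HNN,3,43.4,
9,NARMAX-HNN,3,77.16,
10,NARMAX-HNN,3,78.44,
1,NARMAX-P,3,57.08,
2,NARMAX-P,3,39.53,
3,NARMAX-P,3,31.17,
4,NARMAX-P,3,32.26,
5,NARMAX-P,3,61.57,
6,NARMAX-P,3,49.18,
7,NARMAX-P,3,65.35,
8,NARMAX-P,3,32.57,
9,NARMAX-P,3,37.98,
10,NARMAX-P,3,64.21,
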