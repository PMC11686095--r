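digit,step,x,y
0,1,0.5,0.95
0,2,0.3866,0.9101
0,3,0.3041,0.8211
0,4,0.2529,0.7105
0,5,0.2266,0.5913
0,6,0.2215,0.4695
0,7,0.2369,0.3485
0,8,0.275,0.2326
0,9,0.3411,0.1304
0,10,0.4404,0.0616
0,11,0.5596,0.0616
0,12,0.6589,0.1304
0,13,0.725,0.2326
0,14,0.7631,0.3485
0,15,0.7785,0.4695
0,16,0.7734,0.5913
0,17,0.7471,0.7105
0,18,0.6959,0.8211
0,19,0.6134,0.9101
0,20,0.5,0.95
1,1,0.35,0.7
1,2,0.3901,0.7501
1,3,0.4302,0.8003
1,4,0.4704,0.8504
1,5,0.5105,0.9006
1,6,0.55,0.9491
1,7,0.55,0.8848
1,8,0.55,0.8206
1,9,0.55,0.7564
1,10,0.55,0.6922
1,11,0.55,0.628
1,12,0.55,0.5637
1,13,0.55,0.4995
1,14,0.55,0.4353
1,15,0.55,0.3711
1,16,0.55,0.3069
1,17,0.55,0.2427
1,18,0.55,0.1784
1,19,0.55,0.1142
1,20,0.55,0.05
2,1,0.2,0.75
2,2,0.2604,0.8527
2,3,0.3408,0.9241
2,4,0.4593,0.9359
2,5,0.5778,0.9478
2,6,0.6703,0.8836
2,7,0.7569,0.8018
2,8,0.7513,0.6975
2,9,0.7122,0.585
2,10,0.639,0.4951
2,11,0.5505,0.4154
2,12,0.462,0.3358
2,13,0.3734,0.2561
2,14,0.2849,0.1764
2,15,0.2048,0.0998
2,16,0.3239,0.0959
2,17,0.4429,0.0919
2,18,0.5619,0.0879
2,19,0.681,0.084
2,20,0.8,0.08
3,1,0.22,0.9
3,2,0.3254,0.9042
3,3,0.4308,0.9084
3,4,0.5362,0.9126
3,5,0.6416,0.9169
3,6,0.7032,0.8988
3,7,0.6376,0.8162
3,8,0.5719,0.7336
3,9,0.5063,0.6509
3,10,0.4618,0.5709
3,11,0.5455,0.5067
3,12,0.6293,0.4426
3,13,0.713,0.3784
3,14,0.7166,0.3015
3,15,0.6567,0.2147
3,16,0.5968,0.1279
3,17,0.5276,0.0654
3,18,0.4251,0.0903
3,19,0.3225,0.1151
3,20,0.22,0.14
4,1,0.62,0.05
4,2,0.62,0.1688
4,3,0.62,0.2877
4,4,0.62,0.4065
4,5,0.62,0.5254
4,6,0.62,0.6442
4,7,0.62,0.7631
4,8,0.62,0.8819
4,9,0.5899,0.9091
4,10,0.5194,0.8135
4,11,0.4489,0.7178
4,12,0.3784,0.6221
4,13,0.3079,0.5264
4,14,0.2374,0.4308
4,15,0.2558,0.38
4,16,0.3746,0.38
4,17,0.4935,0.38
4,18,0.6123,0.38
4,19,0.7312,0.38
4,20,0.85,0.38
5,1,0.78,0.95
5,2,0.659,0.9453
5,3,0.538,0.9407
5,4,0.417,0.936
5,5,0.296,0.9314
5,6,0.2531,0.8452
5,7,0.2433,0.7245
5,8,0.2335,0.6038
5,9,0.3062,0.5724
5,10,0.4257,0.5917
5,11,0.5453,0.6111
5,12,0.642,0.5696
5,13,0.7195,0.4765
5,14,0.7971,0.3835
5,15,0.74,0.2801
5,16,0.6777,0.1762
5,17,0.6112,0.081
5,18,0.4908,0.094
5,19,0.3704,0.107
5,20,0.25,0.12
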