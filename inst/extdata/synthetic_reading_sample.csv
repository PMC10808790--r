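"engagement","liking","disorder"
10.758,13.8914,10.7296
7.0843,6.0958,7.5788
13.5008,8.9626,7.667
10.3433,10.405,8.046
7.7725,11.1184,7.7468
10.2581,10.4192,8.4555
11.7782,7.9285,10.143
10.794,10.9065,11.9425
14.3738,13.086,11.6521
12.9814,10.3721,13.4913
6.1814,10.0923,8.6136
12.2433,11.0945,8.303
10.2299,7.6345,8.011
7.6225,9.8312,11.3333
13.3669,11.2805,11.789
10.3636,15.0825,8.6577
8.3317,7.4504,10.0677
10.3522,11.4973,8.8885
7.037,4.619,10.1171
9.5287,6.2376,11.1859
5.9083,8.2041,4.8718
10.7556,9.579,11.4926
12.8329,9.4304,9.0334
12.7305,12.354,9.409
11.2312,11.9284,8.152
13.0588,12.4317,7.6558
12.5156,12.7075,10.0867
10.9884,11.2968,4.1944
10.9509,9.143,8.5791
11.314,10.6782,12.4933
13.0353,13.5275,9.2719
8.7234,9.2854,9.5524
13.3288,13.1007,12.0246
11.4288,9.7246,8.724
13.6619,14.8025,11.6072
9.7275,8.1281,13.6852
10.3395,13.5365,14.3559
13.3065,10.2136,11.6736
9.9379,7.2724,7.6455
5.1597,4.7793,6.1816
10.3618,8.6825,9.617
7.6348,8.8806,11.0552
6.7302,7.0785,11.5076
9.2969,8.4957,10.4262
9.9438,8.1758,7.4936
11.5027,12.8998,10.9609
7.7195,8.1163,7.9968
5.8584,5.4331,9.5887
6.7766,7.9445,9.7433
9.1293,13.7563,9.0268
6.7438,8.7806,9.1101
8.4146,11.6706,15.1681
7.1662,13.137,6.6823
13.166,13.3708,8.682
11.9334,11.3571,10.9566
7.9314,8.8473,11.9128
8.1421,6.8635,12.2638
9.9959,9.0416,8.3785
12.093,10.6773,11.9365
12.6593,10.7726,8.3005
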