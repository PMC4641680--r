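channel	time_ms
48	4.05
36	14.339
0	34.677
24	164.482
9	172.918
35	267.355
17	320.448
57	328.091
48	388.159
46	481.933
23	486.411
6	520.156
35	619.41
24	723.671
36	728.918
45	790.505
19	836.953
25	838.848
49	928.594
46	950.683
2	996.406
40	1063.096
24	1069.947
26	1147.627
35	1148.325
36	1153.62
30	1270.028
44	1322.038
4	1365.052
19	1375.178
33	1427.307
27	1465.724
39	1505.976
2	1544.35
57	1639.289
32	1656.782
41	1730.012
23	1745.28
29	1771.364
42	1832.878
14	1887.495
21	1991.984
57	2039.407
7	2056.736
35	2065.289
3	2065.7
21	2082.855
17	2131.856
44	2248.729
27	2269.761
4	2291.465
3	2301.233
33	2329.344
55	2458.533
49	2485.452
34	2516.636
23	2530.025
22	2551.073
48	2663.696
52	2665.206
25	2770.604
49	2827.642
5	2845.741
5	3009.062
1	3038.528
51	3051.433
2	3053.993
53	3069.202
20	3165.616
1	3198.318
54	3205.662
37	3238.22
57	3345.997
9	3399.056
39	3410.399
4	3458.498
32	3479.114
48	3488.098
38	3507.546
35	3517.92
44	3626.018
41	3929.019
8	3938.296
28	3968.551
11	4005.549
19	4006.897
8	4009.926
42	4011.479
34	4012.028
28	4012.972
15	4013.898
36	4014.754
27	4014.964
55	4015.92
45	4016
4	4018.058
27	4022.995
53	4024.216
1	4024.306
17	4024.551
23	4025.951
48	4026.404
17	4026.535
4	4026.874
45	4028.871
39	4029.047
54	4031.693
39	4032.894
20	4034.478
35	4035.748
56	4035.778
35	4035.887
38	4037.462
41	4037.678
17	4039.016
26	4039.83
12	4040.228
52	4040.63
53	4042.499
18	4044.974
31	4046.253
15	4046.302
53	4047.342
59	4050.815
28	4051.176
16	4054.717
43	4056.486
8	4056.606
56	4056.711
20	4056.937
42	4057.698
56	4058.974
57	4059.988
47	4060.605
7	4061.511
28	4062.289
54	4062.441
37	4064.175
0	4065.81
12	4067.285
13	4067.789
4	4068.625
8	4069
54	4070.331
15	4073.022
25	4073.507
42	4080.843
41	4083.281
41	4083.681
55	4083.706
32	4084.765
58	4084.842
56	4085.508
28	4085.756
24	4086.057
50	4086.56
31	4086.899
16	4087.373
45	4088.084
13	4088.533
46	4089.848
5	4091.862
55	4091.935
46	4092.169
42	4092.688
36	4093.701
15	4095.558
48	4098.873
53	4098.9
48	4099.765
49	4100.628
30	4101.082
33	4102.263
29	4104.879
31	4105.172
5	4105.252
21	4105.432
37	4105.899
30	4108.129
5	4109.444
19	4110.671
59	4113.455
14	4114.588
33	4114.622
41	4115.776
22	4140.924
59	4162.936
11	4243.347
25	4309.256
40	4339.756
0	4417.741
1	4474.573
55	4501.373
23	4507.74
33	4587.231
24	4636.517
27	4656.624
42	4664.852
13	4769.192
33	4779.508
59	4784.689
1	4806.177
30	4827.569
31	4829.239
26	4841.677
9	4862.422
56	4866.429
27	4893.425
53	4909.19
36	4981.566
9	5141.574
48	5149.23
48	5155.512
4	5174.37
34	5182.666
13	5185.696
13	5195.605
27	5234.077
57	5243.071
32	5246.433
36	5311.337
34	5387.72
53	5429.128
25	5455.144
30	5625.401
44	5705.414
42	5753.529
51	5770.482
57	5784.584
31	5964.72
16	6078.406
58	6340.281
26	6360.845
29	6399.843
51	6454.504
35	6467.749
19	6494.54
10	6501.287
16	6593.197
8	6658.076
16	6669.713
12	6722.162
30	6725.682
59	6809.63
48	6852.282
51	6899.186
0	6903.517
16	6969.568
32	7148.488
27	7169.321
1	7374.533
30	7501.347
7	7501.651
15	7503.179
2	7504.218
36	7507.505
12	7509.841
11	7510.564
0	7512.057
29	7512.431
50	7513.145
59	7514.647
30	7519.123
36	7520.044
46	7520.727
55	7521.061
5	7521.117
54	7521.872
15	7522.21
9	7523.844
6	7524.05
8	7527.384
40	7528.852
24	7529.699
2	7529.7
17	7533.676
52	7536.738
46	7538.619
27	7541.436
59	7542.227
14	7543.698
28	7547.113
56	7550.87
19	7555.248
24	7555.962
15	7556.622
53	7557.04
23	7557.206
32	7557.779
37	7558.504
42	7558.666
40	7559.869
21	7560.586
25	7561.263
53	7561.546
53	7562.047
19	7563.366
54	7565.859
53	7565.947
57	7571.529
44	7574.854
36	7575.553
42	7577.935
14	7578.319
20	7579.844
33	7580.29
24	7580.598
37	7581.229
0	7582.987
13	7586.095
47	7589.284
48	7590.274
10	7591.615
27	7592.302
17	7592.523
54	7592.582
33	7593.766
57	7593.838
41	7594.447
35	7594.833
19	7595.473
14	7598.393
6	7600.614
48	7601.015
26	7602.183
29	7602.974
4	7603.632
21	7605.932
19	7608.754
49	7611.59
57	7613.123
40	7616.74
10	7622.278
27	7623.612
37	7628.892
41	7629.536
8	7633.853
22	7634.989
25	7635.034
50	7636.357
40	7637.179
10	7637.627
18	7637.829
27	7638.095
20	7638.894
35	7639.521
41	7641.254
21	7641.678
24	7642.243
53	7642.788
58	7643.748
48	7644.435
29	7645.615
58	7648.843
20	7685.472
43	7688.522
20	7728.646
5	7764.451
46	7858.811
40	7919.469
9	7950.512
23	8058.112
49	8077.19
54	8086.018
6	8111.208
13	8115.168
11	8284.231
52	8336.876
50	8338.633
9	8396.313
56	8408.77
24	8453.93
36	8457.362
1	8551.35
34	8565.107
33	8620.26
26	8857.939
45	8934.218
30	8941.425
26	8943.934
15	8958.912
35	9028.058
55	9048.984
52	9060.51
23	9112.845
37	9164.49
51	9195.251
20	9204.891
19	9213.298
10	9219.137
57	9301.337
32	9332.703
58	9517.234
13	9613.436
27	9791.736
32	9798.159
28	9865.186
35	9930.453
44	9931.198
31	9959.923
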