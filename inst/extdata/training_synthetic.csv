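"class","length_um","thickness_um","r1","r2"
"hermaphrodite",1216.58,56.36,0.3462,0.4286
"hermaphrodite",1065.43,58.21,0.3077,0.4286
"hermaphrodite",1067,60.98,0.4615,0.5217
"hermaphrodite",1008.77,52.35,0.4286,0.4615
"hermaphrodite",972.2,54.71,0.375,0.4583
"hermaphrodite",924,53.27,0.375,0.5385
"hermaphrodite",1119.93,54.55,0.25,0.4286
"hermaphrodite",1142.39,57.99,0.24,0.4286
"hermaphrodite",1198.85,60.26,0.4,0.4615
"hermaphrodite",1093.47,51.23,0.3214,0.5833
"hermaphrodite",1185.66,50.28,0.3077,0.6364
"hermaphrodite",984.54,52.96,0.4286,0.4444
"hermaphrodite",1035.43,49.99,0.2308,0.4615
"hermaphrodite",950.93,56.96,0.25,0.4138
"hermaphrodite",1176.93,50.62,0.25,0.3793
"hermaphrodite",1151.31,61.69,0.375,0.5
"hermaphrodite",932.35,51.43,0.3077,0.5
"hermaphrodite",1165.89,61.32,0.2857,0.5833
"hermaphrodite",1145.74,51.74,0.25,0.5
"hermaphrodite",934.77,48.5,0.4,0.5833
"hermaphrodite",1039.23,49.48,0.2857,0.4583
"hermaphrodite",1015.74,56.49,0.3077,0.6667
"hermaphrodite",990.58,52.29,0.375,0.5714
"hermaphrodite",987.89,59.75,0.3077,0.4583
"hermaphrodite",1082.97,53.18,0.2308,0.5517
"hermaphrodite",1020.01,59.44,0.2857,0.4444
"hermaphrodite",1037,56.88,0.2857,0.5517
"hermaphrodite",1228.85,52.4,0.4375,0.45
"hermaphrodite",950.47,51.08,0.375,0.5
"hermaphrodite",1188.54,60.79,0.2857,0.5833
"hermaphrodite",1166.16,52.9,0.3462,0.3929
"hermaphrodite",1072.66,58.89,0.4,0.4
"hermaphrodite",1040.16,57.84,0.5,0.5714
"hermaphrodite",918.89,59.13,0.2609,0.4667
"hermaphrodite",1024.47,51.55,0.2727,0.5
"hermaphrodite",927.16,49.9,0.2069,0.5
"hermaphrodite",1199.77,55.39,0.25,0.5714
"hermaphrodite",960.31,61.95,0.2759,0.5714
"hermaphrodite",969.31,55.44,0.3333,0.4286
"hermaphrodite",1174.16,60.67,0.3214,0.3333
"hermaphrodite",963,58.79,0.2857,0.5
"hermaphrodite",889.08,55.17,0.2609,0.5517
"hermaphrodite",1139.7,62.39,0.25,0.4074
"hermaphrodite",1092.81,57.88,0.2963,0.5714
"hermaphrodite",1200.43,57.09,0.5,0.5517
"hermaphrodite",1164.77,53,0.25,0.5
"male",888.62,44.98,0.6667,0.6923
"male",775.16,47.69,0.6154,0.8333
"male",797.35,48.64,0.4615,0.7143
"male",761.97,42.97,0.4615,0.8571
"male",731.89,44.28,0.4583,0.8571
"male",694.46,44.35,0.4583,0.8571
"male",843.31,43.14,0.4583,0.7692
"male",829,48.06,0.5714,0.7586
"male",894.66,46.56,0.5217,0.75
"male",814.62,41.7,0.5,0.8148
"male",862.62,41.53,0.3913,0.7586
"male",727.43,44.32,0.5,0.8
"male",784.81,40.16,0.4615,0.7857
"male",720.93,45.65,0.4583,0.75
"male",848.5,41.78,0.6154,0.7857
"male",857.89,49.1,0.5714,0.6923
"male",694.27,43.39,0.5185,0.7586
"male",861.7,48.05,0.5,0.8333
"male",838.85,42.41,0.5,1
"male",707.46,40.61,0.4583,0.8
"male",776.73,40.2,0.4583,0.7143
"male",755.47,45.52,0.5926,0.9167
"male",736.16,43.96,0.4286,0.9167
"male",737.27,48.02,0.375,0.7692
"male",813.97,42.72,0.4615,0.8462
"male",775.43,46.69,0.5,0.6667
"male",776.73,46.13,0.4231,0.75
"male",901.35,42.05,0.4583,0.8333
"male",720.46,41.99,0.5,0.6429
"male",869.77,48.67,0.4231,0.8
"male",897.81,41.32,0.4286,0.7143
"male",777.2,48.44,0.4615,0.9286
"male",769.58,46.88,0.4583,0.7143
"male",708.39,46.88,0.4583,0.8148
"male",771.16,41.36,0.5455,0.6071
"male",702.08,42.12,0.6667,0.8214
"male",889.08,44.05,0.6429,0.6667
"male",743.77,48.68,0.6667,0.7143
"male",719.81,45.14,0.5455,0.6667
"male",862.35,48.21,0.5417,0.8333
"male",732.35,46.9,0.5217,0.8
"male",678.12,45.11,0.5714,0.8077
"male",828.54,49.67,0.6071,0.6154
"male",796.7,47.2,0.5,0.5926
"male",889.27,45.61,0.5417,0.8333
"male",861.7,42.26,0.5185,0.875
"larva",596.96,19.6,0.6667,0.75
"larva",392.31,17.12,0.5,0.7273
"larva",409.58,17.74,0.5,0.7778
"larva",332.23,15.13,0.5,0.6364
"larva",276.62,13.9,0,0.7273
"larva",248.39,14.46,0.6667,0.7273
"larva",489.35,17.27,0.5,0.5
"larva",445.42,20.68,0.5,0.7273
"larva",561.31,19.5,0,0.6667
"larva",425.92,15.97,0.5,0.7273
"larva",521.19,16.54,0.3333,0.5
"larva",299.92,15.5,0.3333,0.6154
"larva",369,15.92,0.4286,0.8
"larva",250.15,14.19,0.5,0.6667
"larva",534.66,16.2,0.5455,0.5455
"larva",519.62,20.82,0.5,0.5714
"larva",529.92,20.49,0,0.3333
"larva",484.89,16.73,0.3636,0.6667
"larva",243.65,13.01,0.5,0.5
"larva",363.16,15.01,0.3636,0.5
"larva",299.73,16.49,0.5,0.6667
"larva",325.27,15.2,0,0.5
"larva",301.04,15.72,0.5,0.6667
"larva",435.12,15.73,0.3636,1
"larva",307.35,18.15,0.5,0.7778
"larva",386.46,17.38,0.5,0.7273
"larva",570.04,17.79,0.3333,0.75
"larva",255.54,14.22,0.5,0.6154
"larva",546.08,21.04,0.5,0.6667
"larva",517.85,17.46,0.375,0.6667
"larva",391.39,18.57,0.3333,0.6667
"larva",368.54,17.31,0,0.5
"larva",348.58,15.27,0.3636,0.75
"larva",247.92,14.49,0.2857,0.3636
"larva",572.54,19.19,0,0.5
"larva",299.92,16.06,0.5,0.6154
"larva",281.54,14.26,0.5,0.6667
"larva",527.23,20.43,0.3333,0.6667
"larva",303.54,15.45,0.75,1
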