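time,0,0.5,1,1.5,2,2.5,3,3.5,4,4.5,5,5.5,6,6.5,7,7.5,8,8.5,9,9.5,10,10.5,11,11.5,12,12.5,13,13.5,14,14.5,15,15.5,16,16.5,17,17.5,18,18.5,19,19.5,20,20.5,21,21.5,22,22.5,23,23.5,24
blank,0.0836,0.085,0.085,0.087,0.0843,0.0864,0.0863,0.0836,0.084,0.086,0.0844,0.084,0.0858,0.0865,0.0857,0.0852,0.0834,0.0863,0.0838,0.0855,0.0839,0.0849,0.0844,0.0852,0.0854,0.0856,0.0861,0.0846,0.0842,0.0847,0.085,0.0865,0.0857,0.0854,0.0857,0.0859,0.0862,0.0855,0.0881,0.0859,0.0859,0.0854,0.0838,0.0832,0.0847,0.0863,0.0855,0.0847,0.0843
blank,0.0855,0.0844,0.0858,0.0845,0.0867,0.0855,0.0848,0.0848,0.084,0.0848,0.0834,0.0837,0.0856,0.0856,0.086,0.0834,0.0862,0.087,0.0846,0.0842,0.085,0.0842,0.0845,0.0841,0.084,0.0872,0.0862,0.0856,0.0861,0.0845,0.0865,0.0847,0.086,0.0871,0.0831,0.084,0.0854,0.0838,0.0856,0.0857,0.0846,0.0862,0.0855,0.0869,0.0845,0.086,0.0842,0.086,0.0838
blank,0.0846,0.0849,0.0848,0.0842,0.0851,0.0867,0.0855,0.0837,0.0857,0.0841,0.0844,0.0854,0.0842,0.0845,0.0826,0.084,0.0862,0.0833,0.083,0.0848,0.0841,0.0852,0.0858,0.0865,0.0847,0.0847,0.0862,0.0844,0.0843,0.0845,0.0847,0.086,0.0838,0.0849,0.0847,0.0846,0.0851,0.0858,0.0853,0.084,0.0859,0.0853,0.086,0.0849,0.085,0.0848,0.0846,0.0858,0.0857
wildtype,0.1253,0.1263,0.1297,0.1258,0.1282,0.1307,0.1319,0.1427,0.1547,0.1724,0.1965,0.233,0.2793,0.3359,0.4,0.4668,0.5414,0.6089,0.6768,0.7367,0.7904,0.8397,0.8802,0.9145,0.9465,0.9698,0.9855,1.0009,1.0136,1.0258,1.0381,1.0424,1.0454,1.0506,1.0529,1.0568,1.0592,1.0597,1.057,1.0629,1.0656,1.0616,1.0644,1.0647,1.0668,1.0654,1.0669,1.0675,1.064
wildtype,0.128,0.1265,0.127,0.1252,0.126,0.1281,0.1298,0.1384,0.1444,0.1588,0.1788,0.205,0.2375,0.2827,0.3348,0.3954,0.4585,0.5216,0.5894,0.6469,0.7033,0.7527,0.7968,0.8321,0.8683,0.8951,0.9216,0.9405,0.9538,0.9634,0.9779,0.9818,0.9919,0.9999,0.9995,1.0047,1.0072,1.0098,1.013,1.0149,1.0148,1.0142,1.0156,1.0163,1.015,1.0165,1.0193,1.0168,1.0153
wildtype,0.125,0.1263,0.1288,0.1262,0.1266,0.1297,0.1333,0.1447,0.1645,0.1874,0.2204,0.2658,0.3239,0.3915,0.4642,0.5433,0.6209,0.7,0.7769,0.8417,0.8959,0.9454,0.9883,1.0195,1.0533,1.0767,1.0945,1.111,1.1237,1.1327,1.1393,1.1464,1.15,1.1559,1.1561,1.1592,1.1647,1.1598,1.162,1.1651,1.171,1.1672,1.1693,1.1673,1.1671,1.1657,1.1692,1.168,1.1665
mutant_A,0.1256,0.1263,0.1248,0.1292,0.1245,0.126,0.1232,0.1292,0.1268,0.1282,0.1288,0.133,0.1371,0.1445,0.1618,0.1657,0.1778,0.1968,0.2161,0.2335,0.2551,0.2796,0.3021,0.3231,0.3458,0.3646,0.3892,0.3963,0.4197,0.4335,0.4426,0.4601,0.4701,0.4739,0.4822,0.4885,0.4919,0.5014,0.5064,0.5024,0.5101,0.5149,0.5157,0.5166,0.5179,0.5232,0.5149,0.5192,0.5214
mutant_A,0.1237,0.1251,0.1267,0.1263,0.1255,0.128,0.1282,0.1228,0.1289,0.1263,0.1266,0.1317,0.132,0.1403,0.1451,0.158,0.168,0.1772,0.1901,0.2073,0.226,0.2492,0.269,0.2922,0.3156,0.3384,0.36,0.3809,0.3985,0.4163,0.4363,0.4541,0.4676,0.4805,0.4943,0.5013,0.5134,0.5188,0.5244,0.533,0.5381,0.5433,0.5463,0.5519,0.5559,0.5535,0.5588,0.5624,0.5599
mutant_A,0.1233,0.1252,0.1224,0.1225,0.125,0.1265,0.1227,0.1286,0.1246,0.1286,0.132,0.1351,0.1436,0.152,0.1601,0.1771,0.1927,0.212,0.2339,0.2548,0.2813,0.3063,0.3314,0.3562,0.3757,0.4005,0.4198,0.435,0.4547,0.4651,0.4797,0.4887,0.4985,0.506,0.5124,0.5152,0.5233,0.5245,0.5332,0.5331,0.5401,0.539,0.5403,0.5419,0.54,0.5448,0.5461,0.5435,0.5454
mutant_B,0.1249,0.1245,0.1234,0.1249,0.1254,0.1231,0.1209,0.1227,0.1292,0.122,0.125,0.1269,0.1263,0.1271,0.1219,0.1294,0.1304,0.1284,0.1386,0.1424,0.1536,0.172,0.1886,0.2157,0.2492,0.285,0.3305,0.3722,0.4248,0.4732,0.5187,0.5691,0.6106,0.6429,0.6835,0.7123,0.7429,0.7667,0.7859,0.8026,0.8174,0.8292,0.8389,0.8476,0.8556,0.858,0.863,0.8671,0.8756
mutant_B,0.1261,0.1247,0.1288,0.1211,0.1242,0.1248,0.1246,0.1254,0.1214,0.1255,0.1228,0.125,0.1261,0.1263,0.123,0.1229,0.1255,0.1284,0.1298,0.1369,0.1405,0.1512,0.1656,0.182,0.2082,0.2304,0.2639,0.3005,0.341,0.3844,0.4267,0.4669,0.5082,0.5452,0.5813,0.6119,0.6427,0.671,0.6881,0.7089,0.7265,0.7419,0.7507,0.7602,0.7739,0.7775,0.7882,0.7891,0.7898
mutant_B,0.1235,0.125,0.123,0.1226,0.1257,0.1278,0.1275,0.1238,0.1254,0.1239,0.1243,0.1237,0.1235,0.122,0.1263,0.1221,0.1249,0.1305,0.1329,0.1337,0.1502,0.1603,0.1778,0.2048,0.2385,0.2775,0.3184,0.3652,0.4192,0.4737,0.5262,0.5821,0.6369,0.6801,0.7248,0.7594,0.7967,0.8242,0.8491,0.8682,0.8872,0.9022,0.9144,0.9248,0.9335,0.9422,0.9466,0.9513,0.957
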