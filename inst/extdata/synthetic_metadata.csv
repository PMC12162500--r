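barcode,sample_id,subset,state
cell0000001,S0_01,sim,0
cell0000002,S0_01,sim,0
cell0000003,S0_01,sim,0
cell0000004,S0_01,sim,0
cell0000005,S0_01,sim,0
cell0000006,S0_01,sim,0
cell0000007,S0_01,sim,0
cell0000008,S0_01,sim,0
cell0000009,S0_01,sim,0
cell0000010,S0_01,sim,0
cell0000011,S0_01,sim,0
cell0000012,S0_01,sim,0
cell0000013,S0_02,sim,0
cell0000014,S0_02,sim,0
cell0000015,S0_02,sim,0
cell0000016,S0_02,sim,0
cell0000017,S0_02,sim,0
cell0000018,S0_02,sim,0
cell0000019,S0_02,sim,0
cell0000020,S0_02,sim,0
cell0000021,S0_02,sim,0
cell0000022,S0_02,sim,0
cell0000023,S0_02,sim,0
cell0000024,S0_02,sim,0
cell0000025,S0_03,sim,0
cell0000026,S0_03,sim,0
cell0000027,S0_03,sim,0
cell0000028,S0_03,sim,0
cell0000029,S0_03,sim,0
cell0000030,S0_03,sim,0
cell0000031,S0_03,sim,0
cell0000032,S0_03,sim,0
cell0000033,S0_03,sim,0
cell0000034,S0_03,sim,0
cell0000035,S0_03,sim,0
cell0000036,S0_03,sim,0
cell0000037,S1_01,sim,1
cell0000038,S1_01,sim,1
cell0000039,S1_01,sim,1
cell0000040,S1_01,sim,1
cell0000041,S1_01,sim,1
cell0000042,S1_01,sim,1
cell0000043,S1_01,sim,1
cell0000044,S1_01,sim,1
cell0000045,S1_01,sim,1
cell0000046,S1_01,sim,1
cell0000047,S1_01,sim,1
cell0000048,S1_01,sim,1
cell0000049,S1_02,sim,1
cell0000050,S1_02,sim,1
cell0000051,S1_02,sim,1
cell0000052,S1_02,sim,1
cell0000053,S1_02,sim,1
cell0000054,S1_02,sim,1
cell0000055,S1_02,sim,1
cell0000056,S1_02,sim,1
cell0000057,S1_02,sim,1
cell0000058,S1_02,sim,1
cell0000059,S1_02,sim,1
cell0000060,S1_02,sim,1
cell0000061,S1_03,sim,1
cell0000062,S1_03,sim,1
cell0000063,S1_03,sim,1
cell0000064,S1_03,sim,1
cell0000065,S1_03,sim,1
cell0000066,S1_03,sim,1
cell0000067,S1_03,sim,1
cell0000068,S1_03,sim,1
cell0000069,S1_03,sim,1
cell0000070,S1_03,sim,1
cell0000071,S1_03,sim,1
cell0000072,S1_03,sim,1
cell0000073,S2_01,sim,2
cell0000074,S2_01,sim,2
cell0000075,S2_01,sim,2
cell0000076,S2_01,sim,2
cell0000077,S2_01,sim,2
cell0000078,S2_01,sim,2
cell0000079,S2_01,sim,2
cell0000080,S2_01,sim,2
cell0000081,S2_01,sim,2
cell0000082,S2_01,sim,2
cell0000083,S2_01,sim,2
cell0000084,S2_01,sim,2
cell0000085,S2_02,sim,2
cell0000086,S2_02,sim,2
cell0000087,S2_02,sim,2
cell0000088,S2_02,sim,2
cell0000089,S2_02,sim,2
cell0000090,S2_02,sim,2
cell0000091,S2_02,sim,2
cell0000092,S2_02,sim,2
cell0000093,S2_02,sim,2
cell0000094,S2_02,sim,2
cell0000095,S2_02,sim,2
cell0000096,S2_02,sim,2
cell0000097,S2_03,sim,2
cell0000098,S2_03,sim,2
cell0000099,S2_03,sim,2
cell0000100,S2_03,sim,2
cell0000101,S2_03,sim,2
cell0000102,S2_03,sim,2
cell0000103,S2_03,sim,2
cell0000104,S2_03,sim,2
cell0000105,S2_03,sim,2
cell0000106,S2_03,sim,2
cell0000107,S2_03,sim,2
cell0000108,S2_03,sim,2
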