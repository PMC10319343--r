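Protein IDs	Peptides	Intensity UP2_r1	Intensity UP2_r2	Intensity UP2_r3	Intensity PRH2_r1	Intensity PRH2_r2	Intensity PRH2_r3
P0001	7	2316673.94770546	1358958.21854037	2312025.63436318	1046824.95324759	1630020.22221322	775396.387799261
P0002	5	692576.619323517	1006923.31680908	1173194.08360689	1476839.97093974	1117695.97724399	1345168.31970932
P0003	3	824325.011991936	1105546.91127766	2022956.03220124	1402797.35014775	1360909.7332087	1089569.23224952
P0004	5	908957.632239859	2239878.51165161	1233084.51637251	1338950.23998518	1287260.42760773	1020444.73169962
P0005	5	749029.663892555	1186674.73195055	769253.532727244	1648797.00695456	745822.968697839	906378.912242333
P0006	5	0	0	0	648165.133890086	952901.80078504	862961.733702306
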