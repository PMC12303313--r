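species	culture	replicate	d0	d2	d4	d6	d8
SM	mono	1	304.1640829460223	857.3442582512499	2084.3338684728983	2709.707320771328	3360.134732561317
SM	mono	2	434.9664430916074	796.9184903848452	2363.926407782651	2744.0197138960543	2825.360301246465
SM	mono	3	369.668977552691	1019.8420921844748	2027.985206723764	2840.605945727808	2978.1374335704436
SM	mono	4	71.23421897540882	788.6413375321843	2223.392227674208	2709.153287438016	3210.8052622263954
SM	mono	5	369.10809977439345	988.5729543537173	1966.1551640354992	2565.5300399984644	3137.1394591943135
SM	mono	6	24.767760161619748	1175.1278302102428	1784.4654432966317	2895.680003684847	2970.8772974330655
SM	mono	7	292.44578273140723	872.1312417462583	1749.2584977730812	2691.4236915035385	3054.9657944401124
SM	mono	8	9.94092307058591	1135.8907233769737	2159.8120107346667	2667.8239900818453	2699.055151873177
SM	co	1	497.04856234950296	486.73191177415833	1753.7470601846453	1843.6208560748212	2174.8096120886075
SM	co	2	97.45169407221158	555.7492935083092	1424.1893321335133	2011.9006306832703	2119.981416162368
SM	co	3	0	581.5771005799986	1573.5770623459903	1746.115184743198	1781.3896484047323
SM	co	4	257.70149035494507	668.1871120084063	1343.510258235371	1955.894115270631	2085.971200622018
PP	mono	1	229.64158592377686	780.6397841305746	2053.1968710743727	2494.3885619187504	2843.058539696974
PP	mono	2	275.5961427278761	1203.6764866829476	2052.0826770757503	3082.736576194322	2674.410584052735
PP	mono	3	487.0810879034443	886.5886580036533	2099.370567148633	2981.657481586547	2901.459164556262
PP	mono	4	118.84188599922388	980.1683816866396	1981.7723317389884	2791.8758712247986	2962.374340898993
PP	mono	5	223.32375592876423	1148.1884434658036	1952.7755920655297	2790.0108223583434	2840.579331873018
PP	mono	6	405.7186968870207	772.6818067548294	1977.315698022032	2847.456468951841	3067.449094272056
PP	mono	7	337.44141023504994	1110.524410802759	2329.341610866645	2986.2999175264617	3112.3810926947017
PP	mono	8	89.1858920522989	749.7426451752069	2152.034693368089	2799.035894350266	2781.3426785705365
PP	co	1	118.73347477714725	1117.6694238798998	2275.001602458356	2940.6790441187313	3219.9392602914872
PP	co	2	183.94534605136334	811.4112230201607	2030.3405359783394	2752.301664805108	3318.603943777732
PP	co	3	239.74997443044106	909.4926943375795	1930.6406059329981	2623.5357589882524	3277.814875778675
PP	co	4	229.0445326620491	804.3712200103955	2212.291495197077	2557.482230949218	3447.1224945981053
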