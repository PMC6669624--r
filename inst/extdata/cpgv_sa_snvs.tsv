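pos_sa	ref	alt	variant_coverage
6530	T	C	906
6823	A	G	1452
6879	A	G	1300
6962	T	C	1210
7542	G	A	642
8502	C	T	1800
8646	G	A	1172
9003	A	T	1282
9242	G	A	1338
11275	C	T	584
11503	T	A	474
15891	T	C	1634
17199	C	T	2158
17572	A	G	794
20415	A	T	750
20439	A	T	2215
20451	A	T	2201
20471	C	A	1915
27091	A	G	492
32302	G	T	532
34540	A	G	738
38386	A	T	614
40007	A	G	817
41403	G	A	1544
43827	T	C	840
47598	C	T	1638
47601	C	T	1388
49694	G	A	840
51160	T	A	2964
51166	C	G	2782
51242	G	T	1088
51259	T	C	1426
51265	A	C	1234
51273	C	T	1234
51279	T	G	1266
51284	A	T	1240
51287	T	G	2136
51289	C	A	3170
51290	T	A	970
51290	T	C	2420
51300	G	C	1406
51301	T	A	1390
51308	T	C	3448
51323	T	A	2756
51393	T	A	3328
51445	C	T	3422
51448	C	T	3394
51605	T	A	1392
62567	T	G	1628
64981	T	C	1742
66790	T	C	880
66971	C	T	462
70464	A	G	1272
79018	A	G	828
82048	G	A	612
90574	G	A	1724
90852	C	T	1992
98024	C	G	1630
99031	A	G	1396
100326	A	G	1224
111158	T	C	904
114455	T	C	544
117293	T	C	1250
117676	C	T	466
119691	G	A	1492
122389	C	T	1730
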