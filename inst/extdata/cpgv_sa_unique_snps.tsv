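pos_m	pos_sa	sa	e2	i07	i12	m	s
1355	1355	A	G	G	G	G	G
4732	4785	T	A	A	A	A	A
6826	6879	A	G	G	G	G	G
6909	6962	T	C	C	C	C	C
7448	7501	A	G	G	G	G	G
8659	8712	A	G	G	G	G	G
12978	13048	T	C	C	C	C	C
13476	13546	A	C	C	C	C	C
13879	13949	G	A	A	A	A	A
14318	14389	T	C	C	C	C	C
15829	15891	T	C	C	C	C	C
17138	17199	C	T	T	T	T	T
17511	17572	A	G	G	G	G	G
20146	20185	A	T	T	T	T	T
20293	20316	T	C	C	C	C	C
20314	20337	A	G	G	G	G	G
20442	20439	A	T	T	T	T	T
24975	24946	T	C	C	C	C	C
27108	27091	A	G	G	G	G	G
30837	30847	A	G	G	G	G	G
34313	34368	A	C	C	C	C	C
34485	34540	A	G	G	G	G	G
38331	38386	A	T	T	T	T	T
41720	41775	T	C	C	C	C	C
43772	43827	T	C	C	C	C	C
43925	43980	A	C	C	C	C	C
51043	51160	T	A	A	A	A	A
51049	51166	C	G	G	G	G	G
51177	51279	T	G	G	G	G	G
51398	51308	T	C	C	C	C	C
51413	51323	T	A	A	A	A	A
51483	51393	T	A	A	A	A	A
51534	51445	C	T	T	T	T	T
51537	51448	C	T	T	T	T	T
58836	58937	T	C	C	C	C	C
62466	62567	T	G	G	G	G	G
64748	64824	T	C	C	C	C	C
66714	66790	T	C	C	C	C	C
67897	67973	T	Y	C	C	C	C
68732	68808	A	C	C	C	C	C
70388	70464	A	G	G	G	G	G
72378	72454	C	Y	Y	Y	Y	Y
72492	72568	T	C	C	C	C	C
76189	76265	A	G	G	G	G	G
77867	77943	A	G	G	G	G	G
78942	79018	A	G	G	G	G	G
84035	84111	A	G	G	G	G	G
90782	90852	C	T	T	T	T	T
93156	93226	G	C	C	C	C	C
93414	93484	G	A	A	A	A	A
94559	94626	A	T	T	T	T	T
97937	98024	C	A	G	G	G	G
98947	99031	A	G	G	G	G	G
105867	105933	G	A	A	A	A	A
106113	106179	A	G	G	G	G	G
109603	109669	T	A	A	A	A	A
110904	110970	T	C	C	C	C	C
111093	111158	T	C	C	C	C	C
111270	111335	A	G	G	G	G	G
111535	111600	A	G	G	G	G	G
115974	116038	T	C	C	C	C	C
116322	116386	C	T	T	T	T	T
116527	116591	A	G	G	G	G	G
117053	117117	C	T	T	T	T	T
120008	120072	A	M	C	C	C	C
120642	120706	A	C	C	C	C	C
122324	122389	C	T	T	T	T	T
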