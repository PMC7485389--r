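bracket	nodes	links	density	average_degree	centralization	k_max
0-10	345	2657	0.045	15.403	0.771	NA
11-20	480	2955	0.026	12.313	0.467	NA
21-30	625	4060	0.021	12.992	0.458	NA
31-40	651	4464	0.021	13.714	0.397	NA
41-50	654	5098	0.024	15.590	0.383	NA
51-60	681	6274	0.027	18.426	0.396	NA
61-70	639	6099	0.030	19.089	0.445	NA
71-80	548	5032	0.034	18.365	0.405	NA
81-90	326	2703	0.051	16.583	0.425	NA
91-100	107	506	0.089	9.458	0.351	NA
all_ages	1473	20543	0.019	27.893	0.462	707
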