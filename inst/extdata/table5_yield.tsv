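entry	site	regime	yield_kg_ha	lsd_kg_ha
IR87729-69-B-B-B	DS10	non_stress	4312	NA
IR87729-69-B-B-B	DS11	non_stress	6308	1053
IR87729-69-B-B-B	DS10	stress	2011	NA
IR87729-69-B-B-B	DS11	stress	1943	690
IR87728-491-B-B	DS11	non_stress	6232	1053
IR87728-491-B-B	DS10	stress	1041	NA
IR87728-491-B-B	DS11	stress	1879	690
IR87707-186-B-B-B	DS10	non_stress	4550	NA
IR87707-186-B-B-B	DS11	non_stress	6103	1053
IR87707-186-B-B-B	DS10	stress	2068	NA
IR87707-186-B-B-B	DS11	stress	2632	690
IR87707-359-B-B-B	DS10	non_stress	4638	NA
IR87707-359-B-B-B	DS11	non_stress	6361	1053
IR87707-359-B-B-B	DS10	stress	1934	NA
IR87707-359-B-B-B	DS11	stress	2581	690
IR87707-446-B-B-B	DS10	non_stress	3752	NA
IR87707-446-B-B-B	DS11	non_stress	4388	1053
IR87707-446-B-B-B	DS10	stress	2556	NA
IR87707-446-B-B-B	DS11	stress	3000	690
IR87707-445-B-B-B	DS10	non_stress	5045	NA
IR87707-445-B-B-B	DS11	non_stress	5844	1053
IR87707-445-B-B-B	DS10	stress	2555	NA
IR87707-445-B-B-B	DS11	stress	3023	690
IR87707-182-B-B-B	DS10	non_stress	3875	NA
IR87707-182-B-B-B	DS11	non_stress	5225	1053
IR87707-182-B-B-B	DS10	stress	1926	NA
IR87707-182-B-B-B	DS11	stress	2891	690
IR87728-162-B-B	DS11	non_stress	6115	1053
IR87728-162-B-B	DS10	stress	1147	NA
IR87728-162-B-B	DS11	stress	1636	690
IR87705-83-12-B	DS10	non_stress	4796	NA
IR87705-83-12-B	DS11	non_stress	5526	1053
IR87705-83-12-B	DS10	stress	1916	NA
IR87705-83-12-B	DS11	stress	2270	690
IR87705-80-15-B	DS10	non_stress	3850	NA
IR87705-80-15-B	DS11	non_stress	5516	1053
IR87705-80-15-B	DS10	stress	2074	NA
IR87705-80-15-B	DS11	stress	2151	690
IR87705-72-12-B	DS10	non_stress	3569	NA
IR87705-72-12-B	DS11	non_stress	6090	1053
IR87705-72-12-B	DS10	stress	1879	NA
IR87705-72-12-B	DS11	stress	1892	690
IR87705-6-8-B	DS10	non_stress	5399	NA
IR87705-6-8-B	DS11	non_stress	6208	1053
IR87705-6-8-B	DS10	stress	2152	NA
IR87705-6-8-B	DS11	stress	2588	690
IR87728-395-B-B	DS11	non_stress	6627	1053
IR87728-395-B-B	DS10	stress	2440	NA
IR87728-395-B-B	DS11	stress	2046	690
IR87705-36-3-B	DS10	non_stress	5052	NA
IR87705-36-3-B	DS11	non_stress	6909	1053
IR87705-36-3-B	DS11	stress	2116	690
IR64	DS10	non_stress	2987	NA
IR64	DS11	non_stress	5435	1053
IR64	DS10	stress	636	NA
IR64	DS11	stress	1442	690
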