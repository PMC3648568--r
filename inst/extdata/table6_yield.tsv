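entry	site	regime	yield_kg_ha	lsd_kg_ha
IR87707-445-B-B	Rajshahi	non_stress	4167	240
IR87707-445-B-B	Rajshahi	stress	1525	156
IR87707-445-B-B	Nepalganj	non_stress	5990	324
IR87707-445-B-B	Nepalganj	stress	3472	170
IR87707-445-B-B	Raipur	non_stress	5084	434
IR87707-445-B-B	Raipur	stress	3956	285
IR87707-445-B-B	Hyderabad1	non_stress	5672	186
IR87707-445-B-B	Hyderabad1	stress	1684	939
IR87707-445-B-B	Hyderabad2	non_stress	5672	186
IR87707-445-B-B	Hyderabad2	stress	3800	600
IR87707-445-B-B	Hazaribagh	non_stress	5690	475
IR87707-445-B-B	Hazaribagh	stress	1604	422
IR87707-445-B-B	Rewa	non_stress	4100	920
IR87707-445-B-B	Rewa	stress	3731	909
IR87707-446-B-B	Rajshahi	non_stress	4521	240
IR87707-446-B-B	Rajshahi	stress	1933	156
IR87707-446-B-B	Nepalganj	non_stress	6302	324
IR87707-446-B-B	Nepalganj	stress	2847	170
IR87707-446-B-B	Raipur	non_stress	5771	434
IR87707-446-B-B	Raipur	stress	3614	285
IR87707-446-B-B	Hyderabad1	non_stress	5634	186
IR87707-446-B-B	Hyderabad1	stress	1813	939
IR87707-446-B-B	Hyderabad2	non_stress	5634	186
IR87707-446-B-B	Hyderabad2	stress	4057	600
IR87707-446-B-B	Hazaribagh	non_stress	5711	475
IR87707-446-B-B	Hazaribagh	stress	1229	422
IR87707-446-B-B	Rewa	non_stress	4911	920
IR87707-446-B-B	Rewa	stress	3899	909
IR87707-182-B-B	Rajshahi	non_stress	4312	240
IR87707-182-B-B	Rajshahi	stress	1508	156
IR87707-182-B-B	Nepalganj	non_stress	6510	324
IR87707-182-B-B	Nepalganj	stress	2778	170
IR87707-182-B-B	Raipur	non_stress	5646	434
IR87707-182-B-B	Raipur	stress	3419	285
IR87707-182-B-B	Hyderabad1	non_stress	6047	186
IR87707-182-B-B	Hyderabad1	stress	1383	939
IR87707-182-B-B	Hyderabad2	non_stress	6047	186
IR87707-182-B-B	Hyderabad2	stress	3604	600
IR87707-182-B-B	Hazaribagh	non_stress	4453	475
IR87707-182-B-B	Hazaribagh	stress	1500	422
IR87707-182-B-B	Rewa	non_stress	4513	920
IR87707-182-B-B	Rewa	stress	3509	909
IR64	Rajshahi	non_stress	3379	240
IR64	Rajshahi	stress	980	156
IR64	Nepalganj	non_stress	4297	324
IR64	Nepalganj	stress	1597	170
IR64	Raipur	non_stress	4083	434
IR64	Raipur	stress	2662	285
IR64	Hyderabad1	non_stress	5699	186
IR64	Hyderabad1	stress	660	939
IR64	Hyderabad2	non_stress	5699	186
IR64	Hyderabad2	stress	3085	600
IR64	Hazaribagh	non_stress	5612	475
IR64	Hazaribagh	stress	958	422
IR64	Rewa	non_stress	3586	920
IR64	Rewa	stress	2503	909
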