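name	kind	chrom	start	end	switch_order
IGHV1-2	V	chr14	106700000	106700499	
IGHV1-3	V	chr14	106680000	106680499	
IGHV1-8	V	chr14	106660000	106660499	
IGHV1-18	V	chr14	106640000	106640499	
IGHV1-24	V	chr14	106620000	106620499	
IGHV1-46	V	chr14	106600000	106600499	
IGHV1-69	V	chr14	106580000	106580499	
IGHV2-5	V	chr14	106560000	106560499	
IGHV2-26	V	chr14	106540000	106540499	
IGHV2-70	V	chr14	106520000	106520499	
IGHV3-7	V	chr14	106500000	106500499	
IGHV3-9	V	chr14	106480000	106480499	
IGHV3-11	V	chr14	106460000	106460499	
IGHV3-13	V	chr14	106440000	106440499	
IGHV3-15	V	chr14	106420000	106420499	
IGHV3-20	V	chr14	106400000	106400499	
IGHV3-21	V	chr14	106380000	106380499	
IGHV3-23	V	chr14	106360000	106360499	
IGHV3-30	V	chr14	106340000	106340499	
IGHV3-33	V	chr14	106320000	106320499	
IGHV3-43	V	chr14	106300000	106300499	
IGHV3-48	V	chr14	106280000	106280499	
IGHV3-49	V	chr14	106260000	106260499	
IGHV3-53	V	chr14	106240000	106240499	
IGHV3-64	V	chr14	106220000	106220499	
IGHV3-66	V	chr14	106200000	106200499	
IGHV3-72	V	chr14	106180000	106180499	
IGHV3-73	V	chr14	106160000	106160499	
IGHV3-74	V	chr14	106140000	106140499	
IGHV4-4	V	chr14	106120000	106120499	
IGHV4-31	V	chr14	106100000	106100499	
IGHV4-34	V	chr14	106080000	106080499	
IGHV4-39	V	chr14	106060000	106060499	
IGHV4-59	V	chr14	106040000	106040499	
IGHV4-61	V	chr14	106020000	106020499	
IGHV5-51	V	chr14	106000000	106000499	
IGHV5-10-1	V	chr14	105980000	105980499	
IGHV6-1	V	chr14	105960000	105960499	
IGHV7-4-1	V	chr14	105940000	105940499	
IGHV7-81	V	chr14	105920000	105920499	
IGHJ1	J	chr14	105866000	105866059	
IGHJ2	J	chr14	105865400	105865459	
IGHJ3	J	chr14	105864800	105864859	
IGHJ4	J	chr14	105864200	105864259	
IGHJ5	J	chr14	105863600	105863659	
IGHJ6	J	chr14	105863000	105863059	
IGHM	CONSTANT	chr14	105849000	105856999	0
IGHD	CONSTANT	chr14	105838000	105845999	0
IGHG3	CONSTANT	chr14	105766000	105773999	1
IGHG1	CONSTANT	chr14	105736000	105743999	2
IGHA1	CONSTANT	chr14	105703000	105710999	3
IGHG2	CONSTANT	chr14	105627000	105634999	4
IGHG4	CONSTANT	chr14	105613000	105620999	5
IGHE	CONSTANT	chr14	105592000	105599999	6
IGHA2	CONSTANT	chr14	105580000	105587999	7
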