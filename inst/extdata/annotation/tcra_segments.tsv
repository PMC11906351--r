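name	kind	chrom	start	end	switch_order
TRAV1-1	V	chr14	21700000	21700499	
TRAV1-2	V	chr14	21718750	21719249	
TRAV2	V	chr14	21737500	21737999	
TRAV3	V	chr14	21756250	21756749	
TRAV4	V	chr14	21775000	21775499	
TRAV5	V	chr14	21793750	21794249	
TRAV6	V	chr14	21812500	21812999	
TRAV7	V	chr14	21831250	21831749	
TRAV8-1	V	chr14	21850000	21850499	
TRAV8-2	V	chr14	21868750	21869249	
TRAV8-3	V	chr14	21887500	21887999	
TRAV8-4	V	chr14	21906250	21906749	
TRAV8-6	V	chr14	21925000	21925499	
TRAV9-1	V	chr14	21943750	21944249	
TRAV9-2	V	chr14	21962500	21962999	
TRAV10	V	chr14	21981250	21981749	
TRAV12-1	V	chr14	22000000	22000499	
TRAV12-2	V	chr14	22018750	22019249	
TRAV12-3	V	chr14	22037500	22037999	
TRAV13-1	V	chr14	22056250	22056749	
TRAV13-2	V	chr14	22075000	22075499	
TRAV14DV4	V	chr14	22093750	22094249	
TRAV16	V	chr14	22112500	22112999	
TRAV17	V	chr14	22131250	22131749	
TRAV18	V	chr14	22150000	22150499	
TRAV19	V	chr14	22168750	22169249	
TRAV20	V	chr14	22187500	22187999	
TRAV21	V	chr14	22206250	22206749	
TRAV22	V	chr14	22225000	22225499	
TRAV23DV6	V	chr14	22243750	22244249	
TRAV24	V	chr14	22262500	22262999	
TRAV25	V	chr14	22281250	22281749	
TRAV26-1	V	chr14	22300000	22300499	
TRAV26-2	V	chr14	22318750	22319249	
TRAV27	V	chr14	22337500	22337999	
TRAV29DV5	V	chr14	22356250	22356749	
TRAV30	V	chr14	22375000	22375499	
TRAV34	V	chr14	22393750	22394249	
TRAV35	V	chr14	22412500	22412999	
TRAV36DV7	V	chr14	22431250	22431749	
TRAJ61	J	chr14	22480000	22480059	
TRAJ58	J	chr14	22484200	22484259	
TRAJ57	J	chr14	22488400	22488459	
TRAJ56	J	chr14	22492600	22492659	
TRAJ54	J	chr14	22496800	22496859	
TRAJ53	J	chr14	22501000	22501059	
TRAJ52	J	chr14	22505200	22505259	
TRAJ50	J	chr14	22509400	22509459	
TRAJ49	J	chr14	22513600	22513659	
TRAJ48	J	chr14	22517800	22517859	
TRAJ47	J	chr14	22522000	22522059	
TRAJ45	J	chr14	22526200	22526259	
TRAJ44	J	chr14	22530400	22530459	
TRAJ43	J	chr14	22534600	22534659	
TRAJ42	J	chr14	22538800	22538859	
TRAJ40	J	chr14	22543000	22543059	
TRAJ39	J	chr14	22547200	22547259	
TRAJ38	J	chr14	22551400	22551459	
TRAJ37	J	chr14	22555600	22555659	
TRAJ36	J	chr14	22559800	22559859	
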