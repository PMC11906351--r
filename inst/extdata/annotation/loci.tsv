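locus	chrom	span_start	span_end	orientation	cn_proxy_gene	segment_file
TCRA	chr14	21621904	22752132	forward	OR10G3	tcra_segments.tsv
TCRB	chr7	142299011	142813287	forward	PRSS58	tcrb_segments.tsv
TCRG	chr7	38240024	38368055	reverse	STARD3NL	tcrg_segments.tsv
IGH	chr14	105566277	106879844	reverse	TMEM121	igh_segments.tsv
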