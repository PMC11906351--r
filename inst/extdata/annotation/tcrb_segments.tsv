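name	kind	chrom	start	end	switch_order
TRBV2	V	chr7	142360000	142360499	
TRBV3-1	V	chr7	142371000	142371499	
TRBV4-1	V	chr7	142382000	142382499	
TRBV4-2	V	chr7	142393000	142393499	
TRBV5-1	V	chr7	142404000	142404499	
TRBV5-4	V	chr7	142415000	142415499	
TRBV5-5	V	chr7	142426000	142426499	
TRBV5-6	V	chr7	142437000	142437499	
TRBV5-8	V	chr7	142448000	142448499	
TRBV6-1	V	chr7	142459000	142459499	
TRBV6-2	V	chr7	142470000	142470499	
TRBV6-4	V	chr7	142481000	142481499	
TRBV6-5	V	chr7	142492000	142492499	
TRBV6-6	V	chr7	142503000	142503499	
TRBV7-2	V	chr7	142514000	142514499	
TRBV7-3	V	chr7	142525000	142525499	
TRBV7-4	V	chr7	142536000	142536499	
TRBV7-6	V	chr7	142547000	142547499	
TRBV7-7	V	chr7	142558000	142558499	
TRBV7-8	V	chr7	142569000	142569499	
TRBV7-9	V	chr7	142580000	142580499	
TRBV9	V	chr7	142591000	142591499	
TRBV10-1	V	chr7	142602000	142602499	
TRBV10-2	V	chr7	142613000	142613499	
TRBV10-3	V	chr7	142624000	142624499	
TRBV11-1	V	chr7	142635000	142635499	
TRBV11-2	V	chr7	142646000	142646499	
TRBV11-3	V	chr7	142657000	142657499	
TRBV12-3	V	chr7	142668000	142668499	
TRBV12-5	V	chr7	142679000	142679499	
TRBD1	D	chr7	142700500	142700512	
TRBD2	D	chr7	142707000	142707016	
TRBJ1-1	J	chr7	142710000	142710049	
TRBJ1-2	J	chr7	142712700	142712749	
TRBJ1-3	J	chr7	142715400	142715449	
TRBJ1-4	J	chr7	142718100	142718149	
TRBJ1-5	J	chr7	142720800	142720849	
TRBJ1-6	J	chr7	142723500	142723549	
TRBJ2-1	J	chr7	142726200	142726249	
TRBJ2-2	J	chr7	142728900	142728949	
TRBJ2-3	J	chr7	142731600	142731649	
TRBJ2-4	J	chr7	142734300	142734349	
TRBJ2-5	J	chr7	142737000	142737049	
TRBJ2-6	J	chr7	142739700	142739749	
TRBJ2-7	J	chr7	142742400	142742449	
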