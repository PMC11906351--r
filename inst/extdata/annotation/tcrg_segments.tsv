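name	kind	chrom	start	end	switch_order
TRGV9	V	chr7	38340000	38340499	
TRGV8	V	chr7	38332000	38332499	
TRGV5	V	chr7	38324000	38324499	
TRGV4	V	chr7	38316000	38316499	
TRGV3	V	chr7	38308000	38308499	
TRGV2	V	chr7	38300000	38300499	
TRGV10	V	chr7	38292000	38292499	
TRGV11	V	chr7	38284000	38284499	
TRGJP1	J	chr7	38272000	38272059	
TRGJP	J	chr7	38268500	38268559	
TRGJ1	J	chr7	38265000	38265059	
TRGJ2	J	chr7	38261500	38261559	
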