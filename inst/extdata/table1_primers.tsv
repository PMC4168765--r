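name	species	transcript	role	sequence	template	binding_start	binding_end	expected_product_bp
hIL18R1_F	human	IL18R1	forward	ACGCCGAGTTTGAAGATCAGGGGT	NM_003855.2	545	568	687
hIL18R1_R	human	IL18R1	reverse	CCCTGGGCAAAATCTCCACAGCA	NM_003855.2	1209	1231	687
hIL18R1_typeII_F	human	IL18R1 type II	forward	ACGCCGAGTTTGAAGATCAGGGGT	NM_003855.2	545	568	874
hIL18R1_typeII_R	human	IL18R1 type II	reverse	ATACAGTTCCTGGGCCCGAGCA	chr2_hg19	103006939	103006960	874
rIl18r1_typeII_F	rat	Il18r1 type II	forward	CCAACGAAGAAGCCACAGACA	NM_001106905.2	1269	1289	463
rIl18r1_typeII_R	rat	Il18r1 type II	reverse	AGCACGGGACATGTGAGGAGA	AC_000077.1	40496516	40496536	463
rActb_F	rat	Actb	forward	TACAACCTTCTTGCAGCTCCTCCG	NM_031144.2	28	51	649
rActb_R	rat	Actb	reverse	TGTAGCCACGCTCGGTCAGG	NM_031144.2	657	676	649
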