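# Subject demographics and co-alterations for the reference cohort
sample_id	age	sex	race	smoking	stage	dna_data	co_alterations
S01	63	male	White	current_or_former	IV	TRUE	TP53:short_variant;TERT:promoter
S02	71	male	White	current_or_former	IV	TRUE	CDKN2A:deletion;CDKN2B:deletion
S03	67	male	White	current_or_former	IV	TRUE	TP53:short_variant
S04	55	male	White	current_or_former	IV	TRUE	TP53:short_variant
S05	72	male	White	current_or_former	I	TRUE	CDKN2A:deletion;CDKN2B:deletion
S06	44	male	White	never	II	TRUE	TP53:short_variant
S07	52	female	White	never	IV	TRUE	EGFR:short_variant;NTRK3:fusion
S08	68	male	White	current_or_former	IV	TRUE	TP53:short_variant
S09	46	female	White	never	III	TRUE	PTEN:deletion
S10	35	male	White	current_or_former	IV	TRUE	CDKN2A:deletion;CDKN2B:deletion;TERT:promoter
S11	48	female	White	current_or_former	IV	TRUE	CDKN2A:deletion;CDKN2B:deletion
S12	74	male	White	current_or_former	IV	TRUE	NF1:short_variant
S13	66	male	White	current_or_former	IV	TRUE	TP53:short_variant
S14	60	male	White	current_or_former	IV	TRUE	CDKN2A:deletion;CDKN2B:deletion
S15	50	female	White	never	IV	TRUE	PIK3CA:short_variant
S16	77	male	White	current_or_former	IV	TRUE	TP53:short_variant
S17	58	female	White	current_or_former	IV	TRUE	PIK3CA:short_variant
S18	70	male	White	current_or_former	II	TRUE	TP53:short_variant
S19	62	female	White	never	IV	TRUE	CDKN2A:deletion;CDKN2B:deletion
S20	54	male	White	current_or_former	IV	TRUE	NF1:short_variant
S21	67	male	Black	current_or_former	IV	TRUE	TP53:short_variant;KRAS:short_variant
S22	76	male	Black	current_or_former	III	TRUE	PTEN:deletion
S23	71	male	Black	current_or_former	IV	TRUE	PIK3CA:short_variant
S24	61	female	Black	never	IV	TRUE	TP53:short_variant
S25	78	female	Other	unknown	IV	FALSE	NA
S26	68	male	Other	current_or_former	IV	TRUE	
S27	42	female	unknown	never	unknown	TRUE	CDKN2A:deletion;CDKN2B:deletion
S28	57	female	unknown	current_or_former	unknown	TRUE	
S29	28	male	unknown	unknown	unknown	TRUE	TP53:short_variant
S30	NA	female	unknown	unknown	unknown	FALSE	NA
S31	64	female	unknown	never	unknown	TRUE	CDKN2A:deletion;CDKN2B:deletion
S32	80	male	unknown	unknown	unknown	TRUE	CDKN2A:deletion;MTAP:deletion;TERT:promoter
S33	75	male	unknown	current_or_former	unknown	TRUE	TP53:short_variant
S34	39	female	unknown	current_or_former	unknown	TRUE	
S35	82	male	unknown	unknown	unknown	TRUE	CDKN2A:deletion;MTAP:deletion
S36	69	male	unknown	unknown	unknown	TRUE	NF1:short_variant
S37	73	male	unknown	unknown	unknown	TRUE	PTEN:deletion
S38	82	female	unknown	unknown	unknown	TRUE	TP53:short_variant;TERT:promoter
S39	79	male	unknown	unknown	unknown	TRUE	CDKN2A:deletion;MTAP:deletion
S40	81	male	unknown	unknown	unknown	TRUE	CDKN2A:deletion;MTAP:deletion
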