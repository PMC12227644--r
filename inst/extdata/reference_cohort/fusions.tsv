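# RAS-GEF fusion reference cohort (40 fusions; see MANIFEST.md for provenance)
# junction_encoding=exon
sample_id	tumor_type	gene5	gene3	junction5	junction3	supporting_reads
S01	Melanoma	IQGAP1	RASGRF1	NA	NA	6
S02	Cholangiocarcinoma	OCLN	RASGRF1	NA	NA	6
S03	Gastroesophageal	TMEM87A	RASGRF1	NA	NA	6
S04	NSCLC/lung	PACSIN2	RASGRF1	NA	NA	6
S05	NSCLC/lung	DLG1	RASGRF1	NA	NA	6
S06	NSCLC/lung	RP2	RASGRF1	NA	NA	6
S07	NSCLC/lung	NPTN	RASGRF1	NA	NA	6
S08	NSCLC/lung	PIAS1	RASGRF1	NA	NA	6
S09	Breast	LINGO1	RASGRF1	1	2	6
S10	Melanoma	SYNPART01	RASGRF1	NA	NA	6
S11	Melanoma	SYNPART02	RASGRF1	NA	NA	6
S12	Pancreatic	SYNPART03	RASGRF1	NA	NA	6
S13	Colorectal	SYNPART04	RASGRF1	NA	NA	6
S14	Bladder	SYNPART05	RASGRF1	NA	NA	6
S15	Breast	SYNPART06	RASGRF1	NA	NA	6
S16	Thyroid	SYNPART07	RASGRF1	NA	NA	6
S17	Endometrial	SYNPART08	RASGRF1	NA	NA	6
S18	Colorectal	MSH3	RASGRF2	NA	NA	6
S19	Ovarian	MSH3	RASGRF2	NA	NA	6
S20	Head and neck	MSH3	RASGRF2	NA	NA	6
S21	Pancreatic	MSH3	RASGRF2	NA	NA	6
S22	Prostate	MSH3	RASGRF2	NA	NA	6
S23	Prostate	MSH3	RASGRF2	NA	NA	6
S24	Pancreatic	OCLN	RASGRF2	4	13	6
S25	Pancreatic	OCLN	RASGRF2	4	13	6
S26	Pancreatic	OCLN	RASGRF2	NA	NA	6
S27	Pancreatic	OCLN	RASGRF2	5	20	6
S28	NSCLC/lung	OCLN	RASGRF2	4	13	6
S29	Cholangiocarcinoma	FARP1	RASGRF2	NA	NA	6
S30	Pancreatic	FARP1	RASGRF2	NA	NA	6
S31	Ovarian	SLC4A4	RASGRF2	NA	NA	6
S32	Melanoma	ERBIN	RASGRF2	NA	NA	6
S33	NSCLC/lung	HSPA4	RASGRF2	NA	NA	6
S34	NSCLC/lung	TOM1L2	RASGRF2	NA	NA	6
S35	Prostate	SYNPART09	RASGRF2	NA	NA	6
S36	Prostate	SYNPART10	RASGRF2	NA	NA	6
S37	Prostate	SYNPART11	RASGRF2	NA	NA	6
S38	Melanoma	SYNPART12	RASGRF2	NA	NA	6
S39	Thyroid	SYNPART13	RASGRF2	NA	NA	6
S40	Endometrial	SYNPART14	RASGRF2	NA	NA	6
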