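# Per-partner transmembrane classification carried as transcribed truth
# (the cohort's partner protein sequences are not available, so topology is
# not recomputed from the hydropathy model for this fixture)
partner	tm_class	provenance
IQGAP1	no_tm	transcribed
OCLN	transmembrane_cytoplasmic_endpoint	transcribed
TMEM87A	transmembrane_cytoplasmic_endpoint	transcribed
PACSIN2	no_tm	inferred
DLG1	no_tm	inferred
RP2	no_tm	inferred
NPTN	transmembrane_cytoplasmic_endpoint	inferred
PIAS1	no_tm	inferred
LINGO1	no_tm	transcribed
MSH3	no_tm	inferred
FARP1	no_tm	inferred
SLC4A4	transmembrane_cytoplasmic_endpoint	inferred
ERBIN	no_tm	inferred
HSPA4	no_tm	inferred
TOM1L2	no_tm	inferred
SYNPART01	transmembrane_cytoplasmic_endpoint	synthetic
SYNPART02	transmembrane_cytoplasmic_endpoint	synthetic
SYNPART03	transmembrane_cytoplasmic_endpoint	synthetic
SYNPART04	transmembrane_cytoplasmic_endpoint	synthetic
SYNPART05	no_tm	synthetic
SYNPART06	no_tm	synthetic
SYNPART07	no_tm	synthetic
SYNPART08	no_tm	synthetic
SYNPART09	transmembrane_cytoplasmic_endpoint	synthetic
SYNPART10	no_tm	synthetic
SYNPART11	no_tm	synthetic
SYNPART12	no_tm	synthetic
SYNPART13	no_tm	synthetic
SYNPART14	no_tm	synthetic
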