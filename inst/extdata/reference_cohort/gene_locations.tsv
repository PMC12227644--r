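# Chromosome of each gene in the reference cohort (synthetic partners carry
# assigned chromosomes; see MANIFEST.md)
symbol	chrom
RASGRF1	chr15
RASGRF2	chr5
IQGAP1	chr15
OCLN	chr5
TMEM87A	chr15
PACSIN2	chr22
DLG1	chr3
RP2	chrX
NPTN	chr15
PIAS1	chr15
LINGO1	chr15
MSH3	chr5
FARP1	chr13
SLC4A4	chr4
ERBIN	chr5
HSPA4	chr5
TOM1L2	chr17
SYNPART01	chr15
SYNPART02	chr7
SYNPART03	chr15
SYNPART04	chr2
SYNPART05	chr15
SYNPART06	chr11
SYNPART07	chr8
SYNPART08	chr19
SYNPART09	chr5
SYNPART10	chr5
SYNPART11	chr9
SYNPART12	chr5
SYNPART13	chr12
SYNPART14	chr6
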