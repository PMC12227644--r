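# Reference cohort fixture: provenance

A 40-fusion RAS-GEF fusion cohort (17 RASGRF1, 23 RASGRF2) transcribed from
a published real-world tumor sequencing study. The raw calls live in a
proprietary database, so this fixture reconstructs the cohort from the
published figures, tables and narrative; fields that the publication does
not disclose per record are filled with clearly labelled stand-ins rather
than guesses presented as data.

## Field provenance

| File | Field | Provenance |
| ---- | ----- | ---------- |
| fusions.tsv | gene3 (RASGRF1/RASGRF2 split 17/23) | transcribed |
| fusions.tsv | tumor_type | transcribed where a fusion-tumor pairing is stated (named partners); remaining rows allocated to reproduce the published per-tumor-type totals (8 NSCLC/lung, 7 pancreatic, 5 melanoma, 5 prostate, 13 tumor types overall) |
| fusions.tsv | gene5, named partners | transcribed (IQGAP1, OCLN, TMEM87A, PACSIN2, DLG1, RP2, NPTN, PIAS1, LINGO1, MSH3 x6, OCLN x5, FARP1 x2, SLC4A4, ERBIN, HSPA4, TOM1L2) |
| fusions.tsv | gene5, SYNPART* rows | synthetic placeholder symbols for the partners not named in the text; allocated so partner-recurrence totals match (29 unique partners, 3 recurrent, 13 distinct RASGRF2 partners) |
| fusions.tsv | junction5/junction3 | transcribed for OCLN-RASGRF2 v1 (exon 4 to exon 13), v3 (exon 5 to exon 20) and LINGO1-RASGRF1 (RASGRF1 exon 2); all other rows unavailable (NA) |
| fusions.tsv | supporting_reads | unavailable per record; set to the funnel minimum (6) consistent with every cohort fusion having passed the read-support filter |
| subjects.tsv | age, sex, race, smoking, stage marginals | transcribed (median 67, range 28-82, one unknown age; 26 male; 20/4/2 White/Black/Other with 14 unknown; 8 never / 22 current-or-former / 10 unknown; stage 1/2/2/21 with 14 unknown; the two NSCLC never-smokers are the NPTN and RP2 fusions) |
| subjects.tsv | per-subject assignment of those marginals | reconstructed: any assignment consistent with the published totals |
| subjects.tsv | co_alterations | transcribed totals (13 TP53, 12 with CDKN2A/CDKN2B/MTAP loss, 4 TERT, NF1/PIK3CA/PTEN present; single KRAS G12D in the MSH3-RASGRF2 pancreatic tumor; EGFR exon-19 del + NTRK3 fusion co-occurring with NPTN-RASGRF1; DNA data missing for the FARP1 pancreatic tumor and one OCLN pancreatic tumor); per-subject placement otherwise reconstructed |
| partners.tsv | tm_class | transcribed where stated (OCLN and TMEM87A transmembrane with cytoplasmic endpoint; IQGAP1 no membrane-spanning domains; LINGO1 retains 2 aa, hence no TM in the fusion); inferred from the partner gene's known biology for other named partners; allocated for SYNPART* so that 7/17 RASGRF1 and 7/23 RASGRF2 fusions carry transmembrane partners with cytoplasmic endpoints |
| gene_locations.tsv | chrom | real chromosome for named genes; assigned for SYNPART* so that the intrachromosomal fraction exceeds one half (24/40), as published |

## Not recoverable

Exon-level junctions for most fusions, per-fusion read counts, per-fusion
domain architectures, and the per-tumor-type sequencing denominators are
not recoverable from the published aggregate data; they are marked
NA/unavailable rather than invented.
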