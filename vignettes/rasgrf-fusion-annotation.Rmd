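---
title: "Annotating and classifying RAS-GEF gene fusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying RAS-GEF gene fusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grffuse)
```

## Background

RASGRF1 and RASGRF2 are guanine nucleotide exchange factors (GEFs) that
load RAS with GTP. Their catalytic machinery sits at the C-terminus: the
CDC25 domain catalyzes nucleotide exchange and the adjacent REM domain
binds RAS substrates. The N-terminus carries pleckstrin-homology (PH1),
coiled-coil, IQ, Dbl-homology (DH) and second PH (PH2) domains implicated
in autoinhibition. Chromosomal rearrangements that fuse a 5' partner gene
to the C-terminal portion of a RAS-GEF can produce chimeric proteins with
two distinct routes to constitutive RAS activation:

* **membrane anchoring** — a transmembrane 5' partner that positions the
  CDC25 domain in the cytoplasm brings it next to membrane-bound RAS;
* **loss of autoinhibition** — removal of both the PH1 and DH domains
  activates the cytosolic protein, while loss of PH1 alone does not, and
  the isolated CDC25 domain without REM is inactive in the cytosol.

This package turns raw exon-level fusion calls into structurally
annotated, mechanistically classified records implementing exactly that
model, and validates every stage against synthetic data with
by-construction truth.

## Coordinate model

All internal coordinates are 0-based half-open; GTF input/output converts
at the file boundary. Exon numbering is always re-derived in transcription
order (exon 1 is 5'-most on the coding strand), never trusted from
annotation attributes, because `exon_number` fields are unreliable across
annotation dialects. One canonical transcript per gene drives all
breakpoint arithmetic; it can be pinned per symbol via the `canonical`
argument. The stop codon is counted inside the CDS and translation drops
the terminal stop — one convention, stated once.

## Reading-frame determination

For a fusion retaining exons 1..j5 of the 5' gene and exons j3..n of the
3' gene, the chimera contributes

* `cds5_len` — coding bases from the 5' gene,
* `junction_offset3` — the wild-type CDS offset of the 3' gene's first
  retained coding base,
* `mid_len` — retained non-coding bases between the two CDS segments
  (3' UTR carried over from the 5' gene plus 5' UTR of the 3' gene; zero
  for the usual junction inside both CDSs).

The fusion is in frame iff
`(cds5_len + mid_len) mod 3 == junction_offset3 mod 3`. Two decisions
resolve cases the phase rule alone does not cover:

* a 5' gene contributing only UTR yields a translatable chimera only when
  the 3' gene's own start codon is retained; such records are in frame
  with translation evaluated from that ATG;
* a junction codon that happens to encode a stop leaves the record in
  frame by phase but flags it `truncating` — codon phase and product
  integrity are separable facts, and the brute-force oracle checks the
  conjunction.

Exon-mode junctions retain junction exons whole. Genomic-coordinate
junctions truncate mid-exon at the breakpoint base (the 5' side keeps its
exon through the breakpoint); a junction falling between exons is flagged
`intronic_endpoint`, but the nearest flanking exon still resolves the
domain breakpoint so the filtering funnel can reject such records at the
coding/exonic stage rather than spuriously at the CDC25 stage.

## Domain retention

Domains are closed 1-based amino-acid intervals classified against the
retained protein segment: `retained` when fully inside, `lost` when fully
outside, `disrupted` otherwise. The funnel's CDC25 requirement accepts
only `retained` — a partially present catalytic domain does not count as
intact. For classification, a disrupted PH1 counts as lost (any
N-terminal truncation into PH1 removes upstream sequence), DH counts as
lost only when fully absent, and REM counts as retained only when fully
present.

The packaged RASGRF1 boundaries are anchored at functionally
characterized truncation points (PH1 ends at residue 139, DH at 422, PH2
at 622, REM at 784, CDC25 from 785 to the 1273-residue C-terminus), so
mapping a breakpoint at each anchor reproduces the corresponding deletion
construct's architecture exactly. For RASGRF2 only the CDC25 start
(residue 825 of 1237) is anchored; the other boundaries are synthetic,
proportioned like RASGRF1's, and a user-supplied domain table (e.g.
transcribed from UniProt) overrides the packaged one. Whether curated
database boundaries or construct-derived ones better reflect any given
cohort is an open question; the construct anchors were chosen because
they reproduce the functional data without external downloads.

## Transmembrane topology

Neural topology predictors are deliberately not wrapped; the package
implements a fully specified classical heuristic instead. Residues whose
centered Kyte–Doolittle window mean exceeds a cutoff are marked; marked
runs separated by at most 3 residues merge; runs of at least
`min_tm_len` residues become TM segments. Defaults — window 19, cutoff
1.6, minimum length 15 — are the classical single-pass membrane-helix
settings: 19 residues spans a bilayer-crossing helix, and 1.6 is the
conventional point where a window is more likely membrane-embedded than
not. The N-terminal compartment defaults to cytoplasmic unless a
signal-peptide-like segment starts at or before residue 10 (then
extracellular); it is overridable per protein. Compartments alternate
across successive segments, so an endpoint after an even number of
retained passes (with a cytoplasmic N-terminus) is cytoplasmic, after an
odd number extracellular. A partner counts as transmembrane only if a
*complete* TM segment lies N-terminal of the fusion endpoint — segments
downstream of the junction are not part of the chimeric protein.

Precomputed topology annotations can be supplied per protein via TSV and
bypass prediction; the packaged reference cohort carries transcribed
partner-TM truth this way, so cohort statistics do not depend on the
heuristic. Lipid-anchor (CAAX-style) membrane targeting is modeled only
as a boolean `forced_membrane` override, not predicted.

## The filtering funnel and transforming-potential classes

Stages run in a fixed order and record the first failure: upstream
artifact pre-mark (an input boolean; the artifact criteria of the
originating assay are proprietary and not modeled) → read support (≥ 6
junction-spanning reads by default) → intact CDC25 → coding 5' gene with
exonic endpoints → in frame. Raising the read threshold can only shrink
the accepted set (a tested monotonicity invariant).

Funnel-passing fusions then receive exactly one class:

| condition | class |
|---|---|
| TM partner with cytoplasmic endpoint, or forced membrane | `membrane_transforming` |
| cytosolic, REM retained, PH1 and DH both lost | `cytosolic_transforming` |
| cytosolic, PH1 lost, DH preserved | `dh_preserved_uncertain` |
| cytosolic, REM not retained | `cdc25_only_uncertain` |
| cytosolic, no N-terminal loss | `dh_preserved_uncertain` |

Two deliberate choices: CDC25-only architectures are "uncertain" only in
the cytosol — with a membrane partner they are transforming, which is why
the membrane test precedes the REM test; and cytosolic REM+CDC25 fusions
*without* N-terminal loss share the `dh_preserved_uncertain` class rather
than receiving a fifth class, since no functional evidence distinguishes
that configuration.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure of a fusion
cohort: exon-structured genes on random strands with planted domain
architectures and transmembrane segments, junctions drawn to hit a target
in-frame fraction, read support, tumor-type frequencies and subject
demographics. Genes are built transcript-first — a protein is drawn,
reverse-translated codon by codon, wrapped in UTRs, split into exons and
placed on its own contig — so frame status, domain statuses, topology and
the chimeric protein are all known by construction, never inferred from
the code under test. The recorded truth is always re-derived from the
transcript bookkeeping, not from the sampling intent, and all randomness
flows through one seeded generator: a fixed seed reproduces every emitted
file byte for byte.

Defaults are one realistic choice made once: 3–7 exons of 90–240 nt,
introns of 60–200 nt, UTRs of 20–60 nt, 95% coding genes, 35% TM
partners with 1–4 planted segments of 25 residues, in-frame target 0.5,
read support uniform on 0–30 (straddling the funnel threshold), tumor
types at roughly the cohort's observed proportions, ages 28–82 and 65%
male.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: splice-site motifs and alternative isoforms
(one transcript per gene), sequencing noise and artifact calls, realistic
amino-acid composition (TM genes use strongly polar backgrounds with
hydrophobic stretches so segment truth is unambiguous; real borderline
helices will be harder), genomic context (each gene sits on its own
contig), and correlated co-alteration structure.

## Validation design

Every stage is checked against an independent oracle rather than against
itself: the frame caller against a translation-suffix brute force (does
the 3' protein suffix appear intact in the translated chimera?), domain
statuses against per-residue membership counts, the hydropathy caller
against a direct sliding-window loop and against planted segments, and
the end-to-end annotator against generator truth on 1000 fusions — all at
100% agreement. The computational analogue of the membrane-disruption
experiment (deleting 5 residues from a planted TM segment abolishes both
the segment call and, in the real protein, membrane localization) is a
fixed deterministic construct: a 25-leucine segment on an aspartate
background loses its call when 5 residues are removed, because no
19-residue window over the remaining 20 hydrophobic residues keeps 15
centers above the cutoff.

Problem sizes used throughout (60 genes, 1000 fusions for the big
validation cohort; 30 genes, 200 fusions for unit-level checks) were
chosen as the package's own trade-off between binomial resolution on the
in-frame fraction and keeping the default test run quick on a laptop.

## Reference cohort fixture

The packaged 40-fusion cohort transcribes a published real-world cohort's
categorical structure: the 17/23 RASGRF1/RASGRF2 split, named recurrent
partners (MSH3, OCLN, FARP1), tumor-type totals, demographics with
unknowns preserved as sentinels (never imputed; the age median excludes
them), co-alteration totals, and per-partner transmembrane status carried
as transcribed truth because the partner protein sequences are not part
of the source. Partners the source does not name are synthetic
placeholders (`SYNPART*`) allocated to reproduce the published aggregate
counts; per-record fields that are not recoverable (most exon junctions,
per-fusion read counts) are `NA` or documented minimums. The fixture's
`MANIFEST.md` records the provenance of every field, and
`load_reference_cohort()` verifies file checksums.

## Known limitations

* One canonical transcript per gene; isoform-level effects are out of
  scope.
* The hydropathy heuristic is a classical approximation — it will miss
  marginally hydrophobic or re-entrant helices that a neural predictor
  calls, and agreement with any specific external predictor is not a
  design goal; supply precomputed topology where fidelity matters.
* Junctions inside the 3' gene's 5' UTR are flagged rather than
  interpreted, since the right biological reading (re-initiation versus
  read-through) is unresolved.
* The funnel starts at read support; upstream artifact filtering must be
  encoded by the caller in the `well_supported` column.
* Fusion discovery itself (from reads) is out of scope: inputs are calls,
  not alignments.
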