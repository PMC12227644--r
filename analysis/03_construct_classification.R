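#!/usr/bin/env Rscript

# Evaluates the N-terminal truncation constructs of RASGRF1/RASGRF2 (and
# CAAX-forced membrane targeting) as pseudo-fusions through the domain
# mapper and the transforming-potential classifier, reproducing the
# structure-function relationships established experimentally: loss of both
# PH1 and DH transforms in the cytosol, loss of PH1 alone does not, the
# isolated CDC25 domain transforms only when membrane-anchored.

suppressMessages(library(grffuse))

dir.create("results", showWarnings = FALSE)
tab <- rasgrf_domain_table()
funnel <- run_funnel("in_frame", TRUE, 10L)

constructs <- data.frame(
  construct = c("RASGRF1_full", "R1_del1-139", "R1_del1-422",
                "R1_del1-622", "R1_del1-784", "RASGRF1_CAAX",
                "R2_del1-824", "OCLN_RASGRF2_v3_like"),
  protein = c(rep("RASGRF1", 6L), "RASGRF2", "RASGRF2"),
  breakpoint_aa = c(1L, 140L, 423L, 623L, 785L, 1L, 825L, 825L),
  topology = c(rep("no_tm", 7L), "transmembrane_cytoplasmic_endpoint"),
  forced_membrane = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                      FALSE),
  stringsAsFactors = FALSE
)

rows <- lapply(seq_len(nrow(constructs)), function(i) {
  cx <- constructs[i, ]
  st <- map_domains(cx$breakpoint_aa, tab, cx$protein)
  cls <- assign_onco_class(funnel, cx$topology, nterm_loss_profile(st),
                           forced_membrane = cx$forced_membrane)
  data.frame(cx, architecture = paste0(st$domain, "=", st$status,
                                       collapse = ";"),
             onco_class = cls)
})
out <- do.call(rbind, rows)
write.table(out, "results/construct_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(out))) {
  message(sprintf("%-22s -> %s", out$construct[i], out$onco_class[i]))
}
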