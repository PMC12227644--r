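test_that("reference cohort aggregates match the published counts", {
  fx <- load_reference_cohort()
  s <- summarize_cohort(fx$fusions, fx$subjects,
                        gene_locations = fx$gene_locations)
  expect_identical(s$n_total, 40L)
  expect_identical(unname(s$n_by_gene["RASGRF1"]), 17L)
  expect_identical(unname(s$n_by_gene["RASGRF2"]), 23L)
  expect_identical(s$n_unique_partners, 29L)
  expect_identical(s$n_recurrent_partners, 3L)
  pr <- partner_recurrence(fx$fusions)
  expect_identical(pr$count[pr$partner == "MSH3"], 6L)
  expect_gt(s$intrachromosomal_fraction, 0.5)
  expect_identical(s$demographics$median_age, 67)
  expect_equal(s$demographics$pct_male, 65)
})

test_that("an empty cohort summarizes to zeros and empty maps", {
  empty <- data.frame(sample_id = character(0), tumor_type = character(0),
                      gene5 = character(0), gene3 = character(0))
  s <- summarize_cohort(empty)
  expect_identical(s$n_total, 0L)
  expect_identical(length(s$n_by_gene), 0L)
  expect_identical(s$n_unique_partners, 0L)
  expect_identical(nrow(s$partner_counts), 0L)
})

test_that("summaries are invariant to input row order and conserve counts", {
  fx <- load_reference_cohort()
  set.seed(31)
  shuf <- fx$fusions[sample(nrow(fx$fusions)), ]
  s1 <- summarize_cohort(fx$fusions, fx$subjects)
  s2 <- summarize_cohort(shuf, fx$subjects)
  expect_identical(s1$n_by_tumor_type, s2$n_by_tumor_type)
  expect_identical(s1$partner_counts, s2$partner_counts)
  expect_identical(s1$demographics, s2$demographics)
  # conservation
  expect_identical(sum(s1$partner_counts$count), s1$n_total)
  expect_identical(sum(s1$n_by_gene), s1$n_total)
  cc <- chromosomal_classes(fx$fusions, fx$gene_locations)
  expect_identical(cc$n_intra + cc$n_extra, s1$n_total)
})

test_that("percentage denominators follow the known-value convention", {
  fx <- load_reference_cohort()
  s <- summarize_cohort(fx$fusions, fx$subjects)
  d <- s$demographics
  # smoking percentages over the 30 subjects with known history
  expect_equal(unname(d$smoking_pct["current_or_former"]), 100 * 22 / 30,
               tolerance = 1e-10)
  expect_equal(unname(d$smoking_pct["never"]), 100 * 8 / 30,
               tolerance = 1e-10)
  # race over 26 known; sex over all 40
  expect_equal(unname(d$race_pct["White"]), 100 * 20 / 26,
               tolerance = 1e-10)
  expect_equal(d$pct_male, 100 * 26 / 40)
  # stage over 26 known
  expect_equal(unname(d$stage_pct["IV"]), 100 * 21 / 26, tolerance = 1e-10)
})

test_that("partner recurrence sorts by count with alphabetical tie-break", {
  rec <- data.frame(gene5 = c("B", "A", "C", "B", "A", "D"),
                    gene3 = "R", tumor_type = "t",
                    sample_id = paste0("s", 1:6))
  pr <- partner_recurrence(rec)
  expect_identical(pr$partner, c("A", "B", "C", "D"))
  expect_identical(pr$count, c(2L, 2L, 1L, 1L))
  one <- partner_recurrence(rec[6L, , drop = FALSE])
  expect_identical(one$count, 1L)
})

test_that("chromosomal classes require locations and split on the 3' gene's chromosome", {
  recs <- data.frame(gene5 = c("MSH3", "FARP1"), gene3 = "RASGRF2")
  loc <- c(MSH3 = "chr5", FARP1 = "chr13", RASGRF2 = "chr5")
  cc <- chromosomal_classes(recs, loc)
  expect_identical(cc$n_intra, 1L)
  expect_identical(cc$n_extra, 1L)
  expect_error(chromosomal_classes(data.frame(gene5 = "X", gene3 = "RASGRF2"),
                                   loc), "no location for gene 'X'")
  arcs <- arc_table(recs, loc)
  expect_identical(sum(arcs$count), 2L)
})

test_that("the co-mutation matrix applies the minimum-altered threshold", {
  fx <- load_reference_cohort()
  m <- comutation_matrix(fx$subjects, min_altered = 3L)
  expect_true("TP53" %in% rownames(m))
  expect_identical(sum(m["TP53", ] == 1L, na.rm = TRUE), 13L)
  expect_identical(sum(m["CDKN2A", ] == 1L, na.rm = TRUE), 12L)
  expect_false("KRAS" %in% rownames(m)) # altered in a single tumor
  # samples without DNA data are carried as all-missing columns
  no_dna <- fx$subjects$sample_id[!fx$subjects$dna_data]
  expect_identical(length(no_dna), 2L)
  expect_true(all(is.na(m[, no_dna])))
  # counting oracle on simulated subjects
  b <- small_bundle()
  m2 <- comutation_matrix(b$subjects, min_altered = 3L)
  per_gene <- table(unlist(lapply(
    b$subjects$co_alterations[b$subjects$dna_data &
                                !is.na(b$subjects$co_alterations)],
    function(x) {
      if (!nzchar(x)) return(character(0))
      vapply(strsplit(x, ";")[[1L]], function(p) strsplit(p, ":")[[1L]][1L],
             "")
    })))
  expect_setequal(rownames(m2), names(per_gene)[per_gene >= 3L])
})

test_that("subject join mismatches are reported with offenders", {
  fx <- load_reference_cohort()
  bad <- fx$fusions
  bad$sample_id[1L] <- "NOT_A_SAMPLE"
  expect_error(summarize_cohort(bad, fx$subjects), "NOT_A_SAMPLE")
})

test_that("tumor-type frequencies appear only when denominators are supplied", {
  fx <- load_reference_cohort()
  s0 <- summarize_cohort(fx$fusions, fx$subjects)
  expect_identical(length(s0$frequency_by_tumor_type), 0L)
  den <- c("Melanoma" = 3300, "NSCLC/lung" = 20000)
  s1 <- summarize_cohort(fx$fusions, fx$subjects, denominators = den)
  expect_equal(unname(s1$frequency_by_tumor_type["Melanoma"]),
               100 * 5 / 3300)
})
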