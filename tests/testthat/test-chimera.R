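# two hand-built coding genes with known phase bookkeeping:
# gene A: exons (8, 10), u5 = 2, CDS = 12 -> exon 1 contributes 6 coding
# bases; gene B: exons (9, 12), u5 = 3, CDS = 15 -> exon 2 starts at CDS
# offset 6
phase_pair <- function(strand5 = "+", strand3 = "+", cds5_extra = 0L) {
  # total CDS length stays 12; shifting the exon boundary changes cds5_len
  a <- make_gene_from_spliced("GA", "cA", strand5,
                              "GGATGAAACCCGGGTTAG",
                              ex_lens = c(8L + cds5_extra,
                                          10L - cds5_extra),
                              u5 = 2L, cds_len = 12L)
  b <- make_gene_from_spliced("GB", "cB", strand3,
                              "CCCATGGTTAAACCCGAATAG",
                              ex_lens = c(9L, 12L), u5 = 3L, cds_len = 18L)
  list(a = a, b = b, seq = c(a$contig, b$contig))
}

test_that("frame status follows codon phase at the junction", {
  pp <- phase_pair()
  ch <- build_chimera(toy_call("GA", "GB", 1L, 2L), pp$a$model, pp$b$model,
                      pp$seq)
  # cds5_len 6, junction_offset3 6: phases match
  expect_identical(ch$cds5_len, 6L)
  expect_identical(ch$junction_offset3, 6L)
  expect_identical(frame_status(ch), "in_frame")

  pp1 <- phase_pair(cds5_extra = 1L) # cds5_len 7: phase mismatch
  ch1 <- build_chimera(toy_call("GA", "GB", 1L, 2L), pp1$a$model,
                       pp1$b$model, pp1$seq)
  expect_identical(ch1$cds5_len, 7L)
  expect_identical(frame_status(ch1), "out_of_frame")
  expect_true(is.na(ch1$protein))
})

test_that("frame verdicts and proteins are invariant under strand placement", {
  ref <- build_chimera(toy_call("GA", "GB", 1L, 2L), phase_pair()$a$model,
                       phase_pair()$b$model, phase_pair()$seq)
  expect_identical(ref$protein, "MKKPE")
  for (s5 in c("+", "-")) for (s3 in c("+", "-")) {
    pp <- phase_pair(strand5 = s5, strand3 = s3)
    ch <- build_chimera(toy_call("GA", "GB", 1L, 2L), pp$a$model,
                        pp$b$model, pp$seq)
    expect_identical(frame_status(ch), "in_frame", info = paste(s5, s3))
    expect_identical(ch$protein, ref$protein, info = paste(s5, s3))
  }
})

test_that("self-splice of a gene's own adjacent exons is the identity", {
  b <- small_bundle()
  g <- Filter(function(g) g$transcripts[[1L]]$coding &&
                nrow(g$transcripts[[1L]]$exons) >= 3L, b$genes)[[1L]]
  ch <- build_chimera(toy_call(g$symbol, g$symbol, 2L, 3L), g, g,
                      b$seq_store)
  expect_identical(ch$fused_cdna,
                   spliced_exons(g$transcripts[[1L]], b$seq_store))
  expect_identical(frame_status(ch), "in_frame")
  expect_false(ch$truncating)
})

test_that("translation starts at the ORF, stops at the first stop, and maps N to X", {
  g1 <- make_gene_from_spliced("TA", "t1", "+", "GGATGAAA", c(8L),
                               u5 = 2L, cds_len = 6L)
  g2 <- make_gene_from_spliced("TB", "t2", "+", "CCCGGGTAGAA",
                               ex_lens = c(4L, 7L), u5 = 0L, cds_len = 9L)
  # CDS of TB: CCCGGGTAG (offsets 0..8); junction at exon 2 -> offset 4?
  # exon 2 starts at transcript pos 4 -> junction_offset3 = 4, phase 1
  ch <- build_chimera(toy_call("TA", "TB", 1L, 2L), g1$model, g2$model,
                      c(g1$contig, g2$contig))
  expect_identical(ch$cds5_len, 6L)
  expect_identical(ch$junction_offset3, 4L)
  expect_identical(frame_status(ch), "out_of_frame")
  expect_error(translate_chimera(ch), "contract violation")

  # in-frame toy whose product is exactly MK: ATG AAA TAG across a junction
  gJ <- make_gene_from_spliced("TC", "t3", "+", "ATGAAA", c(6L),
                               u5 = 0L, cds_len = 6L)
  gK <- make_gene_from_spliced("TD", "t4", "+", "ATGCCCTAGAAG",
                               ex_lens = c(6L, 6L), u5 = 0L, cds_len = 9L)
  chMK <- build_chimera(toy_call("TC", "TD", 1L, 2L), gJ$model, gK$model,
                        c(gJ$contig, gK$contig))
  expect_identical(frame_status(chMK), "in_frame")
  expect_identical(translate_chimera(chMK), "MK")

  # an N inside a retained codon translates to X
  gN <- make_gene_from_spliced("TE", "t5", "+", "ATGCCCANAGGGTAG",
                               ex_lens = c(6L, 9L), u5 = 0L, cds_len = 15L)
  chN <- build_chimera(toy_call("TC", "TE", 1L, 2L), gJ$model, gN$model,
                       c(gJ$contig, gN$contig))
  expect_identical(frame_status(chN), "in_frame")
  expect_identical(translate_chimera(chN), "MKXG")
})

test_that("genomic junctions inside introns are flagged intronic_endpoint", {
  b <- small_bundle()
  g <- Filter(function(g) g$transcripts[[1L]]$coding &&
                nrow(g$transcripts[[1L]]$exons) >= 3L, b$genes)
  g5 <- g[[1L]]; g3 <- g[[2L]]
  t5 <- g5$transcripts[[1L]]
  ex_sorted <- t5$exons[order(t5$exons$start), ]
  intron_pos <- ex_sorted$end[1L] + 2L # between first two genomic exons
  t3 <- g3$transcripts[[1L]]
  exonic3 <- t3$cds$start[1L] + 1L
  ch <- build_chimera(toy_call(g5$symbol, g3$symbol, intron_pos, exonic3,
                               encoding = "genomic"),
                      g5, g3, b$seq_store)
  expect_identical(frame_status(ch), "intronic_endpoint")
})

test_that("mid-exon genomic breakpoints truncate at the breakpoint base", {
  pp <- phase_pair()
  tA <- pp$a$model$transcripts[[1L]]
  # breakpoint at the last base of A's exon 1 reproduces the exon junction
  bp5 <- tA$exons$end[1L] - 1L
  tB <- pp$b$model$transcripts[[1L]]
  bp3 <- tB$exons$start[2L]
  ch <- build_chimera(toy_call("GA", "GB", bp5, bp3, encoding = "genomic"),
                      pp$a$model, pp$b$model, pp$seq)
  chx <- build_chimera(toy_call("GA", "GB", 1L, 2L), pp$a$model, pp$b$model,
                       pp$seq)
  expect_identical(ch$fused_cdna, chx$fused_cdna)
  # one base earlier removes one coding base from the 5' side
  ch2 <- build_chimera(toy_call("GA", "GB", bp5 - 1L, bp3,
                                encoding = "genomic"),
                       pp$a$model, pp$b$model, pp$seq)
  expect_identical(ch2$cds5_len, chx$cds5_len - 1L)
})

test_that("chimeras on simulated fusions reproduce the generator truth", {
  b <- small_bundle()
  for (i in seq_len(nrow(b$calls))) {
    call <- as.list(b$calls[i, ])
    ch <- build_chimera(call, b$genes[[call$gene5]], b$genes[[call$gene3]],
                        b$seq_store)
    expect_identical(frame_status(ch), b$truth$frame_truth[i])
    expect_identical(ch$cds5_len, b$truth$cds5_len[i])
    if (b$truth$frame_truth[i] == "in_frame") {
      expect_identical(ch$protein, b$truth$protein_truth[i])
    }
  }
})

test_that("in-frame chimeras carry the 3' gene's protein suffix verbatim", {
  b <- small_bundle()
  idx <- which(b$truth$frame_truth == "in_frame")[1:40]
  for (i in idx) {
    call <- as.list(b$calls[i, ])
    t3 <- b$genes[[call$gene3]]$transcripts[[1L]]
    ch <- build_chimera(call, b$genes[[call$gene5]], b$genes[[call$gene3]],
                        b$seq_store)
    if (ch$truncating) next
    wt3 <- oracle_wt_protein(t3, b$seq_store)
    off3 <- ch$junction_offset3
    suffix_from <- off3 %/% 3L + 1L + as.integer(off3 %% 3L != 0L)
    expect_true(grepl(substring(wt3, suffix_from), ch$protein, fixed = TRUE))
    # the product reaches at least the chimeric junction residue
    junction_residue <- (ch$cds5_len + ch$mid_len) %/% 3L + 1L
    expect_gte(nchar(ch$protein), junction_residue - 1L)
  }
})
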