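toy_gtf_lines <- function(strand = "+") {
  c(
    sprintf('chrT\ttoy\texon\t11\t25\t.\t%s\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_name "TOY";', strand),
    sprintf('chrT\ttoy\texon\t41\t61\t.\t%s\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_name "TOY";', strand),
    sprintf('chrT\ttoy\texon\t81\t104\t.\t%s\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_name "TOY";', strand)
  )
}

test_that("read_gtf orders exons in transcription order on either strand", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(toy_gtf_lines("+"), f)
  g <- read_gtf(f)[["TOY"]]
  tx <- g$transcripts[[1L]]
  expect_equal(tx$exons$start, c(10L, 40L, 80L)) # 0-based
  expect_equal(tx$exons$end, c(25L, 61L, 104L))
  expect_false(tx$coding)

  writeLines(toy_gtf_lines("-"), f)
  gm <- read_gtf(f)[["TOY"]]
  txm <- gm$transcripts[[1L]]
  # exon 1 on the minus strand is the interval with the largest start
  expect_equal(txm$exons$start[1L], 80L)
  expect_equal(txm$exons$start[3L], 10L)
})

test_that("read_gtf errors carry line numbers and model-integrity checks fire", {
  f <- withr::local_tempfile(fileext = ".gtf")
  bad <- toy_gtf_lines("+")
  bad[2L] <- 'chrT\ttoy\texon\t41\t61\t.\t+\t.\tgene_id "G1";'
  writeLines(bad, f)
  expect_error(read_gtf(f), "missing transcript_id attribute at line 2")

  bad2 <- c(toy_gtf_lines("+"),
            'chrT\ttoy\tCDS\t30\t35\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_name "TOY";')
  writeLines(bad2, f)
  expect_error(read_gtf(f), "model-integrity")
})

test_that("generator-emitted GTF and FASTA round-trip to the truth models", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(sim_params(seed = 11L, n_genes = 10L,
                                  n_fusions = 5L), dir = dir)
  models <- read_gtf(file.path(dir, "genes.gtf"))
  expect_setequal(names(models), names(b$genes))
  for (sym in names(b$genes)) {
    want <- b$genes[[sym]]$transcripts[[1L]]
    got <- models[[sym]]$transcripts[[1L]]
    expect_equal(got$exons, want$exons, info = sym)
    expect_equal(got$cds, want$cds, info = sym)
    expect_identical(got$strand, want$strand, info = sym)
    expect_identical(got$coding, want$coding, info = sym)
  }
  seqs <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(seqs[names(b$seq_store)], b$seq_store)
})

test_that("spliced_cds is strand-symmetric and warns on a non-ATG start", {
  spl <- "GGATGAAATAGTT" # u5=2, CDS=ATGAAATAG, u3=2
  for (st in c("+", "-")) {
    g <- make_gene_from_spliced("A", "c1", st, spl, ex_lens = c(6L, 7L),
                                u5 = 2L, cds_len = 9L)
    expect_identical(spliced_cds(g$model$transcripts[[1L]], g$contig),
                     "ATGAAATAG")
  }
  g2 <- make_gene_from_spliced("B", "c2", "+", "GGAAAAAATAGTT",
                               ex_lens = c(13L), u5 = 2L, cds_len = 9L)
  expect_warning(spliced_cds(g2$model$transcripts[[1L]], g2$contig),
                 "does not begin with ATG")
})

test_that("cds_offset_of matches a base-by-base walk of the spliced CDS", {
  b <- small_bundle()
  set.seed(5)
  coding <- Filter(function(g) g$transcripts[[1L]]$coding, b$genes)
  for (g in coding[1:6]) {
    t <- g$transcripts[[1L]]
    # oracle: enumerate genomic positions of CDS bases in transcription order
    walk <- unlist(lapply(seq_len(nrow(t$cds)), function(i) {
      p <- seq.int(t$cds$start[i], t$cds$end[i] - 1L)
      if (t$strand == "-") rev(p) else p
    }))
    picks <- sample(seq_along(walk), min(60L, length(walk)))
    for (k in picks) {
      expect_identical(cds_offset_of(t, walk[k]), as.integer(k - 1L))
    }
    # intronic and out-of-range behavior
    span <- range(c(t$exons$start, t$exons$end))
    gaps <- setdiff(seq.int(span[1L], span[2L] - 1L),
                    unlist(lapply(seq_len(nrow(t$exons)), function(i)
                      seq.int(t$exons$start[i], t$exons$end[i] - 1L))))
    if (length(gaps)) expect_identical(cds_offset_of(t, gaps[1L]), "intronic")
    expect_error(cds_offset_of(t, span[2L] + 10L), "outside gene span")
  }
})

test_that("cds_offset_of is strictly increasing along transcription order", {
  b <- small_bundle()
  coding <- Filter(function(g) g$transcripts[[1L]]$coding, b$genes)
  for (g in coding[1:4]) {
    t <- g$transcripts[[1L]]
    walk <- unlist(lapply(seq_len(nrow(t$cds)), function(i) {
      p <- seq.int(t$cds$start[i], t$cds$end[i] - 1L)
      if (t$strand == "-") rev(p) else p
    }))
    offs <- vapply(walk, function(p) cds_offset_of(t, p), 0L)
    expect_true(all(diff(offs) == 1L))
  }
})

test_that("protein_coord maps CDS offsets to 1-based residue indices", {
  expect_identical(protein_coord(0L), 1L)
  expect_identical(protein_coord(3L), 2L)
  expect_identical(protein_coord(416L), 139L) # 416 %/% 3 + 1
  expect_error(protein_coord(-1L))
  # last CDS offset lands on len(spliced_cds)/3
  b <- small_bundle()
  g <- Filter(function(g) g$transcripts[[1L]]$coding, b$genes)[[1L]]
  t <- g$transcripts[[1L]]
  clen <- sum(t$cds$end - t$cds$start)
  expect_identical(protein_coord(clen - 1L), clen %/% 3L)
})

test_that("model constructors enforce their invariants", {
  ex <- data.frame(start = c(0L, 50L), end = c(20L, 80L))
  expect_error(transcript_model("t", "c", "+", ex,
                                cds = data.frame(start = 5L, end = 12L)),
               "multiple of 3")
  expect_error(transcript_model("t", "c", "+",
                                data.frame(start = c(0L, 10L),
                                           end = c(20L, 30L))),
               "overlap")
  tx <- transcript_model("t", "c", "+", ex)
  expect_error(gene_model("g", "", "c", "+", list(tx)), "non-empty")
  expect_error(gene_model("g", "S", "c", "-", list(tx)), "chrom/strand")
  expect_error(gene_model("g", "S", "c", "+", list()), "at least one")
})
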