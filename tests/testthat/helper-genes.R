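# Hand construction of a gene model from a spliced transcript string:
# chunks the transcript into exons, interleaves fixed introns and places the
# gene on either strand of its own contig. Independent of the package's
# simulator; used for strand-symmetry and phase fixtures.
make_gene_from_spliced <- function(symbol, chrom, strand, spliced, ex_lens,
                                   u5 = 0L, cds_len = 0L, intron = 30L,
                                   flank = 10L) {
  stopifnot(sum(ex_lens) == nchar(spliced))
  n_ex <- length(ex_lens)
  cum <- cumsum(ex_lens)
  t_starts <- c(0L, cum[-n_ex])
  rand_nt <- function(n) paste(rep("T", n), collapse = "")
  parts <- rand_nt(flank)
  g_starts <- integer(n_ex)
  pos <- flank
  for (k in seq_len(n_ex)) {
    g_starts[k] <- pos
    parts <- paste0(parts, substring(spliced, t_starts[k] + 1L, cum[k]))
    pos <- pos + ex_lens[k]
    if (k < n_ex) {
      parts <- paste0(parts, rand_nt(intron))
      pos <- pos + intron
    }
  }
  parts <- paste0(parts, rand_nt(flank))
  exons <- data.frame(start = g_starts, end = g_starts + ex_lens)
  cds <- NULL
  if (cds_len > 0L) {
    cs <- u5
    ce <- u5 + cds_len
    keep <- list()
    for (k in seq_len(n_ex)) {
      lo <- max(t_starts[k], cs)
      hi <- min(cum[k], ce)
      if (hi > lo) {
        keep[[length(keep) + 1L]] <- data.frame(
          start = g_starts[k] + (lo - t_starts[k]),
          end = g_starts[k] + (hi - t_starts[k]))
      }
    }
    cds <- do.call(rbind, keep)
  }
  contig <- parts
  if (strand == "-") {
    L <- nchar(contig)
    contig <- chartr("ACGTN", "TGCAN", contig)
    contig <- intToUtf8(rev(utf8ToInt(contig)))
    flip <- function(df) data.frame(start = L - df$end, end = L - df$start)
    exons <- flip(exons)
    if (!is.null(cds)) cds <- flip(cds)
  }
  tx <- transcript_model(paste0(symbol, ".t1"), chrom, strand, exons,
                         cds = cds)
  list(model = gene_model(paste0("G_", symbol), symbol, chrom, strand,
                          list(tx)),
       contig = stats::setNames(contig, chrom))
}

# simple exon-mode fusion call for direct build_chimera use
toy_call <- function(gene5, gene3, j5, j3, reads = 10L,
                     encoding = "exon") {
  list(sample_id = "T1", tumor_type = "toy", gene5 = gene5, gene3 = gene3,
       junction5 = j5, junction3 = j3, supporting_reads = reads,
       junction_encoding = encoding)
}

# deterministic occludin-like partner: four 25-residue leucine stretches on
# a strongly polar (aspartate) background, cytoplasmic N-terminus
occludin_like <- function(n_tm = 4L, seg_len = 25L, gap = 30L,
                          nterm = 20L, ctail = 60L) {
  parts <- c(strrep("D", nterm))
  starts <- integer(n_tm)
  pos <- nterm
  for (k in seq_len(n_tm)) {
    starts[k] <- pos + 1L
    parts <- c(parts, strrep("L", seg_len))
    pos <- pos + seg_len
    if (k < n_tm) {
      parts <- c(parts, strrep("D", gap))
      pos <- pos + gap
    }
  }
  parts <- c(parts, strrep("D", ctail))
  list(protein = paste0(parts, collapse = ""),
       segments = data.frame(start = starts, end = starts + seg_len - 1L))
}
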