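# Independent oracles used by the property and acceptance tests. These walk
# sequences and intervals directly and share no arithmetic with the package
# paths they check.

# transcript coordinate of the first CDS base, by walking exons
oracle_tx_pos_of_cds_start <- function(t) {
  first <- if (t$strand == "+") t$cds$start[1L] else t$cds$end[1L] - 1L
  acc <- 0L
  for (i in seq_len(nrow(t$exons))) {
    s <- t$exons$start[i]; e <- t$exons$end[i]
    if (s <= first && first < e) {
      return(acc + if (t$strand == "+") first - s else e - 1L - first)
    }
    acc <- acc + (e - s)
  }
  stop("oracle: CDS start not inside any exon")
}

# wild-type protein of a coding transcript via Biostrings translation
oracle_wt_protein <- function(t, seq_store) {
  cdna <- suppressWarnings(spliced_cds(t, seq_store))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdna)))
  sub("\\*$", "", aa)
}

# Biostrings-based translation of an arbitrary frame, cut at the first stop
oracle_translate <- function(nt, from = 0L) {
  nt <- substring(nt, from + 1L)
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substring(nt, 1L, n)), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) substring(aa, 1L, stop_at - 1L) else aa
}

# Translation-suffix frame oracle: translate the fused cDNA from the
# relevant start codon and ask whether the 3' gene's wild-type protein
# suffix (from its first fully 3'-gene-encoded residue) appears intact
# before any stop. `off3` is the generator's truth junction offset.
oracle_frame_by_suffix <- function(fused_cdna, t5, t3, seq_store, off3,
                                   cds5_len) {
  if (is.na(off3)) return(FALSE)
  wt3 <- oracle_wt_protein(t3, seq_store)
  suffix_from <- off3 %/% 3L + 1L + as.integer(off3 %% 3L != 0L)
  suffix <- substring(wt3, suffix_from)
  if (!nzchar(suffix)) return(FALSE)
  if (cds5_len == 0L) {
    # no 5' coding contribution: translation can only start at the 3'
    # gene's own start codon, which must be retained (off3 == 0); its
    # position inside the fused cDNA follows because the retained 3'
    # segment is a suffix of the wild-type transcript
    if (off3 != 0L) return(FALSE)
    total3 <- sum(t3$exons$end - t3$exons$start)
    orf0 <- nchar(fused_cdna) - total3 + oracle_tx_pos_of_cds_start(t3)
    return(grepl(wt3, oracle_translate(fused_cdna, from = orf0),
                 fixed = TRUE))
  }
  prot <- oracle_translate(fused_cdna, from = oracle_tx_pos_of_cds_start(t5))
  grepl(suffix, prot, fixed = TRUE)
}

# per-residue membership oracle for domain retention of a 3' suffix
oracle_domain_status <- function(start, end, breakpoint_aa, protein_len) {
  residues <- seq.int(start, end)
  inside <- sum(residues >= breakpoint_aa & residues <= protein_len)
  if (inside == length(residues)) "retained"
  else if (inside == 0L) "lost"
  else "disrupted"
}

# direct sliding-window hydropathy oracle (plain loops)
oracle_tm_marked <- function(protein, window = 19L, threshold = 1.6) {
  kd <- kyte_doolittle_scale()
  aa <- strsplit(protein, "")[[1L]]
  h <- unname(kd[aa]); h[is.na(h)] <- 0
  n <- length(h)
  half <- (window - 1L) %/% 2L
  marked <- integer(0)
  for (i in seq_len(n)) {
    if (i - half < 1L || i + half > n) next
    if (mean(h[(i - half):(i + half)]) > threshold) marked <- c(marked, i)
  }
  marked
}
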