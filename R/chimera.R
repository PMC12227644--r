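#' Chimeric transcripts and reading-frame status
#'
#' [build_chimera()] assembles the fused cDNA for one fusion call and
#' computes the quantities that decide reading-frame status:
#'
#' * `cds5_len` - coding bases contributed by the 5' gene up to and including
#'   its junction exon's last retained CDS base;
#' * `junction_offset3` - 0-based CDS offset, in the wild-type 3' gene, of
#'   the first retained coding base;
#' * `mid_len` - retained non-coding bases sitting between the two (3' UTR
#'   carried over from the 5' gene plus 5' UTR of the 3' gene); zero for the
#'   usual junction inside both CDSs.
#'
#' The fusion is in frame when the chimeric offset of the 3' gene's first
#' retained coding base matches its wild-type codon phase:
#' `(cds5_len + mid_len) mod 3 == junction_offset3 mod 3`.
#'
#' Junction exons are retained whole in exon mode; genomic-coordinate
#' junctions truncate at the breakpoint base (the 5' side keeps its exon up
#' to and including the breakpoint). A genomic junction falling between
#' exons yields `frame_status = "intronic_endpoint"`; the nearest flanking
#' exon boundary still determines the domain breakpoint so that downstream
#' filters can report the correct rejection stage. A chimera whose junction
#' codon happens to encode a stop is still in frame by phase but flagged
#' `truncating`: codon phase and product integrity are separable facts.
#'
#' @name chimera
NULL

# standard genetic code as a fast lookup (Biostrings' table, cached)
.gc_env <- new.env(parent = emptyenv())
.genetic_code <- function() {
  if (is.null(.gc_env$tab)) .gc_env$tab <- Biostrings::GENETIC_CODE
  .gc_env$tab
}

# translate to the first stop; codons containing N/ambiguity become X
.translate_to_stop <- function(nt, from = 0L) {
  nt <- substring(nt, from + 1L)
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n, 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste0(aa, collapse = "")
}

# retained genomic intervals (transcription order) for the 5' side of a
# fusion: everything from exon 1 through the junction. Returns
# list(intervals, intronic).
.retained5 <- function(t, junction, mode) {
  if (mode == "exon") {
    j <- as.integer(junction)
    if (is.na(j) || j < 1L || j > nrow(t$exons)) {
      stop("build_chimera: 5' junction exon ", junction,
           " out of range (transcript has ", nrow(t$exons), " exons)")
    }
    return(list(intervals = t$exons[seq_len(j), , drop = FALSE],
                intronic = FALSE))
  }
  pos <- as.integer(junction)
  hit <- which(t$exons$start <= pos & pos < t$exons$end)
  if (length(hit) == 0L) {
    keep <- if (t$strand == "+") t$exons$end <= pos else t$exons$start > pos
    return(list(intervals = t$exons[keep, , drop = FALSE], intronic = TRUE))
  }
  kept <- if (hit > 1L) t$exons[seq_len(hit - 1L), , drop = FALSE] else
    t$exons[0L, , drop = FALSE]
  part <- if (t$strand == "+") {
    data.frame(start = t$exons$start[hit], end = pos + 1L)
  } else {
    data.frame(start = pos, end = t$exons$end[hit])
  }
  list(intervals = rbind(kept, part), intronic = FALSE)
}

# retained genomic intervals for the 3' side: junction through the last exon
.retained3 <- function(t, junction, mode) {
  n <- nrow(t$exons)
  if (mode == "exon") {
    j <- as.integer(junction)
    if (is.na(j) || j < 1L || j > n) {
      stop("build_chimera: 3' junction exon ", junction,
           " out of range (transcript has ", n, " exons)")
    }
    return(list(intervals = t$exons[seq(j, n), , drop = FALSE],
                intronic = FALSE))
  }
  pos <- as.integer(junction)
  hit <- which(t$exons$start <= pos & pos < t$exons$end)
  if (length(hit) == 0L) {
    keep <- if (t$strand == "+") t$exons$start > pos else t$exons$end <= pos
    return(list(intervals = t$exons[keep, , drop = FALSE], intronic = TRUE))
  }
  part <- if (t$strand == "+") {
    data.frame(start = pos, end = t$exons$end[hit])
  } else {
    data.frame(start = t$exons$start[hit], end = pos + 1L)
  }
  rest <- if (hit < n) t$exons[seq(hit + 1L, n), , drop = FALSE] else
    t$exons[0L, , drop = FALSE]
  list(intervals = rbind(part, rest), intronic = FALSE)
}

# bases of `intervals` overlapping `targets` (both genomic, half-open)
.overlap_len <- function(intervals, targets) {
  if (is.null(intervals) || nrow(intervals) == 0L || nrow(targets) == 0L) {
    return(0L)
  }
  tot <- 0L
  for (i in seq_len(nrow(targets))) {
    ov <- pmin(targets$end[i], intervals$end) -
      pmax(targets$start[i], intervals$start)
    tot <- tot + sum(pmax(ov, 0L))
  }
  as.integer(tot)
}

# bases of `intervals` strictly 5' (transcription order) of genomic point
# `cut` on the given strand; `after = TRUE` counts bases 3' of the point
.bases_beyond <- function(intervals, cut, strand, after = FALSE) {
  if (nrow(intervals) == 0L) return(0L)
  count_lower <- xor(after, strand == "+") # count bases with genomic < cut
  if (count_lower) {
    as.integer(sum(pmax(pmin(intervals$end, cut) - intervals$start, 0L)))
  } else {
    as.integer(sum(pmax(intervals$end - pmax(intervals$start, cut), 0L)))
  }
}

#' Build the chimeric transcript for a fusion call
#'
#' @param call one fusion call: a list or one-row data.frame with fields
#'   `gene5`, `gene3`, `junction5`, `junction3` and optionally
#'   `junction_encoding` (`"exon"`, the default, or `"genomic"`).
#' @param g5,g3 `gene_model`s for the 5' and 3' genes.
#' @param seq_store named character vector of contig sequences.
#' @param canonical optional named map `symbol -> transcript_id` selecting
#'   the canonical transcript of each gene.
#' @return an object of class `chimeric_transcript` with fields `call`,
#'   `fused_cdna`, `cds5_len`, `junction_offset3`, `mid_len`, `utr5_len`,
#'   `orf_start`, `frame_status`, `protein` (or `NA`), `truncating`,
#'   `breakpoint_aa3` (1-based index of the first 3'-gene-derived residue in
#'   wild-type protein coordinates) and `endpoint_aa5` (last retained residue
#'   of the 5' partner protein).
#' @seealso [frame_status()], [translate_chimera()]
#' @export
build_chimera <- function(call, g5, g3, seq_store, canonical = NULL) {
  call <- as.list(call)
  mode <- call$junction_encoding
  if (is.null(mode) || is.na(mode)) mode <- "exon"
  t5 <- canonical_transcript(g5, canonical)
  t3 <- canonical_transcript(g3, canonical)

  side5 <- .retained5(t5, call$junction5, mode)
  side3 <- .retained3(t3, call$junction3, mode)
  r5 <- side5$intervals
  r3 <- side3$intervals
  intronic <- side5$intronic || side3$intronic

  out <- list(call = call, fused_cdna = NA_character_, cds5_len = 0L,
              junction_offset3 = NA_integer_, mid_len = 0L, utr5_len = 0L,
              orf_start = NA_integer_, frame_status = NA_character_,
              protein = NA_character_, truncating = FALSE,
              breakpoint_aa3 = NA_integer_, endpoint_aa5 = 0L)
  class(out) <- "chimeric_transcript"

  seq5 <- if (nrow(r5)) paste0(vapply(seq_len(nrow(r5)), function(i) {
    .fetch_seq(seq_store, t5$chrom, r5$start[i], r5$end[i],
               revcomp = (t5$strand == "-"))
  }, character(1L)), collapse = "") else ""
  seq3 <- if (nrow(r3)) paste0(vapply(seq_len(nrow(r3)), function(i) {
    .fetch_seq(seq_store, t3$chrom, r3$start[i], r3$end[i],
               revcomp = (t3$strand == "-"))
  }, character(1L)), collapse = "") else ""
  out$fused_cdna <- paste0(seq5, seq3)
  len5 <- nchar(seq5)

  # 3' side bookkeeping: retained CDS is a suffix of the wild-type CDS
  cds3_total <- sum(t3$cds$end - t3$cds$start)
  cds3_kept <- .overlap_len(r3, t3$cds)
  lead3 <- 0L
  if (cds3_kept > 0L) {
    cds3_first <- if (t3$strand == "+") t3$cds$start[1L] else t3$cds$end[1L]
    lead3 <- .bases_beyond(r3, cds3_first, t3$strand, after = FALSE)
    out$junction_offset3 <- as.integer(cds3_total - cds3_kept)
    out$breakpoint_aa3 <- protein_coord(out$junction_offset3)
  }

  if (!t5$coding) {
    out$utr5_len <- len5
    out$frame_status <- if (intronic) "intronic_endpoint" else
      "noncoding_partner"
    return(out)
  }

  # 5' side bookkeeping
  out$cds5_len <- .overlap_len(r5, t5$cds)
  cds5_first <- if (t5$strand == "+") t5$cds$start[1L] else t5$cds$end[1L]
  cds5_last <- if (t5$strand == "+") t5$cds$end[nrow(t5$cds)] else
    t5$cds$start[nrow(t5$cds)]
  out$utr5_len <- .bases_beyond(r5, cds5_first, t5$strand, after = FALSE)
  trailing5 <- if (out$cds5_len > 0L) {
    .bases_beyond(r5, cds5_last, t5$strand, after = TRUE)
  } else 0L
  out$mid_len <- as.integer(trailing5 + lead3)
  out$endpoint_aa5 <- if (out$cds5_len > 0L)
    as.integer(ceiling(out$cds5_len / 3)) else 0L

  if (intronic) {
    out$frame_status <- "intronic_endpoint"
    return(out)
  }

  if (out$cds5_len == 0L) {
    # 5' gene contributes UTR only: in frame only when the 3' gene keeps its
    # own start codon, from which translation is then evaluated
    if (!is.na(out$junction_offset3) && out$junction_offset3 == 0L) {
      out$frame_status <- "in_frame"
      out$orf_start <- as.integer(len5 + lead3)
    } else {
      out$frame_status <- "out_of_frame"
      return(out)
    }
  } else if (is.na(out$junction_offset3)) {
    out$frame_status <- "out_of_frame"
    return(out)
  } else {
    phase_match <- (out$cds5_len + out$mid_len) %% 3L ==
      out$junction_offset3 %% 3L
    out$frame_status <- if (phase_match) "in_frame" else "out_of_frame"
    out$orf_start <- out$utr5_len
  }

  if (out$frame_status == "in_frame") {
    out$protein <- .translate_to_stop(out$fused_cdna, from = out$orf_start)
    # chimeric CDS offset of the 3' gene's first retained coding base
    pos3 <- if (out$cds5_len > 0L) out$cds5_len + out$mid_len else 0L
    junction_residue <- pos3 %/% 3L + 1L
    out$truncating <- nchar(out$protein) < junction_residue
  }
  out
}

#' Reading-frame status of a chimeric transcript
#'
#' One of `in_frame`, `out_of_frame`, `noncoding_partner` (the 5' gene's
#' canonical transcript is non-coding) or `intronic_endpoint` (a
#' genomic-coordinate junction fell between exons).
#'
#' @param c a `chimeric_transcript` from [build_chimera()].
#' @return character scalar.
#' @export
frame_status <- function(c) {
  stopifnot(inherits(c, "chimeric_transcript"))
  c$frame_status
}

#' Translate an in-frame chimera
#'
#' Standard-code translation from the chimeric ORF start to the first stop;
#' codons containing N translate to X.
#'
#' @param c a `chimeric_transcript` with `frame_status == "in_frame"`.
#' @return amino-acid string.
#' @export
translate_chimera <- function(c) {
  stopifnot(inherits(c, "chimeric_transcript"))
  if (!identical(c$frame_status, "in_frame")) {
    stop("translate_chimera: chimera is not in frame (contract violation)")
  }
  c$protein
}

#' @export
print.chimeric_transcript <- function(x, ...) {
  cat(sprintf("<chimeric_transcript> %s::%s %s, cds5_len=%d, offset3=%s\n",
              x$call$gene5, x$call$gene3, x$frame_status, x$cds5_len,
              ifelse(is.na(x$junction_offset3), "NA", x$junction_offset3)))
  invisible(x)
}
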