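#' Gene and transcript models
#'
#' A `gene_model` is a light container for one gene: identifiers, contig,
#' strand, and one or more `transcript_model`s. All internal coordinates are
#' 0-based half-open; GTF input/output converts at the boundary so interval
#' arithmetic never carries the 1-based closed convention around.
#'
#' @param gene_id gene identifier (string).
#' @param symbol gene symbol (non-empty string).
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of objects created by [transcript_model()].
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol, chrom, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol)) {
    stop("gene_model: 'symbol' must be a non-empty string")
  }
  if (!strand %in% c("+", "-")) stop("gene_model: strand must be '+' or '-'")
  if (length(transcripts) < 1L) {
    stop("gene_model: at least one transcript is required")
  }
  for (t in transcripts) {
    if (!inherits(t, "transcript_model")) {
      stop("gene_model: transcripts must be transcript_model objects")
    }
    if (!identical(t$strand, strand) || !identical(t$chrom, chrom)) {
      stop("gene_model: all transcripts must share the gene's chrom/strand")
    }
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(gene_id = gene_id, symbol = symbol, chrom = chrom, strand = strand,
         transcripts = transcripts),
    class = "gene_model"
  )
}

#' Construct a transcript model
#'
#' Exons and CDS intervals are supplied as two-column data frames
#' (`start`, `end`; 0-based half-open, genomic coordinates). They are stored
#' in transcription order: exon 1 is the 5'-most exon on the coding strand,
#' so on the minus strand it is the interval with the largest genomic start.
#'
#' @param transcript_id transcript identifier.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open).
#' @param cds data.frame of CDS intervals, or `NULL` for a non-coding
#'   transcript. The stop codon is counted inside the CDS; translation drops
#'   the terminal stop.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, cds = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-")) stop("transcript_model: bad strand")
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L || any(exons$end <= exons$start)) {
    stop("transcript_model: exons must be non-empty, end > start")
  }
  exons <- .transcription_order(exons, strand)
  # non-overlap check in genomic order
  g <- exons[order(exons$start), , drop = FALSE]
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
    stop("transcript_model: exons overlap")
  }
  coding <- !is.null(cds) && nrow(as.data.frame(cds)) > 0L
  if (coding) {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds <- .transcription_order(cds, strand)
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1L))
    if (!all(contained)) {
      stop("transcript_model: CDS interval outside any exon (model-integrity error) in '",
           transcript_id, "'")
    }
    clen <- sum(cds$end - cds$start)
    if (clen < 3L || clen %% 3L != 0L) {
      stop("transcript_model: total CDS length must be >= 3 and a multiple of 3 in '",
           transcript_id, "' (got ", clen, ")")
    }
  } else {
    cds <- data.frame(start = integer(0), end = integer(0))
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds, coding = coding),
    class = "transcript_model"
  )
}

# order intervals 5' -> 3' on the coding strand
.transcription_order <- function(df, strand) {
  df <- df[order(df$start, decreasing = (strand == "-")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s, %d transcript(s)\n",
              x$symbol, x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s%s, %d exon(s), %s\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              if (x$coding) "coding" else "non-coding"))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses exon and CDS features for the requested gene symbols (or all genes)
#' and assembles [gene_model()] objects. Exon numbering is always re-derived
#' from the strand rather than trusted from `exon_number` attributes, and
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path path to a GTF 2.2 file (Ensembl attribute dialect: `gene_id`,
#'   `gene_name`, `transcript_id`).
#' @param symbols optional character vector restricting the genes returned
#'   (matched against `gene_name`, falling back to `gene_id`).
#' @return named list of `gene_model`s, keyed by symbol.
#' @export
read_gtf <- function(path, symbols = NULL) {
  if (!file.exists(path)) stop("read_gtf: no such file: ", path)
  # light pre-validation so errors can name the offending line
  raw <- readLines(path, warn = FALSE)
  feat <- !startsWith(raw, "#") & nzchar(raw)
  for (i in which(feat)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) next
    if (!f[3L] %in% c("exon", "CDS")) next
    if (!grepl("gene_id", f[9L], fixed = TRUE)) {
      stop("read_gtf: missing gene_id attribute at line ", i)
    }
    if (!grepl("transcript_id", f[9L], fixed = TRUE)) {
      stop("read_gtf: missing transcript_id attribute at line ", i)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  meta <- S4Vectors::mcols(gr)
  sym <- if ("gene_name" %in% colnames(meta)) {
    ifelse(is.na(meta$gene_name), meta$gene_id, meta$gene_name)
  } else {
    meta$gene_id
  }
  if (!is.null(symbols)) {
    keep <- sym %in% symbols
    gr <- gr[keep]
    meta <- meta[keep, , drop = FALSE]
    sym <- sym[keep]
  }
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    gene_id = meta$gene_id,
    transcript_id = meta$transcript_id,
    symbol = sym,
    stringsAsFactors = FALSE
  )
  out <- list()
  for (gid in unique(df$gene_id)) {
    gd <- df[df$gene_id == gid, , drop = FALSE]
    chrom <- gd$chrom[1L]
    strand <- gd$strand[1L]
    txs <- lapply(unique(gd$transcript_id), function(tid) {
      td <- gd[gd$transcript_id == tid, , drop = FALSE]
      ex <- td[td$type == "exon", c("start", "end"), drop = FALSE]
      cd <- td[td$type == "CDS", c("start", "end"), drop = FALSE]
      transcript_model(tid, chrom, strand, ex,
                       cds = if (nrow(cd)) cd else NULL)
    })
    gm <- gene_model(gid, gd$symbol[1L], chrom, strand, txs)
    out[[gm$symbol]] <- gm
  }
  out
}

#' Canonical transcript of a gene
#'
#' One transcript per gene drives all breakpoint arithmetic. The choice is
#' supplied via `canonical`, a named map `symbol -> transcript_id`; without an
#' entry the gene's first transcript is used.
#'
#' @param g a `gene_model`.
#' @param canonical optional named character vector `symbol -> transcript_id`.
#' @return a `transcript_model`.
#' @export
canonical_transcript <- function(g, canonical = NULL) {
  if (!is.null(canonical) && g$symbol %in% names(canonical)) {
    tid <- canonical[[g$symbol]]
    if (!tid %in% names(g$transcripts)) {
      stop("canonical_transcript: transcript '", tid, "' not found in gene ",
           g$symbol)
    }
    return(g$transcripts[[tid]])
  }
  g$transcripts[[1L]]
}

#' Read genome sequence into a sequence store
#'
#' The sequence store used throughout is a plain named character vector,
#' contig name to nucleotide string (alphabet A/C/G/T/N).
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# reverse-complement without S4 overhead (hot path)
.revcomp_str <- function(x) {
  if (!nzchar(x)) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

# fetch [start, end) of a contig, optionally reverse-complemented
.fetch_seq <- function(seq_store, chrom, start, end, revcomp = FALSE) {
  if (!chrom %in% names(seq_store)) {
    stop("sequence store: contig '", chrom, "' is absent")
  }
  s <- substring(seq_store[[chrom]], start + 1L, end)
  if (revcomp) s <- .revcomp_str(s)
  s
}

#' Spliced CDS sequence of a coding transcript
#'
#' Concatenates the CDS intervals in transcription order,
#' reverse-complementing on the minus strand. Warns (does not fail) when the
#' result does not begin with ATG.
#'
#' @param t a coding `transcript_model`.
#' @param seq_store named character vector of contig sequences.
#' @return nucleotide string; length is a multiple of 3.
#' @export
spliced_cds <- function(t, seq_store) {
  if (!t$coding) stop("spliced_cds: transcript is non-coding")
  parts <- vapply(seq_len(nrow(t$cds)), function(i) {
    .fetch_seq(seq_store, t$chrom, t$cds$start[i], t$cds$end[i],
               revcomp = (t$strand == "-"))
  }, character(1L))
  out <- paste0(parts, collapse = "")
  if (substr(out, 1L, 3L) != "ATG") {
    warning("spliced_cds: CDS of '", t$transcript_id,
            "' does not begin with ATG")
  }
  out
}

#' Spliced exonic (cDNA) sequence of a transcript
#'
#' @inheritParams spliced_cds
#' @return nucleotide string of the full spliced transcript (UTRs included).
#' @export
spliced_exons <- function(t, seq_store) {
  parts <- vapply(seq_len(nrow(t$exons)), function(i) {
    .fetch_seq(seq_store, t$chrom, t$exons$start[i], t$exons$end[i],
               revcomp = (t$strand == "-"))
  }, character(1L))
  paste0(parts, collapse = "")
}

#' CDS offset of a genomic position
#'
#' Counts coding bases 5' to 3' in transcription order on either strand.
#'
#' @param t a `transcript_model`.
#' @param genomic_pos 0-based genomic coordinate within the gene span.
#' @return integer 0-based CDS offset, or `"noncoding"` for exonic positions
#'   outside the CDS, or `"intronic"` for positions between exons.
#' @export
cds_offset_of <- function(t, genomic_pos) {
  span_lo <- min(t$exons$start)
  span_hi <- max(t$exons$end)
  if (genomic_pos < span_lo || genomic_pos >= span_hi) {
    stop("cds_offset_of: position ", genomic_pos,
         " outside gene span [", span_lo, ", ", span_hi, ")")
  }
  in_exon <- any(t$exons$start <= genomic_pos & genomic_pos < t$exons$end)
  if (!in_exon) return("intronic")
  if (!t$coding) return("noncoding")
  hit <- which(t$cds$start <= genomic_pos & genomic_pos < t$cds$end)
  if (length(hit) == 0L) return("noncoding")
  lens <- t$cds$end - t$cds$start
  before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
  within <- if (t$strand == "+") {
    genomic_pos - t$cds$start[hit]
  } else {
    t$cds$end[hit] - 1L - genomic_pos
  }
  as.integer(before + within)
}

#' Protein coordinate of a CDS offset
#'
#' @param cds_offset non-negative 0-based CDS offset.
#' @return 1-based amino-acid index: `floor(cds_offset / 3) + 1`.
#' @export
protein_coord <- function(cds_offset) {
  stopifnot(all(cds_offset >= 0))
  as.integer(cds_offset %/% 3L + 1L)
}

# total retained CDS bases across exons 1..k (transcription order)
.cds_len_in_exons <- function(t, k) {
  if (!t$coding || k < 1L) return(0L)
  ex <- t$exons[seq_len(min(k, nrow(t$exons))), , drop = FALSE]
  tot <- 0L
  for (i in seq_len(nrow(t$cds))) {
    cs <- t$cds$start[i]; ce <- t$cds$end[i]
    ov <- pmin(ce, ex$end) - pmax(cs, ex$start)
    tot <- tot + sum(pmax(ov, 0L))
  }
  as.integer(tot)
}
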