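#' Fusion call input and annotated output
#'
#' Raw fusion calls arrive as tab-separated UTF-8 with a header row and
#' columns `sample_id`, `tumor_type`, `gene5`, `gene3`, `junction5`,
#' `junction3`, `supporting_reads`. Lines starting with `#` are ignored,
#' except that a directive line `#junction_encoding=genomic` (or `=exon`,
#' the default) declares how junction columns are encoded for the whole
#' file. An optional `well_supported` column lets callers pre-mark artifact
#' calls.
#'
#' @name fusion_io
NULL

.fusion_required_cols <- c("sample_id", "tumor_type", "gene5", "gene3",
                           "junction5", "junction3", "supporting_reads")

#' Read raw fusion calls from TSV
#'
#' @param path TSV file path.
#' @return data.frame of fusion calls, one row per record, with attribute
#'   `junction_encoding` (`"exon"` or `"genomic"`) and a
#'   `junction_encoding` column replicated onto every row. Blank tumor
#'   types are recorded as `"unknown"`.
#' @export
read_fusion_calls <- function(path) {
  raw <- readLines(path, warn = FALSE)
  enc <- "exon"
  directive <- grep("^#\\s*junction_encoding\\s*=", raw, value = TRUE)
  if (length(directive)) {
    enc <- trimws(sub("^#\\s*junction_encoding\\s*=", "", directive[1L]))
    if (!enc %in% c("exon", "genomic")) {
      stop("read_fusion_calls: unknown junction_encoding '", enc, "'")
    }
  }
  df <- utils::read.delim(text = raw, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(.fusion_required_cols, names(df))
  if (length(miss)) {
    stop("read_fusion_calls: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  reads <- suppressWarnings(as.integer(df$supporting_reads))
  bad <- which(is.na(reads) & !is.na(df$supporting_reads) &
                 nzchar(df$supporting_reads))
  if (length(bad)) {
    stop("read_fusion_calls: non-integer supporting_reads at data row ",
         bad[1L], " ('", df$supporting_reads[bad[1L]], "')")
  }
  if (any(!is.na(reads) & reads < 0L)) {
    stop("read_fusion_calls: negative supporting_reads")
  }
  df$supporting_reads <- reads
  if (any(df$gene5 == df$gene3)) {
    stop("read_fusion_calls: gene5 == gene3 at data row ",
         which(df$gene5 == df$gene3)[1L])
  }
  df$tumor_type[is.na(df$tumor_type) | !nzchar(df$tumor_type)] <- "unknown"
  if (enc == "exon") {
    df$junction5 <- suppressWarnings(as.integer(df$junction5))
    df$junction3 <- suppressWarnings(as.integer(df$junction3))
  } else {
    df$junction5 <- suppressWarnings(as.numeric(df$junction5))
    df$junction3 <- suppressWarnings(as.numeric(df$junction3))
  }
  if (!"well_supported" %in% names(df)) {
    df$well_supported <- TRUE
  } else {
    df$well_supported <- as.logical(df$well_supported)
  }
  df$junction_encoding <- enc
  attr(df, "junction_encoding") <- enc
  df
}

# stable column order for the annotated schema, with storage types
.annotated_schema <- c(
  sample_id = "character", tumor_type = "character",
  gene5 = "character", gene3 = "character",
  junction5 = "character", junction3 = "character",
  supporting_reads = "integer", junction_encoding = "character",
  frame_status = "character", truncating = "logical",
  breakpoint_aa3 = "integer", endpoint_aa5 = "integer",
  retained_domains = "character", partner_topology = "character",
  well_supported = "logical", read_support_pass = "logical",
  cdc25_pass = "logical", coding_exonic_pass = "logical",
  in_frame_pass = "logical", passed_all = "logical",
  rejection_stage = "character", onco_class = "character",
  chrom_class = "character"
)

#' Write annotated fusions to TSV
#'
#' Columns follow a stable order; [read_annotated()] reproduces all fields
#' bit-exactly.
#'
#' @param records data.frame of annotated fusions (see [annotate_fusions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(records, path) {
  cols <- names(.annotated_schema)
  for (cl in setdiff(cols, names(records))) records[[cl]] <- NA
  records <- records[, cols, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read annotated fusions from TSV
#'
#' @param path TSV written by [write_annotated()].
#' @return data.frame with the annotated schema and its storage types.
#' @export
read_annotated <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  miss <- setdiff(names(.annotated_schema), names(df))
  if (length(miss)) {
    stop("read_annotated: missing column(s): ", paste(miss, collapse = ", "))
  }
  for (cl in names(.annotated_schema)) {
    df[[cl]] <- switch(.annotated_schema[[cl]],
      integer = as.integer(df[[cl]]),
      logical = as.logical(df[[cl]]),
      df[[cl]]
    )
  }
  df
}
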