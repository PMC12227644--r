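#' Protein domain tables and retention mapping
#'
#' A domain table holds named protein domain intervals (1-based, inclusive,
#' amino-acid coordinates) per protein. The packaged RAS-GEF table anchors
#' the RASGRF1 boundaries at the experimentally characterized truncation
#' points (PH1 ends at 139, DH at 422, PH2 at 622, REM at 784, CDC25 runs
#' from 785 to the C-terminus) and the RASGRF2 CDC25 domain at residue 825;
#' the remaining RASGRF2 boundaries are synthetic placeholders scaled to the
#' protein and can be overridden by a user-supplied table.
#'
#' @name domains
NULL

#' Read a protein domain table from TSV
#'
#' Expected columns: `protein`, `domain`, `start`, `end`, and optionally
#' `source`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `protein`, `domain`, `start`, `end`,
#'   `source`.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein", "domain", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_domain_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  validate_domain_table(df)
  df[, c("protein", "domain", "start", "end", "source")]
}

#' Validate a domain table
#'
#' Checks `1 <= start <= end` and that domains of one protein do not overlap
#' (abutting intervals are allowed).
#'
#' @param table domain table data.frame.
#' @return the table, invisibly; errors on violation.
#' @export
validate_domain_table <- function(table) {
  if (any(table$start < 1L) || any(table$end < table$start)) {
    stop("domain table: require 1 <= start <= end")
  }
  for (p in unique(table$protein)) {
    d <- table[table$protein == p, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("domain table: overlapping domains for protein ", p)
    }
  }
  invisible(table)
}

#' Packaged RAS-GEF domain boundary table
#'
#' Domain intervals for RASGRF1 (1273 aa) and RASGRF2 (1237 aa). RASGRF1
#' boundaries are anchored at the truncation points of functionally
#' characterized deletion constructs; for RASGRF2 only the CDC25 start
#' (residue 825) is anchored and the N-terminal boundaries are synthetic,
#' proportioned like RASGRF1's.
#'
#' @return domain table data.frame.
#' @export
rasgrf_domain_table <- function() {
  df <- rbind(
    data.frame(protein = "RASGRF1",
               domain = c("PH1", "CC", "IQ", "DH", "PH2", "REM", "CDC25"),
               start = c(1L, 140L, 166L, 206L, 423L, 623L, 785L),
               end = c(139L, 165L, 205L, 422L, 622L, 784L, 1273L),
               source = c("construct_anchor", "synthetic", "synthetic",
                          "construct_anchor", "construct_anchor",
                          "construct_anchor", "construct_anchor")),
    data.frame(protein = "RASGRF2",
               domain = c("PH1", "CC", "IQ", "DH", "PH2", "REM", "CDC25"),
               start = c(1L, 151L, 181L, 221L, 461L, 651L, 825L),
               end = c(150L, 180L, 220L, 460L, 650L, 824L, 1237L),
               source = c("synthetic", "synthetic", "synthetic", "synthetic",
                          "synthetic", "synthetic", "construct_anchor"))
  )
  validate_domain_table(df)
}

# interval-versus-retained-segment status
.domain_status_one <- function(start, end, seg_lo, seg_hi) {
  if (start >= seg_lo && end <= seg_hi) return("retained")
  if (end < seg_lo || start > seg_hi) return("lost")
  "disrupted"
}

#' Map domain retention onto a chimeric protein
#'
#' Classifies each domain of a protein by interval comparison against the
#' segment of that protein retained in the fusion. For the 3' gene the
#' retained segment is `[breakpoint_aa, protein C-terminus]`; for a 5'
#' partner it is the prefix `[1, endpoint_aa]` (`side = "5prime"`).
#'
#' @param breakpoint_aa 1-based index of the first retained residue (3' gene)
#'   or of the last retained residue (`side = "5prime"`).
#' @param table domain table data.frame.
#' @param protein protein symbol to look up in `table`.
#' @param side `"3prime"` (default) or `"5prime"`.
#' @param protein_length optional protein length; defaults to the largest
#'   domain end for the protein.
#' @return data.frame with columns `domain`, `status`
#'   (`retained`/`lost`/`disrupted`). Empty, with a warning, when the protein
#'   has no entries in `table`.
#' @export
map_domains <- function(breakpoint_aa, table, protein,
                        side = c("3prime", "5prime"),
                        protein_length = NULL) {
  side <- match.arg(side)
  d <- table[table$protein == protein, , drop = FALSE]
  if (nrow(d) == 0L) {
    warning("map_domains: no domain entries for protein ", protein)
    return(data.frame(domain = character(0), status = character(0)))
  }
  if (is.null(protein_length)) protein_length <- max(d$end)
  if (side == "3prime") {
    seg_lo <- breakpoint_aa
    seg_hi <- protein_length
  } else {
    seg_lo <- 1L
    seg_hi <- breakpoint_aa
  }
  status <- vapply(seq_len(nrow(d)), function(i) {
    .domain_status_one(d$start[i], d$end[i], seg_lo, seg_hi)
  }, character(1L))
  data.frame(domain = d$domain, status = status, stringsAsFactors = FALSE)
}

#' Is the catalytic CDC25 domain intact?
#'
#' The filtering funnel requires a fully retained CDC25 domain; a disrupted
#' (partially retained) CDC25 does not count as intact.
#'
#' @param statuses data.frame from [map_domains()].
#' @return logical scalar.
#' @export
cdc25_intact <- function(statuses) {
  hit <- statuses$status[statuses$domain == "CDC25"]
  if (length(hit) == 0L) {
    stop("cdc25_intact: no CDC25 entry in domain statuses ",
         "(every RAS-GEF protein in use must carry one)")
  }
  identical(hit[[1L]], "retained")
}

#' N-terminal loss profile of a fusion
#'
#' Summarizes the autoinhibitory-domain losses that matter for
#' transforming-potential classification. Any truncation into PH1 removes
#' upstream sequence, so a disrupted PH1 counts as lost; DH counts as lost
#' only when fully absent; REM counts as retained only when fully present.
#'
#' @param statuses data.frame from [map_domains()].
#' @return list with logical fields `ph1_lost`, `dh_lost`, `rem_retained`.
#' @export
nterm_loss_profile <- function(statuses) {
  get <- function(name) {
    s <- statuses$status[statuses$domain == name]
    if (length(s)) s[[1L]] else NA_character_
  }
  ph1 <- get("PH1"); dh <- get("DH"); rem <- get("REM")
  list(
    ph1_lost = !is.na(ph1) && ph1 %in% c("lost", "disrupted"),
    dh_lost = !is.na(dh) && identical(dh, "lost"),
    rem_retained = !is.na(rem) && identical(rem, "retained")
  )
}
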