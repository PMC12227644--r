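#' Transmembrane topology of 5' fusion partners
#'
#' Transmembrane segments are called from a Kyte-Doolittle hydropathy
#' profile: every residue whose centered window mean exceeds a cutoff is
#' marked, marked runs separated by small gaps are merged, and runs at least
#' `min_tm_len` residues long become segments. Compartments then alternate
#' across successive segments starting from the N-terminal compartment, so
#' the residue label at the fusion endpoint follows from how many membrane
#' passes lie N-terminal of it. Precomputed topology annotations (e.g.
#' transcribed from an external predictor) can be supplied per protein via
#' TSV and bypass prediction entirely.
#'
#' @name topology
NULL

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector, one value per amino acid (X scores 0).
#' @export
kyte_doolittle_scale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

#' Hydropathy predictor parameters
#'
#' @param window odd window width in residues (default 19, the classical
#'   single-pass transmembrane window).
#' @param threshold mean-hydropathy cutoff marking a residue (default 1.6).
#' @param min_tm_len minimum run length for a segment (default 15).
#' @param gap_merge merge marked runs separated by at most this many
#'   unmarked residues (default 3).
#' @param scale residue-to-hydropathy mapping.
#' @return list of class `hydropathy_params`.
#' @export
hydropathy_params <- function(window = 19L, threshold = 1.6,
                              min_tm_len = 15L, gap_merge = 3L,
                              scale = kyte_doolittle_scale()) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L) {
    stop("hydropathy_params: window must be odd and >= 5")
  }
  if (min_tm_len > window + 6L) {
    stop("hydropathy_params: min_tm_len must be <= window + 6")
  }
  structure(list(window = window, threshold = threshold,
                 min_tm_len = as.integer(min_tm_len),
                 gap_merge = as.integer(gap_merge), scale = scale),
            class = "hydropathy_params")
}

#' Call transmembrane segments from hydropathy
#'
#' @param protein amino-acid string.
#' @param p parameters from [hydropathy_params()].
#' @return data.frame with columns `start`, `end` (1-based inclusive residue
#'   indices), sorted and non-overlapping. Empty, with a warning, when the
#'   sequence is shorter than the window.
#' @export
call_tm_segments <- function(protein, p = hydropathy_params()) {
  n <- nchar(protein)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < p$window) {
    warning("call_tm_segments: sequence shorter than window (", n, " < ",
            p$window, ")")
    return(empty)
  }
  aa <- strsplit(toupper(protein), "")[[1L]]
  h <- unname(p$scale[aa])
  h[is.na(h)] <- 0
  half <- (p$window - 1L) %/% 2L
  cs <- cumsum(c(0, h))
  centers <- seq(half + 1L, n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / p$window
  marked <- centers[means > p$threshold]
  if (length(marked) == 0L) return(empty)
  # maximal runs, then merge across gaps <= gap_merge
  brk <- which(diff(marked) > 1L)
  run_start <- marked[c(1L, brk + 1L)]
  run_end <- marked[c(brk, length(marked))]
  i <- 1L
  while (i < length(run_start)) {
    if (run_start[i + 1L] - run_end[i] - 1L <= p$gap_merge) {
      run_end[i] <- run_end[i + 1L]
      run_start <- run_start[-(i + 1L)]
      run_end <- run_end[-(i + 1L)]
    } else {
      i <- i + 1L
    }
  }
  keep <- (run_end - run_start + 1L) >= p$min_tm_len
  data.frame(start = run_start[keep], end = run_end[keep])
}

#' Topology annotation for one protein
#'
#' @param protein protein symbol.
#' @param tm_segments data.frame with columns `start`, `end`.
#' @param nterm_compartment `"cytoplasmic"` or `"extracellular"`, or `NULL`
#'   to apply the default rule: cytoplasmic unless a signal-peptide-like
#'   segment starts at or before residue 10.
#' @param protein_length total protein length (optional, used for bounds
#'   checks).
#' @return object of class `topology_annotation`.
#' @export
topology_annotation <- function(protein, tm_segments,
                                nterm_compartment = NULL,
                                protein_length = NA_integer_) {
  tm_segments <- as.data.frame(tm_segments)
  if (nrow(tm_segments)) {
    tm_segments <- tm_segments[order(tm_segments$start), , drop = FALSE]
    if (any(tm_segments$end < tm_segments$start)) {
      stop("topology_annotation: segment end < start")
    }
    if (nrow(tm_segments) > 1L &&
        any(tm_segments$start[-1L] <= tm_segments$end[-nrow(tm_segments)])) {
      stop("topology_annotation: overlapping TM segments")
    }
  }
  if (is.null(nterm_compartment)) {
    nterm_compartment <- if (nrow(tm_segments) && tm_segments$start[1L] <= 10L)
      "extracellular" else "cytoplasmic"
  }
  if (!nterm_compartment %in% c("cytoplasmic", "extracellular")) {
    stop("topology_annotation: bad nterm_compartment")
  }
  structure(list(protein = protein, tm_segments = tm_segments,
                 nterm_compartment = nterm_compartment,
                 protein_length = protein_length),
            class = "topology_annotation")
}

#' Predict the topology annotation of a protein sequence
#'
#' @param protein_seq amino-acid string.
#' @param symbol protein symbol carried into the annotation.
#' @param p parameters from [hydropathy_params()].
#' @return a `topology_annotation`.
#' @export
predict_topology <- function(protein_seq, symbol = "protein",
                             p = hydropathy_params()) {
  segs <- call_tm_segments(protein_seq, p)
  topology_annotation(symbol, segs, protein_length = nchar(protein_seq))
}

.flip_compartment <- function(x) {
  if (x == "cytoplasmic") "extracellular" else "cytoplasmic"
}

#' Compartment of a residue under the alternating-topology model
#'
#' @param topo a `topology_annotation`.
#' @param endpoint_aa 1-based residue index (e.g. the fusion junction in the
#'   partner protein).
#' @return `"cytoplasmic"`, `"extracellular"`, or `"membrane"`.
#' @export
endpoint_compartment <- function(topo, endpoint_aa) {
  stopifnot(inherits(topo, "topology_annotation"))
  if (!is.na(topo$protein_length) && endpoint_aa > topo$protein_length) {
    stop("endpoint_compartment: endpoint beyond protein length")
  }
  segs <- topo$tm_segments
  if (nrow(segs) &&
      any(segs$start <= endpoint_aa & endpoint_aa <= segs$end)) {
    return("membrane")
  }
  crossed <- if (nrow(segs)) sum(segs$end < endpoint_aa) else 0L
  label <- topo$nterm_compartment
  if (crossed %% 2L == 1L) label <- .flip_compartment(label)
  label
}

#' Classify a 5' fusion partner by retained transmembrane topology
#'
#' A partner counts as transmembrane only if at least one complete TM
#' segment lies N-terminal of the fusion endpoint (segments downstream of
#' the junction are not part of the chimeric protein). Transmembrane
#' partners split on whether the endpoint residue sits in the cytoplasm.
#'
#' @param topo a `topology_annotation`.
#' @param endpoint_aa 1-based residue index of the fusion junction.
#' @return one of `"transmembrane_cytoplasmic_endpoint"`,
#'   `"transmembrane_noncytoplasmic_endpoint"`, `"no_tm"`.
#' @export
classify_partner <- function(topo, endpoint_aa) {
  stopifnot(inherits(topo, "topology_annotation"))
  segs <- topo$tm_segments
  retained <- if (nrow(segs)) sum(segs$end < endpoint_aa) else 0L
  if (retained == 0L) return("no_tm")
  comp <- endpoint_compartment(topo, endpoint_aa)
  if (comp == "cytoplasmic") "transmembrane_cytoplasmic_endpoint"
  else "transmembrane_noncytoplasmic_endpoint"
}

#' Read precomputed topology annotations from TSV
#'
#' Expected columns: `protein`, `tm_start`, `tm_end` (one row per segment;
#' `NA` for a protein with no segments) and optionally `nterm_compartment`.
#'
#' @param path TSV file path.
#' @return named list of `topology_annotation`s keyed by protein symbol.
#' @export
read_topology_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein", "tm_start", "tm_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_topology_tsv: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- list()
  for (pr in unique(df$protein)) {
    d <- df[df$protein == pr, , drop = FALSE]
    segs <- d[!is.na(d$tm_start), c("tm_start", "tm_end"), drop = FALSE]
    names(segs) <- c("start", "end")
    nterm <- if ("nterm_compartment" %in% names(d) &&
                 !all(is.na(d$nterm_compartment))) {
      d$nterm_compartment[!is.na(d$nterm_compartment)][1L]
    } else NULL
    out[[pr]] <- topology_annotation(pr, segs, nterm_compartment = nterm)
  }
  out
}
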