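#' Candidate-functional filtering funnel
#'
#' Stages are evaluated in a fixed order: upstream artifact pre-mark
#' (`well_supported`), read support (at least `min_reads` junction-spanning
#' reads), intact CDC25 domain, coding 5' gene with exonic endpoints, and
#' preserved reading frame. The first failing stage is recorded; the
#' proprietary artifact-filtering that produced the upstream call set is not
#' modeled, so `well_supported` is an input boolean that defaults to `TRUE`.
#'
#' @param frame_status one of `in_frame`, `out_of_frame`,
#'   `noncoding_partner`, `intronic_endpoint`.
#' @param cdc25_ok logical: is the CDC25 domain fully retained? `NA` is
#'   treated as a failure of the CDC25 stage.
#' @param supporting_reads non-negative integer read count.
#' @param well_supported upstream artifact pre-mark (default `TRUE`).
#' @param min_reads read-support threshold (default 6).
#' @return object of class `funnel_result` with logical stage fields
#'   `well_supported`, `read_support_pass`, `cdc25_pass`,
#'   `coding_exonic_pass`, `in_frame_pass`, plus `passed_all` and
#'   `rejection_stage` (name of the first failed stage, or `NA`).
#' @export
run_funnel <- function(frame_status, cdc25_ok, supporting_reads,
                       well_supported = TRUE, min_reads = 6L) {
  stages <- c(
    well_supported = isTRUE(well_supported),
    read_support_pass = !is.na(supporting_reads) &&
      supporting_reads >= min_reads,
    cdc25_pass = isTRUE(cdc25_ok),
    coding_exonic_pass = !frame_status %in%
      c("noncoding_partner", "intronic_endpoint"),
    in_frame_pass = identical(frame_status, "in_frame")
  )
  first_fail <- which(!stages)
  out <- as.list(stages)
  out$passed_all <- all(stages)
  out$rejection_stage <- if (length(first_fail))
    names(stages)[first_fail[1L]] else NA_character_
  structure(out, class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat(sprintf("<funnel_result> %s\n",
              if (x$passed_all) "passed all stages"
              else paste0("rejected at ", x$rejection_stage)))
  invisible(x)
}

#' Mechanistic transforming-potential class of a fusion
#'
#' Implements the structural model distilled from functional assays of
#' RAS-GEF fusions and truncation constructs:
#'
#' * a fusion that keeps at least the CDC25 domain fused to a transmembrane
#'   partner positioning the catalytic domain in the cytoplasm is
#'   transforming (`membrane_transforming`); a forced membrane anchor (CAAX)
#'   has the same effect;
#' * a cytosolic fusion retaining REM + CDC25 with both PH1 and DH lost is
#'   transforming (`cytosolic_transforming`), consistent with relief of
#'   N-terminal autoinhibition;
#' * a cytosolic fusion losing PH1 but keeping DH has reduced transforming
#'   capacity (`dh_preserved_uncertain`), as does one with no N-terminal
#'   loss at all;
#' * a cytosolic fusion keeping CDC25 without REM is `cdc25_only_uncertain`;
#' * anything rejected by the funnel is `not_candidate`.
#'
#' @param funnel a `funnel_result`.
#' @param topo_class partner topology class from [classify_partner()].
#' @param profile list from [nterm_loss_profile()].
#' @param forced_membrane logical: experimental membrane targeting (CAAX)
#'   override (default `FALSE`).
#' @return one of `membrane_transforming`, `cytosolic_transforming`,
#'   `dh_preserved_uncertain`, `cdc25_only_uncertain`, `not_candidate`.
#' @export
assign_onco_class <- function(funnel, topo_class, profile,
                              forced_membrane = FALSE) {
  stopifnot(inherits(funnel, "funnel_result"))
  if (!funnel$passed_all) return("not_candidate")
  if (identical(topo_class, "transmembrane_cytoplasmic_endpoint") ||
      isTRUE(forced_membrane)) {
    return("membrane_transforming")
  }
  if (profile$rem_retained && profile$ph1_lost && profile$dh_lost) {
    return("cytosolic_transforming")
  }
  if (profile$ph1_lost && !profile$dh_lost) {
    return("dh_preserved_uncertain")
  }
  if (!profile$rem_retained) {
    return("cdc25_only_uncertain")
  }
  "dh_preserved_uncertain"
}
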