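#' Load the packaged reference fusion cohort
#'
#' Returns the transcribed 40-fusion RAS-GEF cohort shipped with the package
#' (fusion calls, subject demographics with co-alterations, per-partner
#' transmembrane classification, and gene chromosome locations). Partner
#' protein sequences are not part of the fixture, so partner transmembrane
#' status is carried as transcribed truth rather than recomputed; symbols
#' prefixed `SYNPART` are synthetic placeholders for partners the source
#' does not name (see the fixture's `MANIFEST.md`).
#'
#' File integrity is verified against packaged MD5 checksums.
#'
#' @return list with elements `fusions` (data.frame of 40 calls),
#'   `subjects` (data.frame of 40 subject records), `partners` (data.frame
#'   with per-partner `tm_class` and provenance) and `gene_locations`
#'   (named character vector `symbol -> chromosome`).
#' @export
load_reference_cohort <- function() {
  dir <- system.file("extdata", "reference_cohort", package = "grffuse")
  if (!nzchar(dir)) stop("load_reference_cohort: fixture directory not found")
  files <- c("fusions.tsv", "subjects.tsv", "partners.tsv",
             "gene_locations.tsv")
  sums <- utils::read.delim(file.path(dir, "checksums.tsv"),
                            stringsAsFactors = FALSE)
  for (f in files) {
    want <- sums$md5[sums$file == f]
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (length(want) != 1L || !identical(want, got)) {
      stop("load_reference_cohort: checksum mismatch for ", f,
           " (integrity error)")
    }
  }
  fusions <- read_fusion_calls(file.path(dir, "fusions.tsv"))
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  partners <- utils::read.delim(file.path(dir, "partners.tsv"),
                                stringsAsFactors = FALSE,
                                comment.char = "#")
  loc <- utils::read.delim(file.path(dir, "gene_locations.tsv"),
                           stringsAsFactors = FALSE, comment.char = "#")
  list(
    fusions = fusions,
    subjects = subjects,
    partners = partners,
    gene_locations = stats::setNames(loc$chrom, loc$symbol)
  )
}

#' Transmembrane-partner fraction of a cohort
#'
#' Fraction (as a percentage) of fusions to one 3' gene whose 5' partner is
#' transmembrane with the fusion endpoint predicted in the cytoplasm.
#'
#' @param fusions fusion call data.frame with columns `gene5`, `gene3`.
#' @param partners data.frame with columns `partner`, `tm_class`.
#' @param gene3 3' gene symbol to restrict to.
#' @return list with `n`, `n_tm`, `pct_tm`.
#' @export
tm_partner_fraction <- function(fusions, partners, gene3) {
  sel <- fusions[fusions$gene3 == gene3, , drop = FALSE]
  cls <- partners$tm_class[match(sel$gene5, partners$partner)]
  if (anyNA(cls)) {
    stop("tm_partner_fraction: partner(s) missing from annotation table: ",
         paste(unique(sel$gene5[is.na(cls)]), collapse = ", "))
  }
  n_tm <- sum(cls == "transmembrane_cytoplasmic_endpoint")
  list(n = nrow(sel), n_tm = n_tm, pct_tm = 100 * n_tm / nrow(sel))
}
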