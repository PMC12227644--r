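#' Cohort-level summarization of annotated fusions
#'
#' Aggregates a fusion cohort into the per-gene, per-tumor-type, per-partner,
#' chromosomal-class and demographic summaries used to describe the cohort.
#' Percentage denominators follow the conventions a demographics table
#' implies: sex percentages use all subjects, while race, smoking and stage
#' percentages use the subjects with known values.
#'
#' @name cohort
NULL

#' Read a subject demographics table from TSV
#'
#' Expected columns: `sample_id`, `age`, `sex`, `race`, `smoking`, `stage`,
#' `dna_data` (logical; subjects without DNA sequencing carry no co-mutation
#' information) and `co_alterations` (semicolon-separated `gene:class`
#' pairs, empty for none). Unknown values are the literal string `unknown`
#' (ages may also be `NA`).
#'
#' @param path TSV file path.
#' @return data.frame of subject records.
#' @export
read_subjects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  need <- c("sample_id", "age", "sex", "race", "smoking", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_subjects: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$age <- suppressWarnings(as.numeric(ifelse(df$age == "unknown", NA,
                                               df$age)))
  if (!"dna_data" %in% names(df)) df$dna_data <- TRUE
  df$dna_data <- as.logical(df$dna_data)
  if (!"co_alterations" %in% names(df)) df$co_alterations <- NA_character_
  df
}

.count_map <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' 5' partner recurrence
#'
#' @param records data.frame of fusion records with a `gene5` column.
#' @return data.frame with columns `partner`, `count`, sorted by descending
#'   count with alphabetical tie-break.
#' @export
partner_recurrence <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(partner = character(0), count = integer(0)))
  }
  cm <- .count_map(records$gene5)
  out <- data.frame(partner = names(cm), count = unname(cm),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intra- versus extrachromosomal fusion classes
#'
#' A fusion is intrachromosomal when its 5' partner lies on the same
#' chromosome as the 3' RAS-GEF gene.
#'
#' @param records data.frame with columns `gene5`, `gene3`.
#' @param gene_locations named character vector `symbol -> chromosome`.
#' @return list with `n_intra`, `n_extra`, `fraction_intra`.
#' @export
chromosomal_classes <- function(records, gene_locations) {
  for (sym in unique(c(records$gene5, records$gene3))) {
    if (!sym %in% names(gene_locations)) {
      stop("chromosomal_classes: no location for gene '", sym, "'")
    }
  }
  intra <- gene_locations[records$gene5] == gene_locations[records$gene3]
  n <- nrow(records)
  list(n_intra = sum(intra), n_extra = sum(!intra),
       fraction_intra = if (n) sum(intra) / n else NA_real_)
}

#' Chromosome-pair arc table for circos-style plots
#'
#' @inheritParams chromosomal_classes
#' @return data.frame with columns `chrom5`, `chrom3`, `count`.
#' @export
arc_table <- function(records, gene_locations) {
  key <- paste(gene_locations[records$gene5], gene_locations[records$gene3],
               sep = "\r")
  cm <- .count_map(key)
  parts <- strsplit(names(cm), "\r", fixed = TRUE)
  out <- data.frame(
    chrom5 = vapply(parts, `[[`, "", 1L),
    chrom3 = vapply(parts, `[[`, "", 2L),
    count = unname(cm), stringsAsFactors = FALSE
  )
  out[order(out$chrom5, out$chrom3), , drop = FALSE]
}

#' Gene-by-sample co-mutation presence matrix
#'
#' @param subjects data.frame from [read_subjects()].
#' @param min_altered genes altered in fewer than this many subjects are
#'   dropped (default 3).
#' @return integer matrix (1 = altered, 0 = not altered, `NA` = no DNA
#'   data), genes in rows sorted by descending alteration count, samples in
#'   columns.
#' @export
comutation_matrix <- function(subjects, min_altered = 3L) {
  genes_per <- lapply(seq_len(nrow(subjects)), function(i) {
    if (!isTRUE(subjects$dna_data[i])) return(NA_character_)
    co <- subjects$co_alterations[i]
    if (is.na(co) || !nzchar(co)) return(character(0))
    vapply(strsplit(co, ";", fixed = TRUE)[[1L]],
           function(x) strsplit(x, ":", fixed = TRUE)[[1L]][1L], "")
  })
  all_genes <- sort(unique(unlist(genes_per[!is.na(genes_per)])))
  if (length(all_genes) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = nrow(subjects),
                  dimnames = list(NULL, subjects$sample_id)))
  }
  m <- matrix(0L, nrow = length(all_genes), ncol = nrow(subjects),
              dimnames = list(all_genes, subjects$sample_id))
  for (i in seq_len(nrow(subjects))) {
    g <- genes_per[[i]]
    if (length(g) == 1L && is.na(g[1L])) {
      m[, i] <- NA_integer_
    } else if (length(g)) {
      m[unique(g), i] <- 1L
    }
  }
  counts <- rowSums(m == 1L, na.rm = TRUE)
  keep <- counts >= min_altered
  m <- m[keep, , drop = FALSE]
  m[order(-counts[keep], rownames(m)), , drop = FALSE]
}

.pct <- function(num, den) if (den > 0L) 100 * num / den else NA_real_

#' Summarize a fusion cohort
#'
#' @param records data.frame of (annotated) fusion records; requires columns
#'   `sample_id`, `tumor_type`, `gene5`, `gene3`.
#' @param subjects data.frame from [read_subjects()], joinable to `records`
#'   by `sample_id`; may be `NULL` to skip demographics.
#' @param gene_locations optional named map `symbol -> chromosome` enabling
#'   the chromosomal-class fractions.
#' @param denominators optional named map `tumor_type -> cohort size`
#'   enabling per-tumor-type fusion frequencies; frequencies are omitted
#'   when absent rather than fabricated.
#' @return list of class `cohort_summary`: `n_total`, `n_by_gene`,
#'   `n_by_tumor_type`, `partner_counts`, `n_unique_partners`,
#'   `n_recurrent_partners`, `intrachromosomal_fraction`,
#'   `frequency_by_tumor_type`, `demographics`.
#' @export
summarize_cohort <- function(records, subjects = NULL,
                             gene_locations = NULL, denominators = NULL) {
  n_total <- nrow(records)
  out <- list(
    n_total = n_total,
    n_by_gene = .count_map(records$gene3),
    n_by_tumor_type = .count_map(records$tumor_type),
    partner_counts = partner_recurrence(records),
    n_unique_partners = length(unique(records$gene5)),
    n_recurrent_partners = 0L,
    intrachromosomal_fraction = NA_real_,
    frequency_by_tumor_type = numeric(0),
    demographics = NULL
  )
  out$n_recurrent_partners <- sum(out$partner_counts$count > 1L)
  if (!is.null(gene_locations) && n_total > 0L) {
    out$intrachromosomal_fraction <-
      chromosomal_classes(records, gene_locations)$fraction_intra
  }
  if (!is.null(denominators) && n_total > 0L) {
    shared <- intersect(names(denominators), names(out$n_by_tumor_type))
    out$frequency_by_tumor_type <- stats::setNames(
      100 * as.numeric(out$n_by_tumor_type[shared]) /
        as.numeric(denominators[shared]),
      shared
    )
  }
  if (!is.null(subjects) && n_total > 0L) {
    missing_ids <- setdiff(records$sample_id, subjects$sample_id)
    if (length(missing_ids)) {
      stop("summarize_cohort: sample_id(s) absent from subjects table: ",
           paste(missing_ids, collapse = ", "))
    }
    sub <- subjects[match(unique(records$sample_id), subjects$sample_id), ,
                    drop = FALSE]
    ages <- sub$age[!is.na(sub$age)]
    n_sub <- nrow(sub)
    n_male <- sum(sub$sex == "male", na.rm = TRUE)
    known <- function(x) x[!is.na(x) & x != "unknown"]
    smoking <- known(sub$smoking)
    race <- known(sub$race)
    stage <- known(sub$stage)
    out$demographics <- list(
      median_age = if (length(ages)) stats::median(ages) else NA_real_,
      age_range = if (length(ages)) range(ages) else c(NA_real_, NA_real_),
      n_age_unknown = sum(is.na(sub$age)),
      n_male = n_male,
      pct_male = .pct(n_male, n_sub),
      smoking_counts = .count_map(smoking),
      smoking_pct = stats::setNames(
        100 * as.numeric(.count_map(smoking)) / length(smoking),
        names(.count_map(smoking))),
      stage_counts = .count_map(stage),
      stage_pct = stats::setNames(
        100 * as.numeric(.count_map(stage)) / length(stage),
        names(.count_map(stage))),
      race_counts = .count_map(race),
      race_pct = stats::setNames(
        100 * as.numeric(.count_map(race)) / length(race),
        names(.count_map(race)))
    )
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d fusions, %d unique 5' partners\n",
              x$n_total, x$n_unique_partners))
  if (length(x$n_by_gene)) {
    cat("  by 3' gene:",
        paste(names(x$n_by_gene), x$n_by_gene, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
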