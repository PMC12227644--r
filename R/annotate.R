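#' Annotate fusion calls end to end
#'
#' Runs the full annotation pipeline over a table of fusion calls: chimeric
#' transcript construction and frame determination, domain-retention mapping
#' on the 3' RAS-GEF gene, transmembrane-topology classification of the 5'
#' partner, the candidate-functional filtering funnel, transforming-potential
#' classification, and chromosomal class.
#'
#' Partner topology comes from `topology` (precomputed annotations, e.g.
#' [read_topology_tsv()]) when the partner is listed there, and otherwise is
#' predicted from the partner's wild-type protein with the hydropathy model.
#'
#' @param calls data.frame from [read_fusion_calls()] (or with the same
#'   columns).
#' @param genes named list of `gene_model`s keyed by symbol (see
#'   [read_gtf()]).
#' @param seq_store named character vector of contig sequences.
#' @param domain_table domain table data.frame (see [rasgrf_domain_table()]).
#' @param topology optional named list of `topology_annotation`s.
#' @param topo_params [hydropathy_params()] used when predicting.
#' @param canonical optional named map `symbol -> transcript_id`.
#' @param min_reads read-support threshold for the funnel (default 6).
#' @param forced_membrane character vector of 5' partner symbols carrying an
#'   experimental membrane anchor (CAAX-style override).
#' @return data.frame, one row per call, in the stable annotated schema
#'   accepted by [write_annotated()].
#' @export
annotate_fusions <- function(calls, genes, seq_store, domain_table,
                             topology = NULL,
                             topo_params = hydropathy_params(),
                             canonical = NULL, min_reads = 6L,
                             forced_membrane = character(0)) {
  n <- nrow(calls)
  rows <- vector("list", n)
  topo_cache <- list()
  for (i in seq_len(n)) {
    call <- as.list(calls[i, , drop = FALSE])
    for (sym in c(call$gene5, call$gene3)) {
      if (!sym %in% names(genes)) {
        stop("annotate_fusions: no gene model for '", sym, "'")
      }
    }
    g5 <- genes[[call$gene5]]
    g3 <- genes[[call$gene3]]
    chim <- build_chimera(call, g5, g3, seq_store, canonical = canonical)

    # domain retention on the 3' gene (evaluable whenever the breakpoint
    # resolves to a coding position, regardless of frame)
    t3 <- canonical_transcript(g3, canonical)
    len3 <- if (t3$coding) sum(t3$cds$end - t3$cds$start) %/% 3L - 1L else
      NA_integer_
    statuses <- if (!is.na(chim$breakpoint_aa3)) {
      map_domains(chim$breakpoint_aa3, domain_table, call$gene3,
                  protein_length = len3)
    } else {
      data.frame(domain = character(0), status = character(0))
    }
    cdc25_ok <- if (nrow(statuses)) cdc25_intact(statuses) else NA
    profile <- nterm_loss_profile(statuses)
    dom_str <- if (nrow(statuses)) {
      paste0(statuses$domain, "=", statuses$status, collapse = ";")
    } else NA_character_

    # partner topology
    t5 <- canonical_transcript(g5, canonical)
    topo <- NULL
    if (!is.null(topology) && call$gene5 %in% names(topology)) {
      topo <- topology[[call$gene5]]
    } else if (t5$coding) {
      if (is.null(topo_cache[[call$gene5]])) {
        prot5 <- .translate_to_stop(spliced_cds(t5, seq_store))
        topo_cache[[call$gene5]] <- suppressWarnings(
          predict_topology(prot5, call$gene5, topo_params)
        )
      }
      topo <- topo_cache[[call$gene5]]
    }
    topo_class <- if (is.null(topo) || chim$endpoint_aa5 == 0L) "no_tm" else
      classify_partner(topo, chim$endpoint_aa5)

    well <- if (!is.null(call$well_supported)) call$well_supported else TRUE
    funnel <- run_funnel(chim$frame_status, cdc25_ok, call$supporting_reads,
                         well_supported = well, min_reads = min_reads)
    onco <- assign_onco_class(funnel, topo_class, profile,
                              forced_membrane = call$gene5 %in% forced_membrane)

    rows[[i]] <- data.frame(
      sample_id = call$sample_id, tumor_type = call$tumor_type,
      gene5 = call$gene5, gene3 = call$gene3,
      junction5 = as.character(call$junction5),
      junction3 = as.character(call$junction3),
      supporting_reads = as.integer(call$supporting_reads),
      junction_encoding = if (is.null(call$junction_encoding)) "exon" else
        call$junction_encoding,
      frame_status = chim$frame_status, truncating = chim$truncating,
      breakpoint_aa3 = chim$breakpoint_aa3,
      endpoint_aa5 = chim$endpoint_aa5,
      retained_domains = dom_str, partner_topology = topo_class,
      well_supported = funnel$well_supported,
      read_support_pass = funnel$read_support_pass,
      cdc25_pass = funnel$cdc25_pass,
      coding_exonic_pass = funnel$coding_exonic_pass,
      in_frame_pass = funnel$in_frame_pass,
      passed_all = funnel$passed_all,
      rejection_stage = funnel$rejection_stage,
      onco_class = onco,
      chrom_class = if (identical(g5$chrom, g3$chrom)) "intrachromosomal"
        else "extrachromosomal",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
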