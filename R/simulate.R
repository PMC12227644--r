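#' Synthetic cohort simulation with known truth
#'
#' [simulate_cohort()] generates a bundle of synthetic genome, gene models,
#' fusion calls, partner topologies and subject demographics in which every
#' downstream quantity - reading-frame status, retained domains, planted
#' transmembrane segments, chimeric protein - is known by construction, so
#' the whole annotation pipeline can be validated without external data.
#' Genes are built transcript-first: a protein is drawn (with transmembrane
#' partners receiving planted hydrophobic stretches on a polar background,
#' so hydropathy segment calls have unambiguous truth), reverse-translated
#' codon by codon, wrapped in UTRs, split into exons, interleaved with
#' introns and placed on its own contig on a random strand. Junction exons
#' for each fusion are chosen so the realized in-frame fraction matches
#' `p_inframe` in expectation, but the recorded truth is always re-derived
#' from the transcript bookkeeping, never from the sampling intent.
#'
#' All randomness flows through one seeded generator, and the emitted files
#' are byte-identical under a fixed seed.
#'
#' @name synthetic_data
NULL

#' Simulation parameters
#'
#' @param seed integer seed fixing the entire bundle.
#' @param n_genes number of synthetic genes.
#' @param n_fusions number of fusion calls to simulate.
#' @param exon_count integer range (min, max) of exons per gene.
#' @param exon_len integer range of exon lengths (nt).
#' @param intron_len integer range of intron lengths (nt).
#' @param utr_len integer range of UTR lengths on each end (nt).
#' @param p_coding probability a gene is protein-coding.
#' @param domain_plan named numeric vector of relative domain spans laid
#'   end-to-end over each coding protein.
#' @param p_tm_partner probability a coding gene carries planted
#'   transmembrane segments.
#' @param n_tm_segments integer range of planted segments per TM gene.
#' @param tm_len length of each planted segment (residues).
#' @param p_inframe target in-frame fraction among simulated fusions.
#' @param read_support integer range of junction-spanning read counts.
#' @param tumor_type_freq named probability vector of tumor types.
#' @param age_range integer range of subject ages.
#' @param p_male probability a subject is male.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_genes = 30L, n_fusions = 200L,
                       exon_count = c(3L, 7L), exon_len = c(90L, 240L),
                       intron_len = c(60L, 200L), utr_len = c(20L, 60L),
                       p_coding = 0.95,
                       domain_plan = c(PH1 = 0.12, DH = 0.22, PH2 = 0.16,
                                       REM = 0.13, CDC25 = 0.37),
                       p_tm_partner = 0.35, n_tm_segments = c(1L, 4L),
                       tm_len = 25L, p_inframe = 0.5,
                       read_support = c(0L, 30L),
                       tumor_type_freq = c("NSCLC/lung" = 0.2,
                                           "Pancreatic" = 0.175,
                                           "Melanoma" = 0.125,
                                           "Prostate" = 0.125,
                                           "Other" = 0.375),
                       age_range = c(28L, 82L), p_male = 0.65) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            n_fusions = as.integer(n_fusions), exon_count = exon_count,
            exon_len = exon_len, intron_len = intron_len, utr_len = utr_len,
            p_coding = p_coding, domain_plan = domain_plan,
            p_tm_partner = p_tm_partner, n_tm_segments = n_tm_segments,
            tm_len = as.integer(tm_len), p_inframe = p_inframe,
            read_support = read_support, tumor_type_freq = tumor_type_freq,
            age_range = age_range, p_male = p_male)
  probs <- c(p_coding, p_tm_partner, p_inframe, p_male, tumor_type_freq)
  if (any(probs < 0) || any(probs > 1)) {
    stop("sim_params: probabilities must lie in [0, 1]")
  }
  for (r in list(exon_count, exon_len, intron_len, utr_len, read_support,
                 age_range, n_tm_segments)) {
    if (length(r) != 2L || any(r < 0) || r[2L] < r[1L]) {
      stop("sim_params: ranges must be non-negative (min, max) pairs")
    }
  }
  if (exon_len[1L] < 3L) {
    stop("sim_params: infeasible range, exon shorter than 3")
  }
  structure(p, class = "sim_params")
}

.polar_aa <- c("D", "E", "N", "Q", "K", "R", "S", "T", "G", "P", "H")
.tm_aa <- c("L", "I", "V")

# synonymous codons per amino acid (stops excluded)
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

.sample_range <- function(r) {
  if (r[1L] == r[2L]) as.integer(r[1L]) else
    sample(seq.int(r[1L], r[2L]), 1L)
}

.random_nt <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) .revcomp_str(x)

# one synthetic gene: protein-first construction (see module docs)
.sim_gene <- function(i, p, codon_tab) {
  symbol <- sprintf("SGENE%03d", i)
  gene_id <- sprintf("SG%03d", i)
  chrom <- sprintf("chrS%03d", i)
  strand <- sample(c("+", "-"), 1L)
  coding <- stats::runif(1L) < p$p_coding
  n_ex <- .sample_range(p$exon_count)
  ex_lens <- vapply(seq_len(n_ex), function(k) .sample_range(p$exon_len),
                    integer(1L))

  tm <- FALSE
  tm_segments <- data.frame(start = integer(0), end = integer(0))
  protein <- NA_character_
  u5 <- u3 <- 0L
  cds_len <- 0L
  if (coding) {
    u5 <- .sample_range(p$utr_len)
    u3 <- .sample_range(p$utr_len)
    cds_len <- sum(ex_lens) - u5 - u3
    cds_len <- cds_len - cds_len %% 3L
    plen <- cds_len %/% 3L - 1L # without terminal stop
    tm <- stats::runif(1L) < p$p_tm_partner
    if (tm) {
      n_tm <- .sample_range(p$n_tm_segments)
      gap <- 30L
      needed <- 20L + n_tm * p$tm_len + (n_tm - 1L) * gap + 5L
      if (plen < needed) {
        extra_aa <- needed - plen
        ex_lens[n_ex] <- ex_lens[n_ex] + 3L * extra_aa
        cds_len <- cds_len + 3L * extra_aa
        plen <- plen + extra_aa
      }
      starts <- 21L + (seq_len(n_tm) - 1L) * (p$tm_len + gap)
      tm_segments <- data.frame(start = starts, end = starts + p$tm_len - 1L)
    }
    if (plen < 10L) {
      extra_aa <- 10L - plen
      ex_lens[n_ex] <- ex_lens[n_ex] + 3L * extra_aa
      cds_len <- cds_len + 3L * extra_aa
      plen <- plen + extra_aa
    }
    aa <- c("M", sample(.polar_aa, plen - 1L, replace = TRUE))
    for (k in seq_len(nrow(tm_segments))) {
      idx <- seq(tm_segments$start[k], tm_segments$end[k])
      aa[idx] <- sample(.tm_aa, length(idx), replace = TRUE)
    }
    protein <- paste0(aa, collapse = "")
    codons <- character(length(aa))
    for (a in unique(aa)) {
      idx <- which(aa == a)
      opts <- codon_tab[[a]]
      codons[idx] <- opts[sample.int(length(opts), length(idx),
                                     replace = TRUE)]
    }
    codons[1L] <- "ATG"
    cds_seq <- paste0(paste0(codons, collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    spliced <- paste0(.random_nt(u5), cds_seq, .random_nt(u3))
  } else {
    spliced <- .random_nt(sum(ex_lens))
  }

  # split spliced transcript into exons, interleave introns, place on contig
  cum <- cumsum(ex_lens)
  t_starts <- c(0L, cum[-n_ex])
  flank <- 25L
  introns <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L), function(k) {
    .sample_range(p$intron_len)
  }, integer(1L)) else integer(0)
  g_starts <- integer(n_ex)
  pos <- flank
  contig_parts <- character(0)
  contig_parts <- c(contig_parts, .random_nt(flank))
  for (k in seq_len(n_ex)) {
    g_starts[k] <- pos
    contig_parts <- c(contig_parts,
                      substring(spliced, t_starts[k] + 1L, cum[k]))
    pos <- pos + ex_lens[k]
    if (k < n_ex) {
      contig_parts <- c(contig_parts, .random_nt(introns[k]))
      pos <- pos + introns[k]
    }
  }
  contig_parts <- c(contig_parts, .random_nt(flank))
  contig <- paste0(contig_parts, collapse = "")
  exons <- data.frame(start = g_starts, end = g_starts + ex_lens)

  # CDS genomic intervals from transcript span [u5, u5 + cds_len)
  cds <- NULL
  if (coding) {
    cs <- u5
    ce <- u5 + cds_len
    keep <- list()
    for (k in seq_len(n_ex)) {
      lo <- max(t_starts[k], cs)
      hi <- min(cum[k], ce)
      if (hi > lo) {
        keep[[length(keep) + 1L]] <- data.frame(
          start = g_starts[k] + (lo - t_starts[k]),
          end = g_starts[k] + (hi - t_starts[k])
        )
      }
    }
    cds <- do.call(rbind, keep)
  }

  if (strand == "-") {
    L <- nchar(contig)
    contig <- .revcomp(contig)
    flip <- function(df) data.frame(start = L - df$end, end = L - df$start)
    exons <- flip(exons)
    if (!is.null(cds)) cds <- flip(cds)
  }

  tx <- transcript_model(paste0(gene_id, ".t1"), chrom, strand, exons,
                         cds = cds)
  gm <- gene_model(gene_id, symbol, chrom, strand, list(tx))

  # domain intervals laid end-to-end over the protein by the domain plan
  domains <- NULL
  if (coding) {
    plen <- cds_len %/% 3L - 1L
    cuts <- round(cumsum(c(0, p$domain_plan)) / sum(p$domain_plan) * plen)
    domains <- data.frame(protein = symbol, domain = names(p$domain_plan),
                          start = as.integer(cuts[-length(cuts)] + 1L),
                          end = as.integer(cuts[-1L]),
                          source = "synthetic")
  }

  list(symbol = symbol, gene_id = gene_id, chrom = chrom, strand = strand,
       coding = coding, model = gm, contig = contig, spliced = spliced,
       ex_lens = ex_lens, t_starts = t_starts, u5 = u5, cds_len = cds_len,
       protein = protein, tm = tm, tm_segments = tm_segments,
       domains = domains)
}

# frame truth for one (gene5, j5, gene3, j3) from transcript bookkeeping;
# the 3' breakpoint is recorded regardless of the 5' gene's coding status
# because domain retention is evaluable (and evaluated) independently
.sim_frame_truth <- function(g5, j5, g3, j3) {
  start3 <- sum(g3$ex_lens[seq_len(j3 - 1L)]) # transcript offset, 0-based
  cds3_kept <- max(0L, min(g3$u5 + g3$cds_len, sum(g3$ex_lens)) -
                     max(start3, g3$u5))
  off3 <- if (cds3_kept > 0L) as.integer(g3$cds_len - cds3_kept) else
    NA_integer_
  if (!g5$coding) {
    return(list(frame = "noncoding_partner", cds5 = 0L, off3 = off3,
                mid = 0L))
  }
  keep5 <- sum(g5$ex_lens[seq_len(j5)])
  cds5 <- max(0L, min(keep5 - g5$u5, g5$cds_len))
  trailing5 <- max(0L, keep5 - (g5$u5 + g5$cds_len))
  if (cds3_kept == 0L) {
    return(list(frame = "out_of_frame", cds5 = cds5, off3 = off3,
                mid = trailing5))
  }
  lead3 <- max(0L, g3$u5 - start3)
  mid <- trailing5 + lead3
  frame <- if (cds5 == 0L) {
    if (off3 == 0L) "in_frame" else "out_of_frame"
  } else if ((cds5 + mid) %% 3L == off3 %% 3L) "in_frame" else "out_of_frame"
  list(frame = frame, cds5 = as.integer(cds5), off3 = off3,
       mid = as.integer(mid))
}

# status of one domain interval against the retained 3' suffix
.sim_domain_status <- function(start, end, bp, plen) {
  if (start >= bp && end <= plen) "retained"
  else if (end < bp) "lost"
  else "disrupted"
}

#' Simulate a synthetic fusion cohort bundle
#'
#' @param p parameters from [sim_params()].
#' @param dir optional directory; when given, the bundle is written as
#'   `genome.fa`, `genes.gtf`, `fusions.tsv`, `topology.tsv`,
#'   `subjects.tsv`, `domains.tsv` and `truth.tsv`.
#' @return list with elements `genes` (named list of `gene_model`s),
#'   `seq_store`, `calls` (fusion call data.frame), `domain_table`,
#'   `topology` (named list of `topology_annotation`s), `subjects`, `truth`
#'   (data.frame of per-fusion truth records) and `params`.
#' @export
simulate_cohort <- function(p, dir = NULL) {
  stopifnot(inherits(p, "sim_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(p$seed)
  codon_tab <- .codons_by_aa()

  genes <- lapply(seq_len(p$n_genes), .sim_gene, p = p,
                  codon_tab = codon_tab)
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  coding_idx <- which(vapply(genes, `[[`, TRUE, "coding"))
  if (length(coding_idx) < 2L) {
    stop("simulate_cohort: need at least two coding genes; raise p_coding")
  }
  seq_store <- vapply(genes, `[[`, "", "contig")
  names(seq_store) <- vapply(genes, `[[`, "", "chrom")
  models <- lapply(genes, `[[`, "model")
  domain_table <- do.call(rbind, Filter(Negate(is.null),
                                        lapply(genes, `[[`, "domains")))
  rownames(domain_table) <- NULL

  topo <- list()
  for (g in genes) {
    if (g$coding && g$tm) {
      topo[[g$symbol]] <- topology_annotation(
        g$symbol, g$tm_segments, nterm_compartment = "cytoplasmic",
        protein_length = nchar(g$protein))
    }
  }

  calls <- vector("list", p$n_fusions)
  truth <- vector("list", p$n_fusions)
  type_names <- names(p$tumor_type_freq)
  for (j in seq_len(p$n_fusions)) {
    # choose the target frame status first, then draw gene pairs until a
    # junction pair realizing it exists, so the in-frame fraction tracks
    # p_inframe in expectation (non-coding 5' genes can only serve
    # out-of-frame draws)
    want <- stats::runif(1L) < p$p_inframe
    for (attempt in seq_len(20L)) {
      i5 <- if (want) {
        coding_idx[sample.int(length(coding_idx), 1L)]
      } else {
        sample(seq_len(p$n_genes), 1L)
      }
      pool3 <- setdiff(coding_idx, i5)
      i3 <- pool3[sample.int(length(pool3), 1L)]
      g5 <- genes[[i5]]
      g3 <- genes[[i3]]
      n5 <- length(g5$ex_lens)
      n3 <- length(g3$ex_lens)
      combos <- expand.grid(j5 = seq_len(max(n5 - 1L, 1L)),
                            j3 = seq.int(min(2L, n3), n3))
      frames <- vapply(seq_len(nrow(combos)), function(k) {
        .sim_frame_truth(g5, combos$j5[k], g3, combos$j3[k])$frame
      }, character(1L))
      pool <- which((frames == "in_frame") == want)
      if (length(pool)) break
    }
    if (length(pool) == 0L) pool <- seq_along(frames)
    pick <- pool[sample.int(length(pool), 1L)]
    j5 <- combos$j5[pick]
    j3 <- combos$j3[pick]
    ft <- .sim_frame_truth(g5, j5, g3, j3)

    # truth chimeric protein by direct transcript-string splicing
    fused <- paste0(substring(g5$spliced, 1L, sum(g5$ex_lens[seq_len(j5)])),
                    substring(g3$spliced,
                              sum(g3$ex_lens[seq_len(j3 - 1L)]) + 1L))
    prot <- NA_character_
    if (ft$frame == "in_frame") {
      orf <- if (ft$cds5 > 0L) min(g5$u5, sum(g5$ex_lens[seq_len(j5)])) else
        sum(g5$ex_lens[seq_len(j5)]) +
          (g3$u5 - sum(g3$ex_lens[seq_len(j3 - 1L)]))
      prot <- .translate_to_stop(fused, from = orf)
    }

    # truth domain statuses on the 3' gene
    bp3 <- if (!is.na(ft$off3)) ft$off3 %/% 3L + 1L else NA_integer_
    dom_truth <- NA_character_
    if (!is.na(bp3)) {
      d <- g3$domains
      plen3 <- g3$cds_len %/% 3L - 1L
      st <- vapply(seq_len(nrow(d)), function(k) {
        .sim_domain_status(d$start[k], d$end[k], bp3, plen3)
      }, character(1L))
      dom_truth <- paste0(d$domain, "=", st, collapse = ";")
    }

    # truth partner topology class
    end5 <- if (ft$cds5 > 0L) as.integer(ceiling(ft$cds5 / 3)) else 0L
    tclass <- "no_tm"
    if (g5$coding && g5$tm && end5 > 0L) {
      segs <- g5$tm_segments
      crossed <- sum(segs$end < end5)
      inside <- any(segs$start <= end5 & end5 <= segs$end)
      if (crossed > 0L) {
        tclass <- if (!inside && crossed %% 2L == 0L)
          "transmembrane_cytoplasmic_endpoint" else
          "transmembrane_noncytoplasmic_endpoint"
      }
    }

    sid <- sprintf("SIM%04d", j)
    calls[[j]] <- data.frame(
      sample_id = sid,
      tumor_type = sample(type_names, 1L, prob = p$tumor_type_freq),
      gene5 = g5$symbol, gene3 = g3$symbol,
      junction5 = j5, junction3 = j3,
      supporting_reads = .sample_range(p$read_support),
      well_supported = TRUE, junction_encoding = "exon",
      stringsAsFactors = FALSE
    )
    truth[[j]] <- data.frame(
      sample_id = sid, gene5 = g5$symbol, gene3 = g3$symbol,
      frame_truth = ft$frame, cds5_len = ft$cds5,
      junction_offset3 = ifelse(is.na(ft$off3), NA_integer_, ft$off3),
      breakpoint_aa3 = bp3, endpoint_aa5 = end5,
      retained_domains_truth = dom_truth,
      partner_topology_truth = tclass,
      protein_truth = prot,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, calls)
  truth <- do.call(rbind, truth)
  attr(calls, "junction_encoding") <- "exon"

  subjects <- data.frame(
    sample_id = calls$sample_id,
    age = sample(seq.int(p$age_range[1L], p$age_range[2L]),
                 p$n_fusions, replace = TRUE),
    sex = ifelse(stats::runif(p$n_fusions) < p$p_male, "male", "female"),
    race = sample(c("White", "Black", "Other", "unknown"), p$n_fusions,
                  replace = TRUE, prob = c(0.5, 0.1, 0.05, 0.35)),
    smoking = sample(c("never", "current_or_former", "unknown"),
                     p$n_fusions, replace = TRUE, prob = c(0.2, 0.55, 0.25)),
    stage = sample(c("I", "II", "III", "IV", "unknown"), p$n_fusions,
                   replace = TRUE, prob = c(0.03, 0.07, 0.08, 0.52, 0.3)),
    dna_data = stats::runif(p$n_fusions) < 0.95,
    stringsAsFactors = FALSE
  )
  subjects$co_alterations <- vapply(seq_len(p$n_fusions), function(i) {
    if (!subjects$dna_data[i]) return(NA_character_)
    hits <- c("TP53", "CDKN2A", "TERT", "NF1")[
      stats::runif(4L) < c(0.35, 0.3, 0.1, 0.08)]
    if (length(hits)) paste0(hits, ":short_variant", collapse = ";") else ""
  }, character(1L))

  bundle <- list(genes = models, seq_store = seq_store, calls = calls,
                 domain_table = domain_table, topology = topo,
                 subjects = subjects, truth = truth, params = p)
  if (!is.null(dir)) .write_bundle(bundle, genes, dir)
  bundle
}

# plain-text emission of a simulated bundle (deterministic byte layout)
.write_bundle <- function(bundle, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    con <- file(file.path(dir, name), open = "wb")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", eol = "\n")
    close(con)
  }
  fa <- file(file.path(dir, "genome.fa"), open = "wb")
  for (g in genes) {
    writeLines(c(paste0(">", g$chrom), g$contig), fa)
  }
  close(fa)

  gtf <- file(file.path(dir, "genes.gtf"), open = "wb")
  for (g in genes) {
    tx <- g$model$transcripts[[1L]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     g$gene_id, tx$transcript_id, g$symbol)
    emit <- function(df, type) {
      df <- df[order(df$start), , drop = FALSE]
      sprintf("%s\tgrffuse_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, df$start + 1L, df$end, g$strand, attrs)
    }
    writeLines(emit(tx$exons, "exon"), gtf)
    if (tx$coding) writeLines(emit(tx$cds, "CDS"), gtf)
  }
  close(gtf)

  tsv(bundle$calls, "fusions.tsv")
  tsv(bundle$domain_table, "domains.tsv")
  topo_rows <- list()
  for (sym in names(bundle$topology)) {
    segs <- bundle$topology[[sym]]$tm_segments
    topo_rows[[sym]] <- data.frame(
      protein = sym, tm_start = segs$start, tm_end = segs$end,
      nterm_compartment = bundle$topology[[sym]]$nterm_compartment,
      stringsAsFactors = FALSE
    )
  }
  topo_df <- if (length(topo_rows)) do.call(rbind, topo_rows) else
    data.frame(protein = character(0), tm_start = integer(0),
               tm_end = integer(0), nterm_compartment = character(0))
  tsv(topo_df, "topology.tsv")
  tsv(bundle$subjects, "subjects.tsv")
  tsv(bundle$truth, "truth.tsv")
  invisible(dir)
}
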