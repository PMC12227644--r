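test_that("window means reproduce a direct sliding-window oracle", {
  set.seed(23)
  bg <- c("D", "E", "K", "S", "T", "G", "N")
  prot <- paste0(c(sample(bg, 40L, TRUE), rep("L", 25L),
                   sample(bg, 40L, TRUE)), collapse = "")
  marked <- oracle_tm_marked(prot)
  segs <- call_tm_segments(prot)
  expect_identical(nrow(segs), 1L)
  # the called segment is exactly the maximal marked run
  expect_identical(segs$start, min(marked))
  expect_identical(segs$end, max(marked))
  # and covers the planted leucine run's interior
  expect_lte(segs$start, 45L)
  expect_gte(segs$end, 61L)
})

test_that("hydrophilic sequences yield no segments and short ones warn", {
  expect_identical(nrow(call_tm_segments(strrep("D", 80L))), 0L)
  expect_warning(out <- call_tm_segments("MKT"), "shorter than window")
  expect_identical(nrow(out), 0L)
})

test_that("an occludin-like four-pass protein yields four segments inside the planted runs", {
  oc <- occludin_like()
  segs <- call_tm_segments(oc$protein)
  expect_identical(nrow(segs), 4L)
  for (k in 1:4) {
    expect_gte(segs$start[k], oc$segments$start[k])
    expect_lte(segs$end[k], oc$segments$end[k])
  }
})

test_that("compartments alternate from the N-terminus across TM segments", {
  oc <- occludin_like()
  topo <- predict_topology(oc$protein, "OCLN_LIKE")
  expect_identical(topo$nterm_compartment, "cytoplasmic")
  segs <- topo$tm_segments
  # before any segment
  expect_identical(endpoint_compartment(topo, 5L), "cytoplasmic")
  # between segments 1 and 2: one membrane pass crossed
  expect_identical(endpoint_compartment(topo, segs$end[1L] + 3L),
                   "extracellular")
  # inside a segment
  expect_identical(endpoint_compartment(topo, segs$start[2L] + 5L),
                   "membrane")
  # C-terminal tail after four passes is cytoplasmic again
  expect_identical(endpoint_compartment(topo, segs$end[4L] + 10L),
                   "cytoplasmic")
  # parity property across all inter-segment gaps
  gaps <- c(segs$end[1L] + 2L, segs$end[2L] + 2L, segs$end[3L] + 2L,
            segs$end[4L] + 2L)
  want <- c("extracellular", "cytoplasmic", "extracellular", "cytoplasmic")
  expect_identical(vapply(gaps, endpoint_compartment, "", topo = topo), want)
})

test_that("partner classification requires a complete retained TM segment", {
  oc <- occludin_like()
  topo <- predict_topology(oc$protein, "OCLN_LIKE")
  segs <- topo$tm_segments
  # endpoint in the C-terminal cytoplasmic tail
  expect_identical(classify_partner(topo, segs$end[4L] + 10L),
                   "transmembrane_cytoplasmic_endpoint")
  # endpoint between segments 1 and 2 sits outside the cell
  expect_identical(classify_partner(topo, segs$end[1L] + 3L),
                   "transmembrane_noncytoplasmic_endpoint")
  # endpoint before the first segment retains no TM at all
  expect_identical(classify_partner(topo, 5L), "no_tm")
  # a soluble partner is no_tm everywhere
  sol <- topology_annotation("IQGAP1_LIKE",
                             data.frame(start = integer(0),
                                        end = integer(0)),
                             protein_length = 52L)
  expect_identical(classify_partner(sol, 52L), "no_tm")
  expect_identical(endpoint_compartment(sol, 30L), "cytoplasmic")
})

test_that("deleting five residues from a TM segment abolishes the call", {
  oc <- occludin_like(n_tm = 1L)
  seg <- oc$segments[1L, ]
  expect_identical(nrow(call_tm_segments(oc$protein)), 1L)
  # remove 5 residues from inside the segment (the del255-259 analogue)
  del <- paste0(substring(oc$protein, 1L, seg$start + 4L),
                substring(oc$protein, seg$start + 10L))
  expect_identical(nrow(call_tm_segments(del)), 0L)
})

test_that("a signal-peptide-like segment flips the default N-terminal compartment", {
  prot <- paste0(strrep("L", 35L), strrep("D", 80L))
  topo <- predict_topology(prot, "SP_LIKE")
  expect_identical(topo$nterm_compartment, "extracellular")
})

test_that("hydropathy parameters enforce their invariants", {
  expect_error(hydropathy_params(window = 18L), "odd")
  expect_error(hydropathy_params(window = 3L), "odd")
  expect_error(hydropathy_params(window = 9L, min_tm_len = 16L),
               "window \\+ 6")
  expect_error(topology_annotation("P", data.frame(start = c(1L, 5L),
                                                   end = c(10L, 20L))),
               "overlapping")
})
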