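test_that("poly tracts are maximal, sorted and non-overlapping", {
  tr <- find_poly_tracts("AATTTTTTTTTTGG", "T", 10)
  expect_equal(tr, data.frame(base = "T", start = 3L, length = 10L))
  expect_equal(nrow(find_poly_tracts("ACGT", "T", 2)), 0)
  set.seed(21)
  for (rep in 1:20) {
    s <- random_dna(200, at = 0.8)
    tr <- find_poly_tracts(s, "T", 3)
    # regex oracle for maximal runs
    g <- gregexpr("T{3,}", s)[[1]]
    if (g[1] == -1L) expect_equal(nrow(tr), 0)
    else {
      expect_equal(tr$start, as.integer(g))
      expect_equal(tr$length, attr(g, "match.length"))
    }
    if (nrow(tr) > 1)
      expect_true(all(tr$start[-1] > tr$start[-nrow(tr)] +
                        tr$length[-nrow(tr)]))
  }
})

test_that("stem-loop detection handles perfect and mismatched hairpins", {
  hit <- find_stem_loops("GGGGAAAACCCC", min_stem = 4, loop_range = c(3, 8),
                         max_mismatch = 0)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$arm5_start, 1L)
  expect_equal(hit$stem_length, 4L)
  expect_equal(hit$mismatches, 0L)
  mut <- "GGTGAAAACCCC"   # one arm base mutated
  expect_equal(nrow(find_stem_loops(mut, 4, c(3, 8), 0)), 0)
  hit1 <- find_stem_loops(mut, 4, c(3, 8), 1)
  expect_equal(nrow(hit1), 1)
  expect_equal(hit1$mismatches, 1L)
  # G.T wobble only counts when asked
  gt <- "GCGGAAATCGC"     # stem needs a G.T pair at the loop boundary
  expect_equal(nrow(find_stem_loops(gt, 4, c(3, 8), 0, gu_pairs = FALSE)), 0)
  expect_equal(nrow(find_stem_loops(gt, 4, c(3, 8), 0, gu_pairs = TRUE)), 1)
})

test_that("stem-loop scan equals brute-force enumeration on random input", {
  set.seed(31)
  for (rep in 1:150) {
    n <- sample(15:40, 1)
    s <- random_dna(n, at = sample(c(0.5, 0.7), 1))
    ms <- sample(3:5, 1)
    lr <- c(3, sample(6:10, 1))
    mm <- sample(0:1, 1)
    impl <- find_stem_loops(s, ms, lr, mm)
    oracle <- brute_stem_loops(s, ms, lr, mm)
    if (is.null(oracle)) expect_equal(nrow(impl), 0)
    else expect_identical(impl, oracle)
  }
})

test_that("reverse-complementing a region mirrors its stem-loops", {
  set.seed(8)
  for (rep in 1:10) {
    s <- random_dna(60, at = 0.7)
    fw <- find_stem_loops(s, 4, c(3, 8), 1)
    rv <- find_stem_loops(reverse_complement(s), 4, c(3, 8), 1)
    expect_equal(nrow(fw), nrow(rv))
    if (nrow(fw)) {
      n <- nchar(s)
      mirrored <- data.frame(
        arm5_start = n - fw$arm3_end + 1L, arm5_end = n - fw$arm3_start + 1L,
        arm3_start = n - fw$arm5_end + 1L, arm3_end = n - fw$arm5_start + 1L,
        stem_length = fw$stem_length, loop_length = fw$loop_length,
        mismatches = fw$mismatches)
      mirrored <- mirrored[order(mirrored$arm5_start, mirrored$stem_length,
                                 mirrored$arm3_start), ]
      rownames(mirrored) <- NULL
      expect_equal(rv, mirrored)
    }
  }
})

test_that("motif search finds literal motifs and maximal TA runs", {
  expect_equal(find_motifs("CCGAATCC", "GAAT"),
               data.frame(motif = "GAAT", start = 3L, length = 4L,
                          n = NA_integer_))
  ta <- find_motifs("GGTATATATAGG", "(TA)n", ta_min_n = 3)
  expect_equal(ta$start, 3L)
  expect_equal(ta$n, 4L)
  expect_equal(nrow(find_motifs("GGTATAGG", "(TA)n", ta_min_n = 3)), 0)
})

test_that("dot-bracket strings pair matched stem positions", {
  s <- "GGGGAAAACCCC"
  sl <- find_stem_loops(s, 4, c(3, 8), 0)
  expect_equal(dot_bracket(s, sl[1, ]), "((((....))))")
  mut <- "GGTGAAAACCCC"
  sl1 <- find_stem_loops(mut, 4, c(3, 8), 1)
  expect_equal(dot_bracket(mut, sl1[1, ]), "((.(....).))")
})

test_that("control-region scan reports planted structure at absolute coordinates", {
  sim <- default_sim()
  scan <- scan_control_region(sim$genome)
  truth <- sim$truth$control_region
  expect_equal(scan$region$length,
               unname(truth$region["end"] - truth$region["start"] + 1L))
  expect_equal(scan$poly_tracts$abs_start, truth$poly_tracts$start)
  expect_equal(scan$poly_tracts$length, truth$poly_tracts$length)
  expect_equal(sort(scan$motifs$abs_start), sort(truth$motifs$start))
  planted <- paste(truth$hairpins$arm5_start, truth$hairpins$stem_length,
                   truth$hairpins$loop_length)
  found <- paste(scan$stem_loops$abs_arm5_start, scan$stem_loops$stem_length,
                 scan$stem_loops$loop_length)
  expect_true(all(planted %in% found))
  # the published coordinates put the control region at 1251 nt
  ann <- kwangi_annotation()
  cr <- ann[ann$class == "control_region", ]
  expect_equal(feature_length(cr$start, cr$end), 1251)
  # a genome without a control region yields a finding, not an error
  g <- mito_genome(random_dna(100),
                   annotation_table(gene_feature("t", "tRNA", 1, 60),
                                    100, TRUE))
  empty <- scan_control_region(g)
  expect_null(empty$region)
  expect_match(empty$findings, "control_region")
})
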