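test_that("generated genomes satisfy every construction guarantee", {
  sim <- default_sim()
  g <- sim$genome
  ann <- g$annotation
  expect_equal(nrow(validate_annotation(ann)), 0)
  expect_equal(nchar(g$sequence), attr(ann, "genome_length"))
  # the IGN profile round-trips entry for entry (Table-style profile with
  # its negative, overlapping boundaries)
  expect_identical(intergenic_table(ann)$ign, sim$truth$ign_profile)
  expect_identical(sum(feature_lengths(ann)) + sum(sim$truth$ign_profile),
                   attr(ann, "genome_length"))
  # planted protein codons are recovered from the sequence itself
  ss <- start_stop_table(g)
  expect_equal(ss$start_codon, sim$truth$codons$start_codon)
  expect_equal(ss$stop_codon, sim$truth$codons$stop_codon)
  # planted gene payload round-trip: a feature's extracted sequence begins
  # and ends with the planned codons even inside overlap clusters
  expect_true(all(ss$start_ok) && all(ss$stop_complete))
  expect_equal(sim$truth$seed, 101L)
  expect_match(sim$truth$spec_hash, "^[0-9a-f]{8}$")
})

test_that("composition targets are recovered within sampling tolerance", {
  sim <- default_sim()
  rep <- region_composition_report(sim$genome)
  at <- sim$truth$at_targets
  expect_lt(abs(rep$profiles$pcg$at_content - 100 * at[["PCG"]]), 2)
  expect_lt(abs(rep$profiles$trna$at_content - 100 * at[["tRNA"]]), 2)
  expect_lt(abs(rep$profiles$lrrna$at_content - 100 * at[["rRNA"]]), 2)
  expect_lt(abs(rep$profiles$control$at_content -
                  100 * at[["control_region"]]), 2)
  # a deliberately different PCG target is honoured too
  spec <- genome_spec(at_targets = c(PCG = 0.7, tRNA = 0.72, rRNA = 0.71,
                                     control_region = 0.78,
                                     intergenic = 0.7), seed = 55)
  sim2 <- generate_mitogenome(spec)
  rep2 <- region_composition_report(sim2$genome)
  expect_lt(abs(rep2$profiles$pcg$at_content - 70), 2)
  expect_equal(nrow(validate_annotation(sim2$genome$annotation)), 0)
})

test_that("infeasible genome specs are rejected up front", {
  plan <- default_gene_plan()
  plan$ign_before[4] <- -(plan$length[3] + 5L)   # overlap swallows a gene
  expect_error(genome_spec(gene_plan = plan), "infeasible")
  plan2 <- default_gene_plan()
  plan2$length[plan2$name == "ND2"] <- 1000L     # not divisible by 3
  expect_error(genome_spec(gene_plan = plan2), "divisible")
})

test_that("gene-order signatures of same-template genomes agree", {
  sim <- default_sim()
  expect_equal(gene_order_signature(sim$genome$annotation),
               gene_order_signature(kwangi_annotation()))
})

test_that("exactness scaffold yields exactly the planted control elements", {
  p <- plant_control_region(600, background = "ac", seed = 12)
  expect_identical(find_stem_loops(p$seq), p$truth$hairpins)
  expect_identical(find_poly_tracts(p$seq), p$truth$poly_tracts)
  expect_identical(find_motifs(p$seq), p$truth$motifs)
})

test_that("protein evolution honours the replacement process", {
  # zero-length branches: all tips identical to the root
  ev0 <- evolve_alignment(evolution_spec(
    tree = "((a:0,b:0):0,c:0);", gene_lengths = c(ND2 = 50), seed = 3,
    mu = 0.5))
  rows <- ev0$alignments$ND2$rows
  expect_equal(unname(rows["a"]), unname(rows["b"]))
  expect_equal(unname(rows["a"]), unname(rows["c"]))
  # two tips at total distance t: mismatches ~ Binomial(n, p) with
  # p = (1 - (1 - mu)^t) x 19/20 + parallel-hit terms; check within 3 sigma
  # of the first-order expectation
  mu <- 0.3; t <- 1.0; n <- 4000
  ev2 <- evolve_alignment(evolution_spec(
    tree = sprintf("(a:%g,b:%g);", t / 2, t / 2),
    gene_lengths = c(COI = n), mu = mu, seed = 9))
  m <- alignment <- ev2$alignments$COI$rows
  mism <- sum(strsplit(m[["a"]], "")[[1]] != strsplit(m[["b"]], "")[[1]])
  p <- 1 - (1 - mu)^t
  expect_lt(abs(mism - n * p), 3 * sqrt(n * p * (1 - p)) + n * p^2 / 10)
  # determinism under the seed
  ev2b <- evolve_alignment(evolution_spec(
    tree = sprintf("(a:%g,b:%g);", t / 2, t / 2),
    gene_lengths = c(COI = n), mu = mu, seed = 9))
  expect_identical(ev2$alignments$COI$rows, ev2b$alignments$COI$rows)
  expect_error(evolution_spec(mu = 1.2), "mu")
})

test_that("the full simulation pipeline recovers the guide topology", {
  ev <- evolve_alignment(evolution_spec(seed = 31))
  aln <- concatenate_pcgs(ev$alignments)
  est <- neighbor_joining(p_distance_matrix(aln))
  expect_equal(ape::dist.topo(ape::unroot(ev$tree), est), 0,
               ignore_attr = TRUE)
})

test_that("synthetic genomes export with a truth sidecar", {
  sim <- default_sim()
  dir <- tempfile()
  files <- export_synthetic_genome(sim, dir)
  expect_true(all(file.exists(files)))
  truth <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  expect_equal(truth$seed, sim$truth$seed)
  expect_equal(truth$coordinates$start, sim$truth$coordinates$start)
})
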