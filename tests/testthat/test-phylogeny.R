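test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(as.character(translate_cds("ATGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("ATATGATCT")), "MWS")
  expect_equal(as.character(translate_cds("atgaaataa")), "MK")
  kept <- translate_cds("ATGTAAAAA", trim_terminal_stop = FALSE)
  expect_equal(as.character(kept), "M*K")
  expect_equal(attr(kept, "internal_stops"), 2L)
  expect_error(translate_cds("ATGA"), "divisible")
  # synthetic protein genes translate without internal stops
  sim <- default_sim()
  ann <- sim$genome$annotation
  for (i in which(ann$class == "PCG")) {
    aa <- translate_cds(extract_feature_sequence(sim$genome, ann[i, ]))
    expect_length(attr(aa, "internal_stops"), 0)
  }
})

test_that("supermatrix concatenation is canonical and gap-fills", {
  a <- protein_alignment(c(t1 = "MKLLV", t2 = "MKLIV", t3 = "MRLLV"))
  b <- protein_alignment(c(t1 = "AHWQRST", t2 = "AHWQRSA", t3 = "AHFQRSA"))
  cab <- concatenate_pcgs(list(ND2 = a, COI = b))
  expect_equal(cab$length, 12)
  expect_equal(cab$partitions,
               data.frame(gene = c("ND2", "COI"), start = c(1L, 6L),
                          end = c(5L, 12L), stringsAsFactors = FALSE))
  # input order does not matter
  cba <- concatenate_pcgs(list(COI = b, ND2 = a))
  expect_equal(cba$rows, cab$rows)
  # missing taxon becomes an all-gap block with a finding
  b2 <- protein_alignment(c(t1 = "AHWQRST", t3 = "AHFQRSA"))
  cg <- concatenate_pcgs(list(ND2 = a, COI = b2), min_shared_taxa = 2)
  expect_equal(substr(cg$rows[["t2"]], 6, 12), "-------")
  expect_match(attr(cg, "findings"), "t2")
  ev <- evolve_alignment(evolution_spec(seed = 5))
  sup <- concatenate_pcgs(ev$alignments)
  expect_equal(sup$length,
               sum(vapply(ev$alignments, function(a) a$length, 1L)))
})

test_that("p-distances equal a per-column tally and respect gaps", {
  expect_equal(p_distance_matrix(protein_alignment(
    c(a = "AAAA", b = "AAAA")))["a", "b"], 0)
  expect_equal(p_distance_matrix(protein_alignment(
    c(a = "AAAA", b = "AAAT")))["a", "b"], 0.25)
  # gapped columns excluded from the denominator
  expect_equal(p_distance_matrix(protein_alignment(
    c(a = "A-AT", b = "AAAA")))["a", "b"], 1 / 3)
  expect_error(p_distance_matrix(protein_alignment(
    c(a = "--", b = "--"))), "comparable")
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- sample(aas, 200, TRUE); y <- sample(aas, 200, TRUE)
  d <- p_distance_matrix(protein_alignment(
    c(a = paste(x, collapse = ""), b = paste(y, collapse = ""))))["a", "b"]
  expect_equal(d, mean(x != y))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form star resolution
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(el[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  # additive matrices from random trees: exact topology and branch lengths
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    D <- stats::cophenetic(true)
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    # path lengths reproduce the input distances
    expect_equal(stats::cophenetic(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
    # agrees with an independent NJ implementation
    expect_equal(ape::dist.topo(ape::nj(D), est), 0, ignore_attr = TRUE)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "3 taxa")
  asym <- matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3)
  expect_error(neighbor_joining(asym), "symmetric")
  neg <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3)
  expect_error(neighbor_joining(neg), "negative")
})

test_that("bootstrap supports are reproducible and saturate for clean clades", {
  # two clades separated by many diagnostic columns
  rows <- c(a1 = strrep("AK", 30), a2 = strrep("AK", 30),
            b1 = strrep("GR", 30), b2 = strrep("GR", 30),
            c1 = strrep("LM", 30))
  rows <- vapply(seq_along(rows), function(i) {
    s <- strsplit(rows[[i]], "")[[1]]
    s[i * 3] <- "W"   # make every row unique
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(rows) <- c("a1", "a2", "b1", "b2", "c1")
  aln <- protein_alignment(rows)
  bt <- bootstrap_support(aln, n_reps = 100, seed = 4)
  expect_equal(clade_support(bt, c("a1", "a2")), 100)
  expect_equal(clade_support(bt, c("b1", "b2")), 100)
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 4)
  expect_equal(bt$supports, bt2$supports)
  # invariant to taxon input order under the same seed
  bt3 <- bootstrap_support(protein_alignment(rows[c(3, 1, 5, 2, 4)]),
                           n_reps = 100, seed = 4)
  expect_equal(bt$supports, bt3$supports)
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
  expect_s3_class(bt$consensus, "phylo")
})

test_that("newick text round-trips topology, lengths and supports", {
  txt <- "(A:1,B:1,(C:1,D:1):0.5);"
  expect_equal(write_newick(parse_newick(txt)), txt)
  sup <- "(A,B,(C,D)95);"
  tr <- parse_newick(sup)
  expect_equal(tr$node.label[2], "95")
  expect_match(write_newick(tr), "95")
  set.seed(23)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:12, 1))
    back <- parse_newick(write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_setequal(back$tip.label, tr$tip.label)
    expect_equal(sum(back$edge.length), sum(tr$edge.length),
                 tolerance = 1e-6)
  }
  expect_error(parse_newick("((A,B);"), "newick")
})

test_that("supermatrix export writes FASTA, PHYLIP and partitions", {
  ev <- evolve_alignment(evolution_spec(
    tree = "((a:0.1,b:0.1):0.1,c:0.2);",
    gene_lengths = c(ND2 = 20, COI = 30), seed = 2))
  aln <- concatenate_pcgs(ev$alignments)
  fa <- tempfile(fileext = ".fasta"); ph <- tempfile(fileext = ".phy")
  pt <- tempfile(fileext = ".tsv")
  export_supermatrix(aln, fasta = fa, phylip = ph, partitions = pt)
  expect_equal(sum(grepl("^>", readLines(fa))), 3)
  expect_equal(readLines(ph)[1], "3 50")
  parts <- utils::read.delim(pt)
  expect_equal(parts$gene, c("ND2", "COI"))
  expect_equal(parts$end, c(20L, 50L))
})
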