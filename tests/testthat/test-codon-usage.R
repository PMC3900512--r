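test_that("the invertebrate mitochondrial code has its diagnostic assignments", {
  code <- genetic_code(5)
  expect_equal(unname(code$codon_to_aa[c("ATA", "TGA", "AGA", "AGG")]),
               c("M", "W", "S", "S"))
  expect_length(code$families[["S"]], 8)
  expect_setequal(code$families[["*"]], c("TAA", "TAG"))
  expect_setequal(code$families[["M"]], c("ATA", "ATG"))
  expect_true(all(c("ATG", "ATA", "ATT", "GTG", "TTG") %in%
                    code$start_codons))
  expect_length(code$codon_to_aa, 64)
})

test_that("codon counting is exact and additive", {
  code <- genetic_code(5)
  tab <- count_codons("ATGAAATAA", code)
  expect_equal(tab$count[match(c("ATG", "AAA", "TAA"), tab$codon)],
               c(1L, 1L, 1L))
  expect_equal(attr(tab, "total_codons"), 3L)
  set.seed(3)
  cds <- vapply(c(300, 150), random_dna, character(1), at = 0.6)
  both <- count_codons(cds, code)
  concat <- count_codons(paste(cds, collapse = ""), code)
  expect_equal(both$count, concat$count)
  # independent oracle: Biostrings in-frame trinucleotide tally
  oracle <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(cds), 3, step = 3))
  expect_equal(stats::setNames(both$count, both$codon),
               oracle[both$codon])
  expect_error(count_codons("ATGA", code), "divisible")
  amb <- count_codons("ATGNNNTAA", code)
  expect_equal(attr(amb, "ambiguous_codons"), 1L)
  expect_equal(attr(amb, "total_codons"), 2L)
})

test_that("RSCU reproduces printed family values and conserves family sums", {
  code <- genetic_code(5)
  leu <- rscu(codon_usage_table(c(UUA = 193, UUG = 48, CUU = 99, CUC = 43,
                                  CUA = 94, CUG = 25), code))
  expect_equal(round_half_up(leu$rscu[leu$codon == "TTA"], 2), 2.31)
  ser <- rscu(codon_usage_table(c(UCU = 67, UCC = 51, UCA = 77, UCG = 13,
                                  AGU = 28, AGC = 19, AGA = 29, AGG = 21),
                                code))
  expect_equal(round_half_up(ser$rscu[ser$codon == "TCA"], 2), 2.02)
  arg <- rscu(codon_usage_table(c(CGU = 14, CGC = 9, CGA = 24, CGG = 6),
                                code))
  expect_equal(round_half_up(arg$rscu[arg$codon == "CGA"], 2), 1.81)
  stop_fam <- rscu(codon_usage_table(c(UAA = 98, UAG = 28), code))
  expect_equal(round_half_up(stop_fam$rscu[stop_fam$codon == "TAA"], 2),
               1.56)
  # properties over random count tables: family sums and scale invariance
  set.seed(9)
  for (rep in 1:20) {
    counts <- stats::setNames(sample(0:50, 64, replace = TRUE),
                              names(code$codon_to_aa))
    tab <- rscu(codon_usage_table(counts, code))
    sums <- tapply(tab$rscu, tab$aa, sum)
    sizes <- tapply(tab$rscu, tab$aa, length)
    present <- !is.na(sums)
    expect_equal(unname(sums[present]), unname(sizes[present]))
    tab2 <- rscu(codon_usage_table(counts * 7L, code))
    expect_equal(tab2$rscu, tab$rscu)
  }
  uni <- rscu(codon_usage_table(c(CAA = 5, CAG = 5), code))
  expect_equal(uni$rscu[uni$aa == "Q"], c(1, 1))
  zero <- rscu(codon_usage_table(c(CAA = 3), code))
  expect_true(all(is.na(zero$rscu[zero$aa == "K"])))
})

test_that("amino-acid usage normalises over counted codons", {
  code <- genetic_code(5)
  cc <- kwangi_codon_counts()
  tab <- codon_usage_table(stats::setNames(cc$count, cc$codon), code)
  # serine family count across its eight codons
  expect_equal(sum(tab$count[tab$aa == "S"]), 305)
  usage <- amino_acid_usage(tab)
  expect_equal(sum(usage), 100)
  expect_equal(unname(amino_acid_usage(
    codon_usage_table(c(AUU = 4), code))[["I"]]), 100)
  with_stops <- amino_acid_usage(tab, include_stops = TRUE)
  expect_true("*" %in% names(with_stops))
  expect_lt(with_stops[["S"]], usage[["S"]])
})

test_that("start/stop codons are read off annotated genes", {
  sim <- default_sim()
  ss <- start_stop_table(sim$genome)
  truth <- sim$truth$codons
  expect_equal(ss$start_codon, truth$start_codon)
  expect_equal(ss$stop_codon, truth$stop_codon)
  expect_true(all(ss$start_ok))
  expect_true(all(ss$stop_complete))
  # direct read-off on a hand-built gene
  g <- mito_genome("ATACCCGGGTAG",
                   annotation_table(gene_feature("x", "PCG", 1, 12, "J"),
                                    12, FALSE))
  expect_equal(start_stop_table(g)[, c("start_codon", "stop_codon")],
               data.frame(start_codon = "ATA", stop_codon = "TAG"))
})

test_that("codon usage TSV export follows the codon-box layout", {
  code <- genetic_code(5)
  cc <- kwangi_codon_counts()
  tab <- rscu(codon_usage_table(stats::setNames(cc$count, cc$codon), code))
  tmp <- tempfile(fileext = ".tsv")
  df <- codon_usage_tsv(tab, tmp)
  expect_equal(nrow(df), 64)
  expect_equal(df$codon[1:4], c("UUU", "UUC", "UUA", "UUG"))
  expect_equal(df$rscu[df$codon == "UUA"], 2.31)
})
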