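test_that("feature lengths follow the inclusive-coordinate arithmetic", {
  expect_equal(feature_length(1397, 2983), 1587)   # COI span
  expect_equal(feature_length(208, 1245), 1038)    # ND2 span
  expect_equal(feature_length(5, 5), 1)
  # wrapping feature across the origin: count the positions it covers
  wrapped <- c(16170:16179, 1:10)
  expect_equal(feature_length(16170, 10, 16179, circular = TRUE),
               length(wrapped))
  expect_error(feature_length(0, 5), "coordinates")
  expect_error(feature_length(10, 2), "circular")
  expect_error(feature_length(10, 20, genome_length = 15), "genome_length")
})

test_that("intergenic arithmetic reproduces printed overlap/gap values", {
  ann <- kwangi_annotation()
  ign <- intergenic_table(ann)
  expect_equal(ign$ign[ign$feature == "ND1"], -47)
  expect_equal(ign$ign[ign$feature == "COI"], -41)
  expect_equal(ign$ign[ign$feature == "ATP8"], 9)
  expect_equal(ign$ign[ign$feature == "tRNA-Ile"], 0)  # wrap boundary
  toy <- toy_annotation()
  expect_equal(intergenic_table(toy)$ign, c(0, 0, 0))
  bad <- annotation_table(toy[c(2, 1, 3), ], 500, circular = TRUE)
  expect_error(intergenic_table(bad), "sorted")
})

test_that("lengths and IGNs telescope to the genome length", {
  ann <- kwangi_annotation()
  expect_identical(sum(feature_lengths(ann)) +
                     sum(intergenic_table(ann)$ign),
                   attr(ann, "genome_length"))
  # property: holds for arbitrary circular tables by construction
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    lens <- sample(50:400, n, replace = TRUE)
    igns <- sample(-20:30, n, replace = TRUE)
    igns <- pmax(igns, -pmin(lens, c(lens[n], lens[-n])) + 1L)
    igns[1] <- abs(igns[1])   # non-wrapping first feature
    glen <- sum(lens) + sum(igns)
    start <- integer(n); end <- integer(n)
    pos <- igns[1]
    for (i in seq_len(n)) {
      start[i] <- pos + 1L
      end[i] <- start[i] + lens[i] - 1L
      pos <- end[i] + if (i < n) igns[i + 1] else 0L
    }
    ann2 <- annotation_table(
      data.frame(name = paste0("g", 1:n), class = "tRNA", start = start,
                 end = end, strand = "J", stringsAsFactors = FALSE),
      genome_length = glen, circular = TRUE)
    expect_equal(sum(feature_lengths(ann2)) +
                   sum(intergenic_table(ann2)$ign), glen)
    # shifting a feature start by +k moves its boundary IGN by exactly +k
    k <- 3L
    i <- which(diff(start) > k + 1)[1]
    if (!is.na(i)) {
      ann3 <- ann2
      ann3$start[i + 1] <- ann3$start[i + 1] + k
      expect_equal(intergenic_table(ann3)$ign[i + 1],
                   intergenic_table(ann2)$ign[i + 1] + k)
    }
  }
})

test_that("feature sequences are extracted in coding orientation", {
  g <- mito_genome("AAACCCGGG",
                   annotation_table(rbind(
                     gene_feature("f1", "tRNA", 4, 6, "J"),
                     gene_feature("f2", "tRNA", 4, 6, "N")), 9, FALSE))
  expect_equal(extract_feature_sequence(g, "f1"), "CCC")
  expect_equal(extract_feature_sequence(g, "f2"), "GGG")
  # reverse complement twice is the identity, ambiguity codes included
  s <- "ACGTRYSWKMBDHVN"
  expect_equal(reverse_complement(reverse_complement(s)), s)
  # wrapping feature is spliced across the origin
  gw <- mito_genome("AAACCCGGG",
                    annotation_table(gene_feature("w", "tRNA", 8, 2, "J"),
                                     9, TRUE))
  expect_equal(extract_feature_sequence(gw, "w"), "GGAA")
  expect_error(extract_feature_sequence(mito_genome(NULL), "x"),
               "no sequence|annotation")
})

test_that("gene-order signatures are rotation-invariant and order-sensitive", {
  ann <- kwangi_annotation()
  sig <- gene_order_signature(ann)
  # rotate the linearisation origin: same circular order, new first feature
  rot <- rbind(as.data.frame(ann)[10:38, ], as.data.frame(ann)[1:9, ])
  ann_rot <- annotation_table(rot, attr(ann, "genome_length"), TRUE)
  expect_equal(gene_order_signature(ann_rot), sig)
  swapped <- as.data.frame(ann)
  swapped[c(2, 3), c("name", "strand")] <- swapped[c(3, 2),
                                                   c("name", "strand")]
  expect_false(gene_order_signature(
    annotation_table(swapped, attr(ann, "genome_length"), TRUE)) == sig)
})

test_that("validation reports findings instead of failing", {
  expect_equal(nrow(validate_annotation(toy_annotation())), 0)
  bad <- annotation_table(gene_feature("g", "tRNA", 10, 40), 50,
                          circular = FALSE)
  bad$end <- 5L   # end < start on a linear genome
  expect_true(any(validate_annotation(bad)$type == "coordinate"))
  # the published table's one inconsistent row is flagged, not silently fixed
  v <- validate_annotation(kwangi_annotation())
  expect_setequal(v$type, c("printed_length", "printed_ign"))
  expect_true(all(v$feature == "COII"))
})
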