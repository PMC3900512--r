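# Independent oracles and small builders shared across the suite.

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# Brute-force stem-loop enumeration: every (start, stem, loop) triple is
# tested against the constraints; within a loop family only the longest
# valid stem survives, and nested same-antidiagonal candidates are dropped.
# Independent of the scanner's outward-growth implementation.
brute_stem_loops <- function(seq, min_stem, loop_range, max_mismatch,
                             gu_pairs = FALSE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  n <- length(chars)
  cand <- list()
  for (s in seq_len(n)) {
    for (k in min_stem:floor((n - loop_range[1]) / 2)) {
      a5e <- s + k - 1L
      if (a5e + loop_range[1] + k > n) break
      for (l in loop_range[1]:loop_range[2]) {
        a3s <- a5e + l + 1L
        a3e <- a3s + k - 1L
        if (a3e > n) break
        x <- chars[a5e:s]                   # innermost -> outermost
        y <- chars[a3s:a3e]
        m <- comp[x] == y
        if (gu_pairs)
          m <- m | (x == "G" & y == "T") | (x == "T" & y == "G")
        if (!m[1L] || !m[k] || sum(!m) > max_mismatch) next
        cand[[length(cand) + 1L]] <-
          data.frame(arm5_start = s, arm5_end = a5e, arm3_start = a3s,
                     arm3_end = a3e, stem_length = k, loop_length = l,
                     mismatches = as.integer(sum(!m)))
      }
    }
  }
  if (!length(cand)) return(NULL)
  df <- do.call(rbind, cand)
  # per loop family, keep the longest stem
  fam <- paste(df$arm5_end + 1L, df$loop_length)
  keep <- unlist(lapply(split(seq_len(nrow(df)), fam), function(ix)
    ix[which.max(df$stem_length[ix])]), use.names = FALSE)
  df <- df[keep, , drop = FALSE]
  # antidiagonal dominance
  d <- df$arm5_end + df$arm3_start
  drop <- rep(FALSE, nrow(df))
  for (g in split(seq_len(nrow(df)), d)) {
    for (x in g) for (y in g) {
      if (x != y && df$arm5_start[y] <= df$arm5_start[x] &&
          df$arm5_end[x] <= df$arm5_end[y] &&
          df$stem_length[x] < df$stem_length[y]) drop[x] <- TRUE
    }
  }
  df <- df[!drop, , drop = FALSE]
  df <- df[order(df$arm5_start, df$stem_length, df$arm3_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[] <- lapply(df, as.integer)
  df
}

# small circular toy annotation: three abutting features
toy_annotation <- function() {
  feats <- rbind(
    gene_feature("g1", "tRNA", 1, 100),
    gene_feature("g2", "PCG", 101, 400, start_codon = "ATG",
                 stop_codon = "TAA"),
    gene_feature("g3", "tRNA", 401, 500))
  annotation_table(feats, genome_length = 500, circular = TRUE)
}

# default synthetic genome, generated once per test run
sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(sim_cache$sim))
    sim_cache$sim <- generate_mitogenome(genome_spec(seed = 101))
  sim_cache$sim
}
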