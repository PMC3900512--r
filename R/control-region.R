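#' Maximal homopolymer tracts
#'
#' Finds all maximal runs of a given base with at least \code{min_len}
#' repeats, the classic scan for the poly-T stretch implicated in replication
#' initiation in insect control regions.
#'
#' @param seq nucleotide string.
#' @param base single nucleotide whose runs are sought.
#' @param min_len minimum run length.
#' @return data frame with columns \code{base}, \code{start} (1-based within
#'   \code{seq}) and \code{length}, sorted by start; maximal runs of the same
#'   base never overlap.
#' @examples
#' find_poly_tracts("AATTTTTTTTTTGG", "T", 10)  # start 3, length 10
#' @export
find_poly_tracts <- function(seq, base = "T", min_len = 10) {
  seq <- normalize_codon(seq)
  base <- normalize_codon(base)
  stopifnot(nchar(base) == 1L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(base = rep(base, sum(keep)), start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

# Watson-Crick (optionally G.T wobble) pairing indicator for base vectors
wc_pair <- function(x, y, gu_pairs = FALSE) {
  p <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (gu_pairs) p <- p | (x == "G" & y == "T") | (x == "T" & y == "G")
  p
}

#' Inverted-repeat stem-loops
#'
#' Scans for hairpins: two complementary arms (the stem) separated by an
#' unpaired loop. A candidate hairpin is identified by its loop interval; for
#' each admissible loop the stem is grown outwards pair by pair, and the
#' reported stem is the longest extension whose mismatch count stays within
#' \code{max_mismatch} and whose innermost and outermost pairs are
#' Watson-Crick (mismatches are interior to the stem, so every reported stem
#' is maximal: it cannot be extended outwards, and trimming it would not be
#' maximal). Overlapping same-loop candidates are thereby deduplicated to
#' their maximal-stem representative. G.T pairs are not counted by default
#' (DNA-level scan).
#'
#' @param seq nucleotide string.
#' @param min_stem minimum number of paired stem positions.
#' @param loop_range integer vector \code{c(min, max)} of admissible loop
#'   lengths.
#' @param max_mismatch maximum non-complementary pairs tolerated in the stem.
#' @param gu_pairs logical; count G.T as a pair.
#' @return data frame with columns \code{arm5_start}, \code{arm5_end},
#'   \code{arm3_start}, \code{arm3_end}, \code{stem_length},
#'   \code{loop_length}, \code{mismatches}, sorted by position then stem
#'   length.
#' @examples
#' find_stem_loops("GGGGAAAACCCC", min_stem = 4, loop_range = c(3, 8),
#'                 max_mismatch = 0)
#' @export
find_stem_loops <- function(seq, min_stem = 6, loop_range = c(3, 20),
                            max_mismatch = 1, gu_pairs = FALSE) {
  seq <- normalize_codon(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  lmin <- as.integer(loop_range[1]); lmax <- as.integer(loop_range[2])
  if (n < 2L * min_stem + lmin)
    return(empty_stem_loops())
  for (ls in 2:(n - lmin)) {          # first loop position
    ltop <- min(lmax, n - ls)
    if (ltop < lmin) next
    for (l in lmin:ltop) {
      kmax <- min(ls - 1L, n - (ls + l) + 1L)
      if (kmax < min_stem) next
      i <- seq_len(kmax)
      m <- wc_pair(chars[ls - i], chars[ls + l + i - 1L], gu_pairs)
      if (!m[1L]) next                 # innermost pair must be Watson-Crick
      cm <- cumsum(!m)
      ok <- which(m & cm <= max_mismatch & i >= min_stem)
      if (!length(ok)) next
      k <- max(ok)
      out[[length(out) + 1L]] <- c(ls - k, ls - 1L, ls + l,
                                   ls + l + k - 1L, k, l, cm[k])
    }
  }
  if (!length(out)) return(empty_stem_loops())
  df <- as.data.frame(do.call(rbind, out))
  df[] <- lapply(df, as.integer)
  names(df) <- c("arm5_start", "arm5_end", "arm3_start", "arm3_end",
                 "stem_length", "loop_length", "mismatches")
  # deduplicate overlapping candidates to maximal-stem representatives:
  # all pairs of a candidate lie on one antidiagonal (position sums equal),
  # so a candidate whose paired positions are a subset of another's (same
  # antidiagonal, nested 5' arm interval) is dominated and dropped
  d <- df$arm5_end + df$arm3_start
  keep <- rep(TRUE, nrow(df))
  for (g in split(seq_len(nrow(df)), d)) {
    if (length(g) < 2L) next
    for (x in g) for (y in g) {
      if (x == y) next
      if (df$arm5_start[y] <= df$arm5_start[x] &&
          df$arm5_end[x] <= df$arm5_end[y] &&
          df$stem_length[x] < df$stem_length[y]) keep[x] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$arm5_start, df$stem_length, df$arm3_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_stem_loops <- function() {
  data.frame(arm5_start = integer(), arm5_end = integer(),
             arm3_start = integer(), arm3_end = integer(),
             stem_length = integer(), loop_length = integer(),
             mismatches = integer())
}

#' Dot-bracket string for a stem-loop
#'
#' Renders one detected hairpin over its genomic span, pairing brackets for
#' matched stem positions and dots for loop and mismatched positions, for use
#' with RNA-structure viewers.
#'
#' @param seq the scanned nucleotide string.
#' @param stem_loop one row of the [find_stem_loops()] result.
#' @param gu_pairs logical, as used in the scan.
#' @return a string of length \code{arm3_end - arm5_start + 1}.
#' @export
dot_bracket <- function(seq, stem_loop, gu_pairs = FALSE) {
  seq <- normalize_codon(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- stem_loop$stem_length; l <- stem_loop$loop_length
  i <- seq_len(k)
  m <- wc_pair(chars[stem_loop$arm5_end - i + 1L],
               chars[stem_loop$arm3_start + i - 1L], gu_pairs)
  paste(c(ifelse(rev(m), "(", "."), rep(".", l), ifelse(m, ")", ".")),
        collapse = "")
}

#' Sequence motifs in a region
#'
#' Literal motifs are matched exactly; the special motif \code{"(TA)n"}
#' reports maximal TA-dinucleotide runs of at least \code{ta_min_n} repeats
#' together with their repeat number.
#'
#' @param seq nucleotide string.
#' @param motifs character vector of literal motifs and/or \code{"(TA)n"}.
#' @param ta_min_n minimum repeat count for \code{"(TA)n"} runs.
#' @return data frame with columns \code{motif}, \code{start},
#'   \code{length}, and \code{n} (repeat count, \code{NA} for literal
#'   motifs).
#' @examples
#' find_motifs("CCGAATCC", "GAAT")                 # position 3
#' find_motifs("GGTATATATAGG", "(TA)n", ta_min_n = 3)  # start 3, n = 4
#' @export
find_motifs <- function(seq, motifs = c("GAAT", "(TA)n"), ta_min_n = 3) {
  seq <- normalize_codon(seq)
  rows <- list()
  for (m in motifs) {
    if (identical(m, "(TA)n")) {
      g <- gregexpr(sprintf("(TA){%d,}", as.integer(ta_min_n)), seq)[[1]]
      if (g[1] != -1L) {
        len <- attr(g, "match.length")
        rows[[length(rows) + 1L]] <- data.frame(
          motif = "(TA)n", start = as.integer(g), length = len,
          n = len %/% 2L, stringsAsFactors = FALSE)
      }
    } else {
      pat <- normalize_codon(m)
      g <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      if (g[1] != -1L)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = m, start = as.integer(g), length = nchar(pat),
          n = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), start = integer(),
                      length = integer(), n = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default configuration for the control-region scan
#'
#' Published descriptions of the A+T-rich region give no detection
#' parameters; these defaults (poly-T tracts of at least 10 nt, the length
#' observed in the genome that motivated the scanner; stems of at least 6
#' pairs; loops of 3-20 nt; at most 1 stem mismatch) are exposed here and
#' recorded in every report.
#'
#' @param min_poly minimum homopolymer tract length.
#' @param poly_base tract base.
#' @param min_stem,loop_range,max_mismatch,gu_pairs see [find_stem_loops()].
#' @param motifs,ta_min_n see [find_motifs()].
#' @return named list of parameters.
#' @export
cr_scan_config <- function(min_poly = 10, poly_base = "T", min_stem = 6,
                           loop_range = c(3, 20), max_mismatch = 1,
                           gu_pairs = FALSE, motifs = c("GAAT", "(TA)n"),
                           ta_min_n = 3) {
  list(min_poly = min_poly, poly_base = poly_base, min_stem = min_stem,
       loop_range = loop_range, max_mismatch = max_mismatch,
       gu_pairs = gu_pairs, motifs = motifs, ta_min_n = ta_min_n)
}

#' Structural scan of the A+T-rich control region
#'
#' Locates the control-region feature, reports its length and AT content,
#' all qualifying poly-T (or configured base) tracts, stem-loops downstream
#' of the first qualifying tract (higher reference-strand coordinate within
#' the region, where such structures are described in insect control
#' regions), and flanking motifs. All elements carry both region-relative
#' and genome-absolute coordinates.
#'
#' @param genome a [mito_genome()] with sequence and annotation.
#' @param config a [cr_scan_config()].
#' @return list of class \code{cr_scan}: \code{region} (name, start, end,
#'   length, at_content), \code{poly_tracts}, \code{stem_loops} (downstream
#'   of the first tract; \code{stem_loops_all} holds the unfiltered scan),
#'   \code{motifs}, \code{config}, \code{findings}. With no control-region
#'   feature the report is empty and carries one finding.
#' @export
scan_control_region <- function(genome, config = cr_scan_config()) {
  stopifnot(inherits(genome, "mito_genome"))
  ann <- genome$annotation
  empty <- structure(list(region = NULL,
                          poly_tracts = find_poly_tracts("A", "T", 1),
                          stem_loops = empty_stem_loops(),
                          stem_loops_all = empty_stem_loops(),
                          motifs = find_motifs("A", character()),
                          config = config,
                          findings = character()), class = "cr_scan")
  if (is.null(ann) || !any(ann$class == "control_region")) {
    empty$findings <- "no control_region feature annotated"
    return(empty)
  }
  if (is.null(genome$sequence)) {
    empty$findings <- "genome carries no sequence"
    return(empty)
  }
  cr <- ann[which(ann$class == "control_region")[1L], ]
  seq <- extract_feature_sequence(genome, cr)
  glen <- attr(ann, "genome_length")
  abs_pos <- function(p) (cr$start + p - 2L) %% glen + 1L

  tracts <- find_poly_tracts(seq, config$poly_base, config$min_poly)
  if (nrow(tracts)) tracts$abs_start <- abs_pos(tracts$start)
  else tracts$abs_start <- integer()

  sl <- find_stem_loops(seq, config$min_stem, config$loop_range,
                        config$max_mismatch, config$gu_pairs)
  if (nrow(sl)) {
    sl$abs_arm5_start <- abs_pos(sl$arm5_start)
    sl$abs_arm3_end <- abs_pos(sl$arm3_end)
  } else {
    sl$abs_arm5_start <- integer(); sl$abs_arm3_end <- integer()
  }
  sl_down <- if (nrow(tracts)) {
    cut <- tracts$start[1L] + tracts$length[1L] - 1L
    sl[sl$arm5_start > cut, , drop = FALSE]
  } else sl

  motifs <- find_motifs(seq, config$motifs, config$ta_min_n)
  if (nrow(motifs)) motifs$abs_start <- abs_pos(motifs$start)
  else motifs$abs_start <- integer()

  comp <- base_composition(seq, cr$name)
  structure(list(
    region = list(name = cr$name, start = cr$start, end = cr$end,
                  length = feature_length(cr$start, cr$end, glen,
                                          attr(ann, "circular")),
                  at_content = comp$at_content),
    poly_tracts = tracts, stem_loops = sl_down, stem_loops_all = sl,
    motifs = motifs, config = config, findings = character()),
    class = "cr_scan")
}

#' @export
print.cr_scan <- function(x, ...) {
  if (is.null(x$region)) {
    cat("Control-region scan: empty report\n")
    if (length(x$findings)) cat("  finding:", x$findings, "\n")
    return(invisible(x))
  }
  cat(sprintf("Control region %s: %d..%d (%d nt, A+T %.1f%%)\n",
              x$region$name, x$region$start, x$region$end, x$region$length,
              round_half_up(x$region$at_content, 1)))
  cat(sprintf("  poly-%s tracts (>= %d nt): %d\n", x$config$poly_base,
              x$config$min_poly, nrow(x$poly_tracts)))
  cat(sprintf("  stem-loops downstream of first tract: %d (of %d in region)\n",
              nrow(x$stem_loops), nrow(x$stem_loops_all)))
  cat(sprintf("  motif hits: %d\n", nrow(x$motifs)))
  invisible(x)
}
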