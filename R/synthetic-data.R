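## Synthetic annotated mitogenomes and tree-evolved protein alignments with
## recorded ground truth, so every analysis stage can be tested end-to-end
## without external sequence downloads.

# 31-bit polynomial rolling hash of a character vector, for spec fingerprints
spec_hash <- function(x) {
  b <- utf8ToInt(paste(x, collapse = "\r"))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

# sample n bases with P(A)=P(T)=at/2, P(G)=P(C)=(1-at)/2; with exact=TRUE a
# random permutation of the closest integer base composition is returned, so
# long payloads realise their AT target to within one base
sample_bases <- function(n, at, exact = FALSE) {
  if (n <= 0L) return(character())
  if (!exact)
    return(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                  prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)))
  n_a <- round(n * at / 2)
  n_t <- round(n * at) - n_a
  n_g <- round(n * (1 - at) / 2)
  n_c <- n - n_a - n_t - n_g
  sample(c(rep("A", n_a), rep("T", n_t), rep("G", n_g), rep("C", n_c)))
}

# Sample n_codons codons base-wise, rejecting stop codons. Rejection removes
# AT-rich codons (TAA, TAG), so the base-level AT is raised to the value
# whose post-rejection expectation equals the requested target.
codon_at_for_target <- function(at) {
  cond_at <- function(x) {
    p_taa <- (x / 2)^3
    p_tag <- (x / 2)^2 * (1 - x) / 2
    (3 * x - 3 * p_taa - 2 * p_tag) / (3 * (1 - p_taa - p_tag))
  }
  if (at <= 0 || at >= 1) return(at)
  stats::uniroot(function(x) cond_at(x) - at, c(at, min(1, at + 0.1)),
                 tol = 1e-10)$root
}

sample_codons <- function(n_codons, at, stops = c("TAA", "TAG")) {
  if (n_codons <= 0L) return(character())
  at <- codon_at_for_target(at)
  out <- paste0(sample_bases(n_codons, at),
                sample_bases(n_codons, at),
                sample_bases(n_codons, at))
  bad <- out %in% stops
  while (any(bad)) {
    out[bad] <- paste0(sample_bases(sum(bad), at),
                       sample_bases(sum(bad), at),
                       sample_bases(sum(bad), at))
    bad <- out %in% stops
  }
  out
}

#' Default gene plan for the synthetic generator
#'
#' The 38-feature arrangement (37 genes plus control region) of the typical
#' stonefly mitogenome: names, classes, strands, coordinate-derived lengths,
#' the boundary IGN profile (including the negative, overlapping boundaries)
#' and protein start/stop codons, taken from the packaged annotation table.
#'
#' @return data frame with columns \code{name}, \code{class}, \code{strand},
#'   \code{length}, \code{ign_before} (IGN to the previous feature; first row
#'   is the circular wrap boundary), \code{start_codon}, \code{stop_codon}.
#' @export
default_gene_plan <- function() {
  ann <- kwangi_annotation()
  data.frame(name = ann$name, class = ann$class, strand = ann$strand,
             length = feature_lengths(ann),
             ign_before = intergenic_table(ann)$ign,
             start_codon = ann$start_codon, stop_codon = ann$stop_codon,
             stringsAsFactors = FALSE)
}

#' Control-region plan for the synthetic generator
#'
#' Placement plan for the structural elements described in insect A+T-rich
#' regions: one poly-T tract, two stem-loops downstream of it, a (TA)n run
#' and GAAT motifs in the flanking regions. Offsets are fractions of the
#' region length.
#'
#' @param poly_t tract length (default 10, the observed tract length).
#' @param hairpins list of \code{list(stem, loop)} pairs.
#' @param ta_n repeats of the planted (TA)n run.
#' @param n_gaat number of planted GAAT motifs.
#' @return named list.
#' @export
cr_plan <- function(poly_t = 10,
                    hairpins = list(list(stem = 12, loop = 6),
                                    list(stem = 10, loop = 8)),
                    ta_n = 5, n_gaat = 2) {
  list(poly_t = as.integer(poly_t),
       hairpins = lapply(hairpins, function(h)
         list(stem = as.integer(h$stem), loop = as.integer(h$loop))),
       ta_n = as.integer(ta_n), n_gaat = as.integer(n_gaat))
}

#' Specification of a synthetic mitogenome
#'
#' The generator's defaults emulate the annotated stonefly mitogenome this
#' package ships: the 37-gene + control-region arrangement with its real
#' overlap/IGN profile, per-class AT targets matching the published
#' composition (protein genes 68%, tRNAs 72%, rRNAs 71%, A+T-rich region
#' 78%, spacers 70%), and a control region carrying a 10 nt poly-T tract,
#' two downstream stem-loops and (TA)n / GAAT motifs.
#'
#' @param gene_plan data frame as in [default_gene_plan()]; lengths and
#'   \code{ign_before} must telescope to the genome length, and overlaps
#'   may not exceed either flanking gene.
#' @param at_targets named vector of AT fractions per feature class
#'   (\code{PCG}, \code{tRNA}, \code{rRNA}, \code{control_region},
#'   \code{intergenic}).
#' @param control_plan a [cr_plan()].
#' @param scan_config the [cr_scan_config()] the planted truth is guaranteed
#'   against.
#' @param seed single integer governing all randomness.
#' @return object of class \code{genome_spec}.
#' @export
genome_spec <- function(gene_plan = default_gene_plan(),
                        at_targets = c(PCG = 0.68, tRNA = 0.72,
                                       rRNA = 0.71, control_region = 0.78,
                                       intergenic = 0.70),
                        control_plan = cr_plan(),
                        scan_config = cr_scan_config(),
                        seed = 1) {
  stopifnot(is.data.frame(gene_plan),
            all(c("name", "class", "strand", "length", "ign_before")
                %in% names(gene_plan)))
  n <- nrow(gene_plan)
  len <- gene_plan$length; ign <- gene_plan$ign_before
  if (any(len < 1)) stop("gene lengths must be positive", call. = FALSE)
  prev_len <- c(len[n], len[-n])
  bad <- -ign >= pmin(len, prev_len)
  if (any(bad))
    stop("infeasible spec: overlap longer than a flanking gene at ",
         paste(gene_plan$name[bad], collapse = ", "), call. = FALSE)
  pcg <- gene_plan$class == "PCG"
  if (any(len[pcg] %% 3L != 0L))
    stop("infeasible spec: PCG length not divisible by 3 for ",
         paste(gene_plan$name[pcg & len %% 3L != 0L], collapse = ", "),
         call. = FALSE)
  structure(list(gene_plan = gene_plan, at_targets = at_targets,
                 control_plan = control_plan, scan_config = scan_config,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# ---- control-region construction ------------------------------------------

# Build a control-region segment with planted elements and a truth record.
# background "at_rich": i.i.d. bases at the given AT fraction; "ac": the
# non-self-complementary {A, C} scaffold on which detected structure can only
# be planted structure. Chance poly-tracts and motifs are always scrubbed so
# those element sets are exactly the planted ones; chance stem-loops are
# scrubbed only in exact_hairpins mode (feasible on the "ac" scaffold, not on
# a realistic AT-rich background, where planted hairpins are guaranteed as a
# subset of the scan).
build_control_region <- function(length, plan = cr_plan(),
                                 config = cr_scan_config(),
                                 background = c("at_rich", "ac"),
                                 at = 0.78,
                                 exact_hairpins = (background == "ac")) {
  background <- match.arg(background)
  L <- as.integer(length)
  block <- as.integer(config$max_mismatch) + 1L  # extension blocking depth
  for (attempt in 1:20) {
    chars <- if (background == "ac")
      sample(c("A", "C"), L, replace = TRUE)
    else sample_bases(L, at, exact = TRUE)
    protected <- logical(L)
    truth <- list(poly_tracts = NULL, hairpins = NULL, motifs = NULL)
    place <- function(at_pos, payload, margin = 0L) {
      idx <- at_pos:(at_pos + length(payload) - 1L)
      span <- max(1L, at_pos - margin):min(L, at_pos + length(payload) - 1L +
                                             margin)
      if (any(protected[span])) return(FALSE)
      chars[idx] <<- payload
      protected[span] <<- TRUE
      TRUE
    }
    ok <- TRUE

    # poly-T tract, flanked by A so the run is exactly the planted length
    p1 <- max(2L, as.integer(round(0.12 * L)))
    tlen <- plan$poly_t
    payload <- c("A", rep(config$poly_base, tlen), "A")
    if (p1 + length(payload) - 1L > L) stop("control region too short",
                                            call. = FALSE)
    ok <- ok && place(p1, payload)
    truth$poly_tracts <- data.frame(base = config$poly_base,
                                    start = p1 + 1L, length = tlen)
    tract_end <- p1 + tlen

    # stem-loops downstream of the tract, blocked against outward extension
    hp_fracs <- seq(0.35, 0.75, length.out = max(1L, length(plan$hairpins)))
    hp_rows <- list()
    for (h in seq_along(plan$hairpins)) {
      hp <- plan$hairpins[[h]]
      span <- 2L * block + 2L * hp$stem + hp$loop
      pos <- as.integer(round(hp_fracs[h] * L))
      arm5 <- NULL
      # how deep a smaller-loop candidate could reach into this loop while
      # keeping an admissible loop; those end pairs must not be complementary
      # or such a candidate would dominate the planted hairpin
      tmax <- max(0L, (hp$loop - config$loop_range[1L]) %/% 2L)
      for (try in 1:80) {   # arms free of motif-like substrings
        cand <- sample_bases(hp$stem, if (background == "ac") 0.5 else at)
        loop <- if (background == "ac")
          sample(c("A", "C"), hp$loop, replace = TRUE)
        else sample_bases(hp$loop, at)
        if (tmax > 0L) {
          t <- seq_len(tmax)
          if (any(wc_pair(loop[t], loop[hp$loop - t + 1L],
                          config$gu_pairs))) next
        }
        hairpin <- c(cand, loop,
                     strsplit(reverse_complement(paste(cand, collapse = "")),
                              "")[[1]])
        s <- paste(hairpin, collapse = "")
        if (!grepl("GAAT", s) && !grepl("(TA){3,}", s) &&
            !grepl(strrep(config$poly_base, config$min_poly), s)) {
          arm5 <- cand; break
        }
      }
      if (is.null(arm5)) { ok <- FALSE; break }
      payload <- c(rep("A", block), hairpin, rep("A", block))
      if (pos + length(payload) - 1L > L || pos <= tract_end) {
        ok <- FALSE; break
      }
      if (!place(pos, payload)) { ok <- FALSE; break }
      a5s <- pos + block
      hp_rows[[h]] <- data.frame(
        arm5_start = a5s, arm5_end = a5s + hp$stem - 1L,
        arm3_start = a5s + hp$stem + hp$loop,
        arm3_end = a5s + 2L * hp$stem + hp$loop - 1L,
        stem_length = hp$stem, loop_length = hp$loop, mismatches = 0L)
    }
    if (!ok) next
    truth$hairpins <- if (length(hp_rows))
      `rownames<-`(do.call(rbind, hp_rows), NULL)
      else empty_stem_loops()[, 1:7]

    # motifs: a (TA)n run and GAAT copies in the flanking regions
    mot_rows <- list()
    ta <- c("C", "C", rep(c("T", "A"), plan$ta_n), "C", "C")
    pos <- as.integer(round(0.27 * L))
    while (pos < L - length(ta) && !place(pos, ta)) pos <- pos + 3L
    if (pos >= L - length(ta)) next
    mot_rows[[1]] <- data.frame(motif = "(TA)n", start = pos + 2L,
                                length = 2L * plan$ta_n, n = plan$ta_n)
    if (plan$n_gaat > 0) {
      gfr <- seq(0.88, 0.95, length.out = plan$n_gaat)
      gaat_ok <- TRUE
      for (gi in seq_len(plan$n_gaat)) {
        ga <- c("C", "G", "A", "A", "T", "C")
        pos <- as.integer(round(gfr[gi] * L))
        while (pos < L - length(ga) && !place(pos, ga)) pos <- pos + 2L
        if (pos >= L - length(ga)) { gaat_ok <- FALSE; break }
        mot_rows[[length(mot_rows) + 1L]] <-
          data.frame(motif = "GAAT", start = pos + 1L, length = 4L,
                     n = NA_integer_)
      }
      if (!gaat_ok) next
    }
    truth$motifs <- do.call(rbind, mot_rows)
    truth$motifs <- truth$motifs[order(truth$motifs$start), , drop = FALSE]
    rownames(truth$motifs) <- NULL

    chars2 <- scrub_region(chars, protected, truth, config, exact_hairpins)
    if (is.null(chars2)) next
    return(list(seq = paste(chars2, collapse = ""), truth = truth,
                protected = protected))
  }
  stop("could not realise the control-region plan (region too short or ",
       "too constrained)", call. = FALSE)
}

# Remove chance tracts/motifs (always) and chance stem-loops (exact mode)
# outside the protected planted intervals. Returns NULL if not possible.
scrub_region <- function(chars, protected, truth, config, exact_hairpins) {
  key <- function(df) if (nrow(df))
    paste(df[[1]], df[[2]], df[[3]], sep = "/") else character()
  hp_key <- function(df) if (nrow(df))
    paste(df$arm5_start, df$stem_length, df$loop_length, sep = "/")
    else character()
  for (iter in 1:80) {
    seq <- paste(chars, collapse = "")
    mutate_at <- integer(); mutate_to <- character()
    # AT-preserving stray removal: break homopolymer and TA runs by flipping
    # a T to A (or A to T), and GAAT by flipping its G to A, so scrubbing
    # does not erode the region's AT target
    plan_mut <- function(pos) {
      free <- pos[!protected[pos]]
      if (!length(free)) return(FALSE)
      g <- free[chars[free] == "G"]
      p <- if (length(g)) g[1L] else free[(length(free) + 1L) %/% 2L]
      to <- switch(chars[p], G = "A", C = "A", T = "A", A = "T")
      mutate_at <<- c(mutate_at, p); mutate_to <<- c(mutate_to, to)
      TRUE
    }
    clean <- TRUE
    tr <- find_poly_tracts(seq, config$poly_base, config$min_poly)
    for (i in seq_len(nrow(tr)))
      if (!paste(tr$base[i], tr$start[i], tr$length[i], sep = "/") %in%
          key(truth$poly_tracts)) {
        clean <- FALSE
        if (!plan_mut(tr$start[i]:(tr$start[i] + tr$length[i] - 1L)))
          return(NULL)
      }
    mo <- find_motifs(seq, config$motifs, config$ta_min_n)
    for (i in seq_len(nrow(mo)))
      if (!paste(mo$motif[i], mo$start[i], mo$length[i], sep = "/") %in%
          paste(truth$motifs$motif, truth$motifs$start,
                truth$motifs$length, sep = "/")) {
        clean <- FALSE
        if (!plan_mut(mo$start[i]:(mo$start[i] + mo$length[i] - 1L)))
          return(NULL)
      }
    if (exact_hairpins) {
      sl <- find_stem_loops(seq, config$min_stem, config$loop_range,
                            config$max_mismatch, config$gu_pairs)
      for (i in seq_len(nrow(sl)))
        if (!hp_key(sl[i, ]) %in% hp_key(truth$hairpins)) {
          clean <- FALSE
          stem_pos <- c(sl$arm5_start[i]:sl$arm5_end[i],
                        sl$arm3_start[i]:sl$arm3_end[i])
          free <- stem_pos[!protected[stem_pos]]
          if (!length(free)) return(NULL)
          p <- free[1L]
          # partner across the stem
          partner <- if (p <= sl$arm5_end[i])
            chars[sl$arm3_start[i] + (sl$arm5_end[i] - p)]
          else chars[sl$arm5_end[i] - (p - sl$arm3_start[i])]
          mutate_at <- c(mutate_at, p)
          mutate_to <- c(mutate_to,
                         if (partner %in% c("G", "C")) "A" else "C")
        }
    }
    if (clean) return(chars)
    if (!length(mutate_at)) return(NULL)
    chars[mutate_at] <- mutate_to
  }
  NULL
}

#' Plant control-region elements in a synthetic segment
#'
#' Standalone access to the generator's control-region builder: returns a
#' sequence of the requested length with a planted poly-T tract, stem-loops,
#' a (TA)n run and GAAT motifs, together with the truth record of their
#' coordinates. On the \code{"ac"} scaffold (a background over {A, C}, which
#' admits no Watson-Crick self-pairing) the detected element sets equal the
#' planted truth exactly; on the realistic \code{"at_rich"} background,
#' tract and motif sets are exact and planted hairpins are guaranteed to be
#' among those detected.
#'
#' @param length segment length (>= ~200 for the default plan).
#' @param plan a [cr_plan()].
#' @param config the [cr_scan_config()] the truth is guaranteed against.
#' @param background \code{"at_rich"} or \code{"ac"}.
#' @param at AT fraction of the at_rich background.
#' @param seed optional integer; \code{NULL} uses the current RNG state.
#' @return list with \code{seq} and \code{truth} (data frames
#'   \code{poly_tracts}, \code{hairpins}, \code{motifs}).
#' @export
plant_control_region <- function(length, plan = cr_plan(),
                                 config = cr_scan_config(),
                                 background = c("at_rich", "ac"),
                                 at = 0.78, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- build_control_region(length, plan, config, match.arg(background),
                              at)
  list(seq = out$seq, truth = out$truth)
}

# ---- whole-genome construction --------------------------------------------

#' Generate a synthetic annotated mitogenome
#'
#' Builds a circular genome realising the spec exactly: coordinates telescope
#' from the gene-length and IGN profile (overlaps realised base-for-base),
#' protein-coding genes carry the planned initiator and terminator codons
#' and no internal stop codons under the invertebrate mitochondrial code
#' (overlap-induced conflicts are repaired deterministically), the control
#' region contains the planted structural elements at recorded coordinates,
#' and nucleotide sampling honours the per-class AT targets in expectation.
#' Every generated genome passes [validate_annotation()] with no findings.
#'
#' @param spec a [genome_spec()].
#' @return list with \code{genome} (a [mito_genome()]) and \code{truth}
#'   (coordinates, per-PCG codons, control-region elements in absolute
#'   coordinates, seed and spec hash).
#' @export
generate_mitogenome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  plan <- spec$gene_plan
  at <- spec$at_targets
  n <- nrow(plan)
  glen <- sum(plan$length) + sum(plan$ign_before)
  start <- integer(n); end <- integer(n)
  pos <- plan$ign_before[1L]           # end of virtual previous feature
  for (i in seq_len(n)) {
    start[i] <- pos + 1L
    end[i] <- start[i] + plan$length[i] - 1L
    pos <- end[i] + if (i < n) plan$ign_before[i + 1L] else 0L
  }
  if (end[n] + plan$ign_before[1L] != glen)
    stop("gene plan does not telescope to a consistent genome length",
         call. = FALSE)

  chars <- sample_bases(glen, at[["intergenic"]])
  put <- function(idx, payload) chars[idx] <<- payload
  span_idx <- function(i) start[i]:end[i]

  # structural RNAs first; protein payloads and codon stamps overwrite later
  for (i in which(plan$class %in% c("tRNA", "rRNA"))) {
    payload <- sample_bases(plan$length[i], at[[plan$class[i]]],
                            exact = TRUE)
    put(span_idx(i), payload)
  }

  # control region with planted elements
  cr_truth <- NULL
  cri <- which(plan$class == "control_region")
  if (length(cri)) {
    cri <- cri[1L]
    cr <- build_control_region(plan$length[cri], spec$control_plan,
                               spec$scan_config, "at_rich",
                               at[["control_region"]],
                               exact_hairpins = FALSE)
    put(span_idx(cri), strsplit(cr$seq, "", fixed = TRUE)[[1]])
    shift <- function(df, cols) { df[cols] <- df[cols] + start[cri] - 1L; df }
    cr_truth <- list(
      region = c(start = start[cri], end = end[cri]),
      poly_tracts = shift(cr$truth$poly_tracts, "start"),
      hairpins = shift(cr$truth$hairpins,
                       c("arm5_start", "arm5_end", "arm3_start", "arm3_end")),
      motifs = shift(cr$truth$motifs, "start"))
  }

  code <- genetic_code(5)
  stops <- code$families[["*"]]
  pcgs <- which(plan$class == "PCG")
  ref_positions <- function(i, coding_pos) {
    # reference positions of coding positions (vector), honouring strand
    if (plan$strand[i] == "J") start[i] + coding_pos - 1L
    else end[i] - coding_pos + 1L
  }
  write_coding <- function(i, coding_pos, bases) {
    if (plan$strand[i] == "J") put(ref_positions(i, coding_pos), bases)
    else put(ref_positions(i, coding_pos),
             vapply(bases, function(b)
               c(A = "T", T = "A", G = "C", C = "G")[[b]], character(1)))
  }
  for (i in pcgs) {
    ncod <- plan$length[i] %/% 3L
    codons <- c(plan$start_codon[i],
                sample_codons(ncod - 2L, at[["PCG"]], stops),
                plan$stop_codon[i])
    bases <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
    write_coding(i, seq_len(plan$length[i]), bases)
  }

  # stamp pass: start/stop codons of every PCG are authoritative
  stamped <- logical(glen)
  for (i in pcgs) {
    for (cp in list(1:3, (plan$length[i] - 2L):plan$length[i])) {
      codon <- if (cp[1L] == 1L) plan$start_codon[i] else plan$stop_codon[i]
      write_coding(i, cp, strsplit(codon, "", fixed = TRUE)[[1]])
      stamped[ref_positions(i, cp)] <- TRUE
    }
  }

  # repair pass: clear internal stops created by overlap interactions
  comp1 <- c(A = "T", T = "A", G = "C", C = "G")
  for (iter in 1:50) {
    dirty <- FALSE
    for (i in pcgs) {
      cs <- if (plan$strand[i] == "J")
        paste(chars[span_idx(i)], collapse = "")
      else reverse_complement(paste(chars[span_idx(i)], collapse = ""))
      ncod <- nchar(cs) %/% 3L
      codons <- substring(cs, seq(1L, nchar(cs), 3L), seq(3L, nchar(cs), 3L))
      bad <- which(codons %in% stops)
      bad <- bad[bad > 1L & bad < ncod]
      if (!length(bad)) next
      dirty <- TRUE
      b <- bad[1L]
      cps <- (3L * b - 2L):(3L * b)    # coding positions of the codon
      refs <- ref_positions(i, cps)
      free <- which(!stamped[refs])
      if (!length(free))
        stop("cannot repair internal stop codon in ", plan$name[i],
             call. = FALSE)
      # choose replacement coding base killing the stop (TAA/TAG -> C??/
      # T?T/TC?) at the first free codon position
      slot <- free[1L]
      newbase <- c("C", "C", "T")[slot]
      coding_base <- if (plan$strand[i] == "J") newbase else newbase
      write_coding(i, cps[slot], coding_base)
    }
    if (!dirty) break
    if (iter == 50L)
      stop("internal-stop repair did not converge", call. = FALSE)
  }

  features <- data.frame(name = plan$name, class = plan$class,
                         start = start, end = end, strand = plan$strand,
                         start_codon = plan$start_codon,
                         stop_codon = plan$stop_codon,
                         anticodon = NA_character_, notes = "",
                         stringsAsFactors = FALSE)
  ann <- annotation_table(features, genome_length = glen, circular = TRUE)
  genome <- mito_genome(paste(chars, collapse = ""), ann,
                        identifier = sprintf("synthetic-%d", spec$seed))
  truth <- list(
    coordinates = data.frame(name = plan$name, start = start, end = end,
                             strand = plan$strand, stringsAsFactors = FALSE),
    ign_profile = plan$ign_before,
    codons = data.frame(gene = plan$name[pcgs],
                        start_codon = plan$start_codon[pcgs],
                        stop_codon = plan$stop_codon[pcgs],
                        stringsAsFactors = FALSE),
    control_region = cr_truth,
    at_targets = at,
    seed = spec$seed,
    spec_hash = spec_hash(c(deparse(plan), deparse(at),
                        deparse(spec$control_plan), spec$seed)))
  list(genome = genome, truth = truth)
}

#' Export a synthetic genome with its truth sidecar
#'
#' Writes the genome as GenBank flat file, FASTA and annotation TSV, plus a
#' JSON sidecar holding the generator truth record (coordinates, codons,
#' planted control-region elements, seed, spec hash).
#'
#' @param sim result of [generate_mitogenome()].
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisibly, the vector of files written.
#' @export
export_synthetic_genome <- function(sim, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(dir, paste0(stem, ".gb"))
  fa <- file.path(dir, paste0(stem, ".fasta"))
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  js <- file.path(dir, paste0(stem, ".truth.json"))
  write_genbank(sim$genome, gb)
  write_fasta(stats::setNames(sim$genome$sequence,
                              sim$genome$identifier), fa)
  write_annotation_tsv(sim$genome$annotation, tsv)
  jsonlite::write_json(sim$truth, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(gb, fa, tsv, js))
}

# ---- tree-evolved protein alignments --------------------------------------

#' Guide tree of the thirteen-taxon study design
#'
#' A 13-taxon unrooted guide tree over the insect taxa of the comparative
#' mitogenome set (two stoneflies, a mayfly, ten other orders including the
#' damselfly outgroup), with the (stonefly1, stonefly2) + mayfly clade
#' embedded, for simulating alignments whose true topology is known.
#'
#' @return an \code{ape} \code{phylo} tree with branch lengths.
#' @export
default_guide_tree <- function() {
  ape::read.tree(text = paste0(
    "(Euphaea_formosa:0.30,(((Kamimuria_wangi:0.08,",
    "Pteronarcys_princeps:0.09):0.06,Siphlonurus_immanis:0.16):0.05,",
    "((((Blattella_germanica:0.12,Tamolanica_tamolana:0.11):0.04,",
    "(Sclerophasma_paresisense:0.13,Ramulus_hainanense:0.14):0.03):0.03,",
    "Schistocerca_gregaria:0.18):0.02,(Aposthonia_japonica:0.20,",
    "(Schizaphis_graminum:0.22,Orussus_occidentalis:0.21):0.05):0.03):0.02)",
    ":0.04,Ochrogaster_lunifer:0.25);"))
}

#' Default per-gene protein lengths
#'
#' Amino-acid lengths of the 13 mitochondrial protein-coding genes (stop
#' codon excluded), matching the coordinate-derived gene lengths of the
#' packaged annotation.
#'
#' @return named integer vector in canonical gene order.
#' @export
default_gene_lengths <- function() {
  ann <- kwangi_annotation()
  pcg <- ann$class == "PCG"
  len <- feature_lengths(ann)[pcg] %/% 3L - 1L
  stats::setNames(len, ann$name[pcg])[pcg_gene_order()]
}

#' Specification of a tree-evolved protein alignment set
#'
#' A simple equal-rates replacement process: along a branch of length
#' \eqn{b}, each site is replaced with probability \eqn{1 - (1 - \mu)^b}
#' (so replacement probabilities compose along paths), the new residue drawn
#' uniformly from the other 19 amino acids. Gap-free by construction. This
#' is deliberately not a biological substitution model (no JTT/WAG
#' exchangeabilities); it suffices to give the simulated data a known true
#' topology.
#'
#' @param tree guide \code{phylo} tree (or newick string) with nonnegative
#'   branch lengths.
#' @param gene_lengths named integer vector of per-gene protein lengths.
#' @param mu replacement probability per site per unit branch length, in
#'   [0, 1).
#' @param seed integer seed.
#' @return object of class \code{evolution_spec}.
#' @export
evolution_spec <- function(tree = default_guide_tree(),
                           gene_lengths = default_gene_lengths(),
                           mu = 0.5, seed = 1) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("guide tree needs nonnegative branch lengths", call. = FALSE)
  if (length(tree$tip.label) < 2L) stop("guide tree has no taxa",
                                        call. = FALSE)
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)", call. = FALSE)
  stopifnot(length(gene_lengths) >= 1L, !is.null(names(gene_lengths)))
  structure(list(tree = tree, gene_lengths = gene_lengths, mu = mu,
                 seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Evolve protein alignments along a guide tree
#'
#' Root sequences are drawn uniformly over the 20 amino acids and evolved
#' down the tree under the spec's replacement process, yielding one gap-free
#' alignment per gene plus the truth tree. Reproducible under the seed.
#'
#' @param spec an [evolution_spec()].
#' @return list with \code{alignments} (named list of
#'   [protein_alignment()]), \code{tree} (the guide tree) and \code{seed}.
#' @export
evolve_alignment <- function(spec = evolution_spec()) {
  stopifnot(inherits(spec, "evolution_spec"))
  set.seed(spec$seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tree <- ape::reorder.phylo(spec$tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE]
  elen <- rev(tree$edge.length)        # preorder: parent before child
  alns <- vector("list", length(spec$gene_lengths))
  names(alns) <- names(spec$gene_lengths)
  for (g in seq_along(spec$gene_lengths)) {
    nsite <- spec$gene_lengths[[g]]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(aas, nsite, replace = TRUE)
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      s <- seqs[[parent]]
      p <- 1 - (1 - spec$mu)^elen[e]
      hit <- which(stats::runif(nsite) < p)
      if (length(hit)) {
        repl <- aas[(match(s[hit], aas) - 1L +
                       sample.int(19L, length(hit), replace = TRUE)) %% 20L
                    + 1L]
        s[hit] <- repl
      }
      seqs[[child]] <- s
    }
    rows <- vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    names(rows) <- tree$tip.label
    alns[[g]] <- protein_alignment(rows)
  }
  list(alignments = alns, tree = spec$tree, seed = spec$seed)
}
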