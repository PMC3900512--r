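#' Construct a gene feature
#'
#' A single annotated feature on a (possibly circular) mitochondrial genome.
#' Coordinates are 1-based and inclusive on the reference (J, majority) strand,
#' the convention of published mitogenome annotation tables. Features encoded
#' on the minority strand carry strand \code{"N"}. A wrapping feature (one that
#' crosses the linearisation origin of a circular genome) has \code{end <
#' start}.
#'
#' @param name gene identifier, e.g. \code{"COI"}, \code{"tRNA-Ser(AGN)"},
#'   \code{"lrRNA"}, \code{"CR"}.
#' @param feature_class one of \code{"PCG"}, \code{"tRNA"}, \code{"rRNA"},
#'   \code{"control_region"}.
#' @param start,end 1-based inclusive positions on the reference strand.
#' @param strand \code{"J"} (majority) or \code{"N"} (minority).
#' @param start_codon,stop_codon optional codons for protein-coding genes.
#' @param anticodon optional 3-mer for tRNAs.
#' @param notes free text.
#' @return A one-row data frame with the feature's fields.
#' @export
gene_feature <- function(name, feature_class, start, end, strand = "J",
                         start_codon = NA_character_,
                         stop_codon = NA_character_,
                         anticodon = NA_character_, notes = "") {
  stopifnot(is.character(name), length(name) == 1L)
  feature_class <- match.arg(feature_class,
                             c("PCG", "tRNA", "rRNA", "control_region"))
  strand <- match.arg(strand, c("J", "N"))
  if (!is.numeric(start) || !is.numeric(end) || start < 1 || end < 1)
    stop("feature coordinates must be positive integers", call. = FALSE)
  data.frame(name = name, class = feature_class,
             start = as.integer(start), end = as.integer(end),
             strand = strand, start_codon = start_codon,
             stop_codon = stop_codon, anticodon = anticodon,
             notes = notes, stringsAsFactors = FALSE)
}

#' Assemble an annotation table
#'
#' Binds gene features into an ordered annotation table (ascending start, the
#' order of a printed annotation table) and attaches the genome length and
#' circularity flag.
#'
#' @param features a data frame of features as built by [gene_feature()]
#'   (rows may be supplied in any order; they are kept as given, and should
#'   follow ascending start for the intergenic arithmetic to be meaningful).
#' @param genome_length total genome size in nucleotides.
#' @param circular logical; circular genomes admit a wrap boundary between the
#'   last and first feature and wrapping features.
#' @return An object of class \code{annotation_table}: the feature data frame
#'   with attributes \code{genome_length} and \code{circular}.
#' @export
annotation_table <- function(features, genome_length, circular = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  needed <- c("name", "class", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing))
    stop("features lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (!col %in% names(features)) features[[col]] <- NA_character_
  if (!"notes" %in% names(features)) features$notes <- ""
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 1L)
  bad <- features$start < 1L | features$start > genome_length |
    features$end < 1L | features$end > genome_length
  if (any(bad))
    stop("feature coordinates outside [1, genome_length] for: ",
         paste(features$name[bad], collapse = ", "), call. = FALSE)
  if (!circular && any(features$end < features$start))
    stop("end < start only permitted on circular genomes (wrapping feature)",
         call. = FALSE)
  structure(features, genome_length = genome_length,
            circular = isTRUE(circular),
            class = c("annotation_table", "data.frame"))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("Annotation table: %d features, genome %d nt (%s)\n",
              nrow(x), attr(x, "genome_length"),
              if (attr(x, "circular")) "circular" else "linear"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct an annotated mitochondrial genome
#'
#' @param sequence nucleotide string (reference / J strand), or \code{NULL}
#'   when only annotation arithmetic is needed.
#' @param annotation an [annotation_table()].
#' @param identifier accession or free label.
#' @return An object of class \code{mito_genome}.
#' @export
mito_genome <- function(sequence = NULL, annotation = NULL,
                        identifier = "genome") {
  if (!is.null(sequence)) {
    sequence <- normalize_codon(sequence)
    if (!is.null(annotation) &&
        nchar(sequence) != attr(annotation, "genome_length"))
      stop("sequence length (", nchar(sequence),
           ") disagrees with annotation genome_length (",
           attr(annotation, "genome_length"), ")", call. = FALSE)
  }
  structure(list(sequence = sequence, annotation = annotation,
                 identifier = identifier),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("Mitochondrial genome:", x$identifier, "\n")
  if (!is.null(x$sequence)) cat("  sequence:", nchar(x$sequence), "nt\n")
  if (!is.null(x$annotation))
    cat("  annotation:", nrow(x$annotation), "features,",
        attr(x$annotation, "genome_length"), "nt,",
        if (attr(x$annotation, "circular")) "circular" else "linear", "\n")
  invisible(x)
}

#' Length of a feature on a possibly circular genome
#'
#' For a non-wrapping feature the length is \code{end - start + 1}. A wrapping
#' feature (\code{end < start}) is only meaningful on a circular genome and
#' spans \code{genome_length - start + 1 + end} nucleotides.
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @param genome_length genome size; required for wrapping features.
#' @param circular logical; wrapping only permitted when \code{TRUE}.
#' @return integer vector of lengths.
#' @examples
#' feature_length(1397, 2983)            # 1587
#' feature_length(16170, 10, 16179, TRUE)  # 20, crossing the origin
#' @export
feature_length <- function(start, end, genome_length = NULL,
                           circular = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < 1L))
    stop("coordinates must be >= 1", call. = FALSE)
  if (!is.null(genome_length) &&
      (any(start > genome_length) || any(end > genome_length)))
    stop("coordinates outside [1, genome_length]", call. = FALSE)
  wraps <- end < start
  if (any(wraps)) {
    if (!circular)
      stop("end < start requires a circular genome", call. = FALSE)
    if (is.null(genome_length))
      stop("genome_length required for wrapping features", call. = FALSE)
  }
  ifelse(wraps, genome_length - start + 1L + end, end - start + 1L)
}

#' Feature lengths for a whole annotation table
#' @param annotation an [annotation_table()].
#' @return integer vector, one length per feature, in table order.
#' @export
feature_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  feature_length(annotation$start, annotation$end,
                 attr(annotation, "genome_length"),
                 attr(annotation, "circular"))
}

#' Intergenic nucleotides between consecutive features
#'
#' For each feature after the first, the intergenic nucleotide count (IGN) to
#' its predecessor in table order is \code{start_i - end_{i-1} - 1}; negative
#' values denote overlap between the two genes. On a circular genome the first
#' feature additionally has a wrap boundary against the last feature:
#' \code{(start_1 + genome_length) - end_last - 1}. On a linear genome the
#' first feature's IGN is \code{NA}.
#'
#' @param annotation an [annotation_table()] with features in ascending-start
#'   table order.
#' @return data frame with columns \code{feature} and \code{ign}, one row per
#'   feature (the IGN of the boundary preceding it).
#' @export
intergenic_table <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  s <- annotation$start; e <- annotation$end
  n <- length(s)
  if (n > 1L && is.unsorted(s))
    stop("features must be sorted by ascending start (table order)",
         call. = FALSE)
  ign <- rep(NA_integer_, n)
  if (n > 1L) ign[-1L] <- s[-1L] - e[-n] - 1L
  if (attr(annotation, "circular"))
    ign[1L] <- (s[1L] + attr(annotation, "genome_length")) - e[n] - 1L
  data.frame(feature = annotation$name, ign = as.integer(ign),
             stringsAsFactors = FALSE)
}

#' Extract a feature's sequence in coding orientation
#'
#' Returns the substring \code{[start, end]} of the reference strand; features
#' on the minority (N) strand are reverse-complemented so the result reads in
#' coding (mRNA-sense) orientation. Wrapping features on circular genomes are
#' spliced across the origin. IUPAC ambiguity codes are complemented per IUPAC.
#'
#' @param genome a [mito_genome()] with sequence present.
#' @param feature a one-row feature data frame (a row of the annotation), or a
#'   feature name to look up in \code{genome$annotation}.
#' @return nucleotide string, length equal to [feature_length()].
#' @export
extract_feature_sequence <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.null(genome$sequence))
    stop("genome carries no sequence", call. = FALSE)
  if (is.character(feature) && length(feature) == 1L) {
    ann <- genome$annotation
    if (is.null(ann)) stop("genome carries no annotation", call. = FALSE)
    hit <- which(ann$name == feature)
    if (!length(hit)) stop("no feature named '", feature, "'", call. = FALSE)
    feature <- ann[hit[1L], ]
  }
  n <- nchar(genome$sequence)
  s <- feature$start; e <- feature$end
  if (s > n || e > n) stop("feature coordinates beyond sequence", call. = FALSE)
  seq <- if (e >= s) {
    substr(genome$sequence, s, e)
  } else {
    circ <- if (!is.null(genome$annotation))
      attr(genome$annotation, "circular") else TRUE
    if (!circ) stop("wrapping feature on a linear genome", call. = FALSE)
    paste0(substr(genome$sequence, s, n), substr(genome$sequence, 1L, e))
  }
  if (identical(feature$strand, "N")) reverse_complement(seq) else seq
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented per IUPAC.
#' @param seq nucleotide string (DNA; U is accepted and normalised to T).
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(normalize_codon(seq))))
}

#' Rotation-normalised gene-order signature
#'
#' A canonical string of feature names with strand marks, invariant under the
#' choice of linearisation origin of a circular genome: two annotations have
#' equal signatures iff their gene order and strands match. By convention the
#' rotation starts at the feature named in \code{anchor} (tRNA-Ile, the first
#' gene of the typical insect arrangement); when absent, the lexicographically
#' smallest rotation is used.
#'
#' @param annotation an [annotation_table()].
#' @param anchor feature name fixing the start of the rotation.
#' @return single string, tokens \code{name(strand)} joined by \code{" "}.
#' @export
gene_order_signature <- function(annotation, anchor = "tRNA-Ile") {
  stopifnot(inherits(annotation, "annotation_table"))
  tok <- paste0(annotation$name, "(", annotation$strand, ")")
  n <- length(tok)
  rot <- function(k) paste(tok[c(k:n, seq_len(k - 1L))[seq_len(n)]],
                           collapse = " ")
  if (!attr(annotation, "circular")) return(paste(tok, collapse = " "))
  hit <- which(annotation$name == anchor)
  if (length(hit)) return(rot(hit[1L]))
  min(vapply(seq_len(n), rot, character(1)))
}

#' Validate an annotation table
#'
#' Reports findings rather than raising errors: coordinate violations,
#' unexpected feature-class counts for complete 37-gene insect tables,
#' protein-coding gene spans not divisible by 3 (complete stop codons
#' assumed; a note mentioning a truncated stop suppresses the finding), and
#' printed length/IGN cells disagreeing with the coordinate arithmetic when
#' the table carries \code{length_printed} / \code{ign_printed} columns.
#'
#' @param annotation an [annotation_table()].
#' @return data frame of findings with columns \code{feature}, \code{type},
#'   \code{message}; zero rows means the table is clean.
#' @export
validate_annotation <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  g <- attr(annotation, "genome_length")
  circular <- attr(annotation, "circular")
  findings <- list()
  add <- function(feature, type, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      feature = feature, type = type, message = message,
      stringsAsFactors = FALSE)

  bad <- annotation$start < 1L | annotation$start > g |
    annotation$end < 1L | annotation$end > g
  for (i in which(bad))
    add(annotation$name[i], "coordinate",
        sprintf("coordinates (%d, %d) outside [1, %d]",
                annotation$start[i], annotation$end[i], g))
  if (!circular)
    for (i in which(annotation$end < annotation$start))
      add(annotation$name[i], "coordinate",
          "end < start on a linear genome")

  # class counts, checked only for tables that claim completeness
  counts <- table(factor(annotation$class,
                         c("PCG", "tRNA", "rRNA", "control_region")))
  expected <- c(PCG = 13L, tRNA = 22L, rRNA = 2L, control_region = 1L)
  if (nrow(annotation) >= 30L)
    for (cl in names(expected))
      if (counts[[cl]] != expected[[cl]])
        add("(table)", "feature_count",
            sprintf("%d %s features, expected %d for a complete table",
                    counts[[cl]], cl, expected[[cl]]))

  lens <- tryCatch(feature_lengths(annotation), error = function(e) NULL)
  if (!is.null(lens)) {
    pcg <- annotation$class == "PCG"
    trunc_ok <- grepl("truncat", annotation$notes, ignore.case = TRUE)
    for (i in which(pcg & lens %% 3L != 0L & !trunc_ok))
      add(annotation$name[i], "frame",
          sprintf("PCG span of %d nt is not divisible by 3", lens[i]))
    if ("length_printed" %in% names(annotation))
      for (i in which(!is.na(annotation$length_printed) &
                      annotation$length_printed != lens))
        add(annotation$name[i], "printed_length",
            sprintf("printed length %d differs from coordinate span %d",
                    annotation$length_printed[i], lens[i]))
    if ("ign_printed" %in% names(annotation)) {
      ign <- intergenic_table(annotation)$ign
      for (i in which(!is.na(annotation$ign_printed) & !is.na(ign) &
                      annotation$ign_printed != ign))
        add(annotation$name[i], "printed_ign",
            sprintf("printed IGN %d differs from recomputed %d",
                    annotation$ign_printed[i], ign[i]))
    }
  }
  if (!length(findings))
    return(data.frame(feature = character(), type = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
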