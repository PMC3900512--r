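#' Round half away from zero
#'
#' Published composition tables round half-up on the magnitude (2.305 prints
#' as 2.31, -0.005 as -0.01), unlike R's round-half-even. A small epsilon
#' absorbs binary floating-point representation error.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Nucleotide composition profile of a sequence
#'
#' Counts A, T, G, C (IUPAC ambiguity codes are excluded from all denominators
#' and reported separately), and derives base proportions, A+T and G+C
#' content, and the strand-skew statistics AT-skew = (A - T)/(A + T) and
#' GC-skew = (G - C)/(G + C). All derived values are stored unrounded; the
#' print method and [composition_report_tsv()] apply the table rounding
#' policy (half-up, 1 decimal for percentages and 2 for skews by default).
#' A skew whose denominator is zero is undefined and reported as \code{NA},
#' never as 0.
#'
#' @param seq nucleotide string (DNA or RNA alphabet).
#' @param label free-text region label.
#' @return an object of class \code{composition_profile}: list with elements
#'   \code{label}, \code{counts} (A/T/G/C), \code{ambiguous}, \code{n}
#'   (unambiguous total), \code{proportions} (percent), \code{at_content},
#'   \code{gc_content}, \code{at_skew}, \code{gc_skew}.
#' @examples
#' base_composition("AAAT")$at_skew   # 0.5
#' @export
base_composition <- function(seq, label = "") {
  seq <- normalize_codon(seq)
  if (!length(seq) || !any(nzchar(seq)))
    stop("empty sequence", call. = FALSE)
  seq <- paste(seq, collapse = "")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  composition_from_bases(chars, label)
}

# shared core: build a profile from a character vector of bases
composition_from_bases <- function(chars, label = "") {
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  counts <- c(A = sum(chars == "A"), T = sum(chars == "T"),
              G = sum(chars == "G"), C = sum(chars == "C"))
  ambiguous <- length(chars) - sum(counts)
  n <- sum(counts)
  if (n == 0L) stop("sequence contains no unambiguous bases", call. = FALSE)
  prop <- 100 * counts / n
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    label = label, counts = counts, ambiguous = ambiguous, n = n,
    proportions = prop,
    at_content = 100 * at / n, gc_content = 100 * gc / n,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_),
    class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, digits_prop = 1, digits_skew = 2,
                                      ...) {
  cat("Composition", if (nzchar(x$label)) paste0("[", x$label, "]"), ":",
      x$n, "nt",
      if (x$ambiguous > 0) sprintf("(+%d ambiguous)", x$ambiguous), "\n")
  p <- round_half_up(x$proportions, digits_prop)
  cat(sprintf("  A %.1f%%  T %.1f%%  G %.1f%%  C %.1f%%  A+T %.1f%%\n",
              p[["A"]], p[["T"]], p[["G"]], p[["C"]],
              round_half_up(x$at_content, digits_prop)))
  cat(sprintf("  AT-skew %s  GC-skew %s\n",
              format(round_half_up(x$at_skew, digits_skew)),
              format(round_half_up(x$gc_skew, digits_skew))))
  invisible(x)
}

#' @export
as.data.frame.composition_profile <- function(x, ...) {
  data.frame(region = x$label, n = x$n,
             a = x$proportions[["A"]], t = x$proportions[["T"]],
             g = x$proportions[["G"]], c = x$proportions[["C"]],
             at = x$at_content, gc = x$gc_content,
             at_skew = x$at_skew, gc_skew = x$gc_skew,
             ambiguous = x$ambiguous, stringsAsFactors = FALSE)
}

#' Strand skews from printed base proportions
#'
#' Recomputes AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C) from
#' percentages as printed in a composition table, so published skew cells can
#' be cross-checked against their own proportion cells.
#'
#' @param a,t,g,c base percentages (vectorised).
#' @param digits decimals for half-up rounding; \code{NULL} returns raw
#'   values.
#' @return list with numeric vectors \code{at_skew} and \code{gc_skew};
#'   entries with a zero denominator are \code{NA} (undefined, not 0).
#' @examples
#' skew_from_proportions(35.6, 34.0, 11.5, 18.9)  # 0.02, -0.24
#' @export
skew_from_proportions <- function(a, t, g, c, digits = 2) {
  at <- a + t; gc <- g + c
  at_skew <- ifelse(at > 0, (a - t) / at, NA_real_)
  gc_skew <- ifelse(gc > 0, (g - c) / gc, NA_real_)
  if (!is.null(digits)) {
    at_skew <- round_half_up(at_skew, digits)
    gc_skew <- round_half_up(gc_skew, digits)
  }
  list(at_skew = at_skew, gc_skew = gc_skew)
}

#' Composition by codon position across a set of coding sequences
#'
#' Pools the first, second and third codon positions of every supplied coding
#' sequence (already in reading orientation) into three composition profiles.
#' Start and stop codons are included: published codon-position rows state no
#' exclusion rule, and the choice is recorded in the result.
#'
#' @param cds_list character vector or list of CDS nucleotide strings in
#'   reading (mRNA-sense) orientation.
#' @param on_frame_error what to do with a CDS whose length is not divisible
#'   by 3: \code{"error"} (default) or \code{"skip"} (skipped with a finding).
#' @return list with elements \code{position1}, \code{position2},
#'   \code{position3} (each a \code{composition_profile}) and \code{findings}
#'   (data frame of skipped genes).
#' @export
codon_position_composition <- function(cds_list,
                                       on_frame_error = c("error", "skip")) {
  on_frame_error <- match.arg(on_frame_error)
  cds_list <- vapply(cds_list, normalize_codon, character(1))
  lens <- nchar(cds_list)
  bad <- lens %% 3L != 0L
  findings <- data.frame(gene = character(), message = character(),
                         stringsAsFactors = FALSE)
  if (any(bad)) {
    msg <- sprintf("CDS %s length %d not divisible by 3",
                   if (is.null(names(cds_list))) as.character(which(bad))
                   else names(cds_list)[bad], lens[bad])
    if (on_frame_error == "error") stop(paste(msg, collapse = "; "),
                                        call. = FALSE)
    findings <- data.frame(
      gene = if (is.null(names(cds_list))) as.character(which(bad))
             else names(cds_list)[bad],
      message = msg, stringsAsFactors = FALSE)
    cds_list <- cds_list[!bad]
  }
  if (!length(cds_list)) stop("no in-frame coding sequences", call. = FALSE)
  chars <- strsplit(paste(cds_list, collapse = ""), "", fixed = TRUE)[[1]]
  pos <- rep_len(1:3, length(chars))
  out <- lapply(1:3, function(p)
    composition_from_bases(chars[pos == p],
                           sprintf("codon position %d", p)))
  names(out) <- paste0("position", 1:3)
  out$findings <- findings
  out
}

#' Region-by-region composition report for an annotated genome
#'
#' One composition profile per row of a published composition table: the
#' whole genome, the pooled protein-coding genes and their three codon
#' positions, the pooled tRNAs, the large and small rRNAs, and the A+T-rich
#' (control) region. Protein-coding genes are pooled in reading orientation:
#' genes on the minority strand are reverse-complemented before pooling, as
#' the codon-position rows require a reading frame.
#'
#' @param genome a [mito_genome()] with sequence and annotation.
#' @param lr_name,sr_name feature names of the large and small rRNA; when a
#'   name is absent the longer rRNA feature is taken as lrRNA.
#' @return list with \code{profiles} (named list of
#'   \code{composition_profile}, rows omitted when a feature class is absent),
#'   \code{findings} (data frame) and \code{policy} (text describing the
#'   strand and codon-trimming conventions applied).
#' @export
region_composition_report <- function(genome, lr_name = "lrRNA",
                                      sr_name = "srRNA") {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.null(genome$sequence) || is.null(genome$annotation))
    stop("genome must carry sequence and annotation", call. = FALSE)
  ann <- genome$annotation
  profiles <- list()
  findings <- list()
  note <- function(region, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      region = region, message = message, stringsAsFactors = FALSE)

  profiles[["whole"]] <- base_composition(genome$sequence, "Whole mtDNA")

  pull <- function(rows) vapply(rows, function(i)
    extract_feature_sequence(genome, ann[i, ]), character(1))

  pcg <- which(ann$class == "PCG")
  if (length(pcg)) {
    cds <- pull(pcg)
    names(cds) <- ann$name[pcg]
    profiles[["pcg"]] <- base_composition(paste(cds, collapse = ""),
                                          "Protein coding genes")
    cpc <- codon_position_composition(cds, on_frame_error = "skip")
    if (nrow(cpc$findings)) for (i in seq_len(nrow(cpc$findings)))
      note("codon positions", cpc$findings$message[i])
    profiles[["codon1"]] <- cpc$position1
    profiles[["codon1"]]$label <- "1st codon position"
    profiles[["codon2"]] <- cpc$position2
    profiles[["codon2"]]$label <- "2nd codon position"
    profiles[["codon3"]] <- cpc$position3
    profiles[["codon3"]]$label <- "3rd codon position"
  } else note("Protein coding genes", "no PCG features; rows omitted")

  trna <- which(ann$class == "tRNA")
  if (length(trna))
    profiles[["trna"]] <- base_composition(paste(pull(trna), collapse = ""),
                                           "tRNA genes")
  else note("tRNA genes", "no tRNA features; row omitted")

  rrna <- which(ann$class == "rRNA")
  if (length(rrna)) {
    lr <- rrna[ann$name[rrna] == lr_name]
    sr <- rrna[ann$name[rrna] == sr_name]
    if (!length(lr) || !length(sr)) {
      lens <- feature_lengths(ann)[rrna]
      lr <- rrna[which.max(lens)]
      sr <- setdiff(rrna, lr)
    }
    if (length(lr))
      profiles[["lrrna"]] <- base_composition(pull(lr[1]), "lrRNA")
    if (length(sr))
      profiles[["srrna"]] <- base_composition(pull(sr[1]), "srRNA")
  } else note("rRNA", "no rRNA features; rows omitted")

  cr <- which(ann$class == "control_region")
  if (length(cr))
    profiles[["control"]] <- base_composition(pull(cr[1]), "A+T-rich region")
  else note("A+T-rich region", "no control_region feature; row omitted")

  findings <- if (length(findings)) do.call(rbind, findings)
    else data.frame(region = character(), message = character(),
                    stringsAsFactors = FALSE)
  list(profiles = profiles, findings = findings,
       policy = paste("PCGs pooled in coding (mRNA-sense) orientation;",
                      "start and stop codons included in codon-position",
                      "pooling (no trimming)"))
}

#' Write a composition report as TSV
#'
#' Columns follow the printed composition-table layout: per-base percentages,
#' A+T, G+C, AT-skew and GC-skew, one row per region.
#'
#' @param report result of [region_composition_report()], or a list of
#'   \code{composition_profile} objects.
#' @param path output TSV path.
#' @param digits_prop,digits_skew half-up rounding for percentages and skews.
#' @return the written data frame, invisibly.
#' @export
composition_report_tsv <- function(report, path, digits_prop = 1,
                                   digits_skew = 2) {
  profiles <- if (!is.null(report$profiles)) report$profiles else report
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  for (col in c("a", "t", "g", "c", "at", "gc"))
    df[[col]] <- round_half_up(df[[col]], digits_prop)
  for (col in c("at_skew", "gc_skew"))
    df[[col]] <- round_half_up(df[[col]], digits_skew)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
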