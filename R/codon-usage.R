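#' Count codons across a set of coding sequences
#'
#' Every in-frame codon of every coding sequence is counted, including
#' initiator and terminator codons (published codon-usage totals include
#' them). Codons containing ambiguity codes are tallied in a separate bucket
#' and excluded from the 64-codon counts.
#'
#' @param cds_list character vector or list of CDS nucleotide strings in
#'   reading orientation, lengths divisible by 3.
#' @param code a [genetic_code()].
#' @return an object of class \code{codon_usage_table}: data frame with
#'   columns \code{codon} (DNA alphabet), \code{aa}, \code{count} and (after
#'   [rscu()]) \code{rscu}; attributes \code{total_codons},
#'   \code{ambiguous_codons} and \code{code}.
#' @examples
#' tab <- count_codons("ATGAAATAA", genetic_code(5))
#' tab[tab$count > 0, ]
#' @export
count_codons <- function(cds_list, code = genetic_code(5)) {
  stopifnot(inherits(code, "genetic_code"))
  cds_list <- vapply(cds_list, normalize_codon, character(1))
  if (!length(cds_list)) stop("no coding sequences supplied", call. = FALSE)
  lens <- nchar(cds_list)
  if (any(lens %% 3L != 0L))
    stop("CDS lengths not divisible by 3: ",
         paste(which(lens %% 3L != 0L), collapse = ", "), call. = FALSE)
  codons <- unlist(lapply(cds_list, function(s) {
    if (!nchar(s)) return(character())
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", codons)
  counts <- table(factor(codons[clean], levels = names(code$codon_to_aa)))
  codon_usage_table(as.integer(counts), code,
                    ambiguous = sum(!clean))
}

#' Assemble a codon usage table from per-codon counts
#'
#' Used both by [count_codons()] and to load published codon-count tables.
#'
#' @param counts integer vector of counts; either named by codon (DNA or RNA
#'   alphabet) or in the order of \code{code$codon_to_aa}.
#' @param code a [genetic_code()].
#' @param ambiguous number of codons containing ambiguity codes.
#' @return a \code{codon_usage_table}.
#' @export
codon_usage_table <- function(counts, code = genetic_code(5), ambiguous = 0L) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- names(code$codon_to_aa)
  if (!is.null(names(counts))) {
    nm <- normalize_codon(names(counts))
    if (!all(nm %in% codons))
      stop("unknown codons: ", paste(setdiff(nm, codons), collapse = ", "),
           call. = FALSE)
    full <- stats::setNames(integer(64), codons)
    full[nm] <- as.integer(counts)
    counts <- full
  } else {
    stopifnot(length(counts) == 64L)
    counts <- stats::setNames(as.integer(counts), codons)
  }
  if (any(counts < 0)) stop("negative codon counts", call. = FALSE)
  df <- data.frame(codon = codons, aa = unname(code$codon_to_aa),
                   count = unname(counts), stringsAsFactors = FALSE)
  structure(df, total_codons = sum(counts),
            ambiguous_codons = as.integer(ambiguous), code = code,
            class = c("codon_usage_table", "data.frame"))
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} in synonymous family \eqn{F} (all codons translating to
#' the same amino acid under the genetic code; termination codons form their
#' own family), \deqn{RSCU_c = n_c |F| / \sum_{c' \in F} n_{c'},} i.e. the
#' observed count divided by the family mean. A value of 1 means no bias
#' within the family; families with zero total have undefined RSCU, reported
#' as \code{NA}. Values are stored unrounded; published tables print them
#' half-up to 2 decimals ([round_half_up()]).
#'
#' @param table a \code{codon_usage_table} with counts.
#' @return the table with an \code{rscu} column filled.
#' @examples
#' code <- genetic_code(5)
#' tab <- rscu(codon_usage_table(c(UUA = 193, UUG = 48, CUU = 99,
#'                                 CUC = 43, CUA = 94, CUG = 25), code))
#' round_half_up(tab$rscu[tab$codon == "TTA"], 2)  # 2.31
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam_total <- stats::ave(table$count, table$aa, FUN = sum)
  fam_size <- stats::ave(table$count, table$aa, FUN = length)
  table$rscu <- ifelse(fam_total > 0,
                       table$count * fam_size / fam_total, NA_real_)
  table
}

#' Amino-acid usage percentages
#'
#' Per-amino-acid share of the total counted codons. Termination codons are
#' excluded from numerator and denominator unless \code{include_stops}.
#'
#' @param table a \code{codon_usage_table}.
#' @param include_stops logical; count termination codons as a "*" category.
#' @return named numeric vector of percentages, sorted by amino acid.
#' @export
amino_acid_usage <- function(table, include_stops = FALSE) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- if (include_stops) table else table[table$aa != "*", , drop = FALSE]
  tot <- sum(df$count)
  if (tot == 0L) stop("empty codon usage table", call. = FALSE)
  out <- tapply(df$count, df$aa, sum)
  100 * out[order(names(out))] / tot
}

#' Start and stop codons of every protein-coding gene
#'
#' Reads the first and last in-frame codon of each protein-coding gene's
#' coding-sense sequence, classifies the initiator against the genetic code's
#' permitted start codons, and classifies the terminator as complete
#' (TAA/TAG under the invertebrate mitochondrial code) or not. A gene whose
#' span is not divisible by 3 is reported with a truncated-stop finding and
#' its last full codon.
#'
#' @param genome a [mito_genome()] with sequence and annotation.
#' @param code a [genetic_code()].
#' @return data frame with one row per PCG: \code{gene}, \code{start_codon},
#'   \code{stop_codon}, \code{start_ok}, \code{stop_complete},
#'   \code{finding}.
#' @export
start_stop_table <- function(genome, code = genetic_code(5)) {
  stopifnot(inherits(genome, "mito_genome"))
  ann <- genome$annotation
  if (is.null(genome$sequence) || is.null(ann))
    stop("genome must carry sequence and annotation", call. = FALSE)
  pcg <- which(ann$class == "PCG")
  if (!length(pcg)) stop("annotation holds no PCG features", call. = FALSE)
  stops <- code$families[["*"]]
  rows <- lapply(pcg, function(i) {
    seq <- extract_feature_sequence(genome, ann[i, ])
    n <- nchar(seq)
    finding <- ""
    if (n %% 3L != 0L) {
      finding <- sprintf("span of %d nt not divisible by 3; stop may be truncated", n)
      n <- n - n %% 3L
    }
    start <- substr(seq, 1L, 3L)
    stop_c <- substr(seq, n - 2L, n)
    data.frame(gene = ann$name[i], start_codon = start, stop_codon = stop_c,
               start_ok = start %in% code$start_codons,
               stop_complete = stop_c %in% stops,
               finding = finding, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a codon usage table as TSV in codon-box order
#'
#' Codons are printed in RNA notation in the conventional 4x16 codon-box
#' order with amino acid, count and half-up-rounded RSCU.
#'
#' @param table a \code{codon_usage_table} (RSCU filled via [rscu()] if
#'   absent).
#' @param path output TSV path.
#' @param digits RSCU rounding digits.
#' @return the written data frame, invisibly.
#' @export
codon_usage_tsv <- function(table, path, digits = 2) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (is.null(table$rscu)) table <- rscu(table)
  ord <- match(codon_box_order(), table$codon)
  df <- data.frame(codon = rna_codon(table$codon[ord]),
                   aa = table$aa[ord], n = table$count[ord],
                   rscu = round_half_up(table$rscu[ord], digits),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
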