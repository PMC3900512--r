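#' Read sequences from a FASTA file
#' @param path file path.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- normalize_codon(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(normalize_codon(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an annotation table from TSV
#'
#' The TSV dialect mirrors a printed mitogenome annotation table: columns
#' \code{name}, \code{class}, \code{start}, \code{end}, \code{strand}, and
#' optionally \code{start_codon}, \code{stop_codon}, \code{anticodon},
#' \code{notes}. Extra columns (for instance printed length/IGN cells kept for
#' cross-checking) are preserved.
#'
#' @param path TSV file path.
#' @param genome_length genome size; defaults to the maximum end coordinate.
#' @param circular logical.
#' @return an [annotation_table()].
#' @export
read_annotation_tsv <- function(path, genome_length = NULL, circular = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(genome_length)) genome_length <- max(df$end, df$start)
  annotation_table(df, genome_length = genome_length, circular = circular)
}

#' Write an annotation table to TSV
#' @param annotation an [annotation_table()].
#' @param path TSV file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated genome from a GenBank flat file
#'
#' A minimal reader for the GenBank flat-file format as it applies to
#' mitochondrial genomes: the LOCUS line (length, circular flag), accession,
#' the FEATURES table (\code{CDS}, \code{tRNA}, \code{rRNA}, \code{D-loop} and
#' \code{misc_feature} features, \code{complement(a..b)} locations, and the
#' \code{/gene}, \code{/product}, \code{/transl_table} and \code{/note}
#' qualifiers), and the ORIGIN sequence block.
#'
#' @param path GenBank flat file path.
#' @return a [mito_genome()]; the transl_table qualifier, when present, is
#'   attached as attribute \code{transl_table}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line",
                           call. = FALSE)
  circular <- grepl("circular", locus[1], ignore.case = TRUE)
  acc <- sub("^ACCESSION\\s+", "", grep("^ACCESSION", lines, value = TRUE))
  identifier <- if (length(acc) && nzchar(acc[1])) acc[1]
    else strsplit(sub("^LOCUS\\s+", "", locus[1]), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart)) stop("no FEATURES table", call. = FALSE)
  fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  # split the feature table into records: a new record starts at column 6
  keys <- grepl("^ {5}\\S", flines)
  idx <- cumsum(keys)
  feats <- list()
  for (k in seq_len(max(idx, 0))) {
    rec <- flines[idx == k]
    header <- rec[1]
    key <- sub("^\\s+", "", substr(header, 1, 20))
    key <- strsplit(key, "\\s+")[[1]][1]
    loc <- sub("^\\s*\\S+\\s+", "", header)
    quals <- paste(sub("^\\s+", "", rec[-1]), collapse = " ")
    getq <- function(q) {
      m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', q), quals))
      if (length(m)) sub(sprintf('^/%s="', q), "", sub('"$', "", m))
      else {
        m <- regmatches(quals, regexpr(sprintf("/%s=[^ /]+", q), quals))
        if (length(m)) sub(sprintf("^/%s=", q), "", m) else NA_character_
      }
    }
    strand <- if (grepl("^complement", loc)) "N" else "J"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2L) next
    cls <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  `D-loop` = "control_region", misc_feature = "control_region",
                  NA_character_)
    if (is.na(cls)) next
    name <- getq("gene")
    if (is.na(name)) name <- getq("product")
    if (is.na(name)) name <- key
    tt <- getq("transl_table")
    nt <- getq("note")
    feats[[length(feats) + 1L]] <- data.frame(
      name = name, class = cls, start = nums[1], end = nums[2],
      strand = strand, start_codon = NA_character_,
      stop_codon = NA_character_, anticodon = NA_character_,
      notes = if (is.na(nt)) "" else nt,
      transl_table = if (is.na(tt)) NA_integer_ else as.integer(tt),
      stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("FEATURES table holds no usable features",
                           call. = FALSE)
  features <- do.call(rbind, feats)
  features <- features[order(features$start), , drop = FALSE]
  tt <- features$transl_table
  features$transl_table <- NULL

  seq <- NULL
  if (length(ostart)) {
    send <- grep("^//", lines)
    send <- if (length(send)) send[1] - 1L else length(lines)
    seqlines <- lines[(ostart[1] + 1L):send]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }
  glen <- if (!is.null(seq)) nchar(seq) else {
    m <- regmatches(locus[1], regexpr("[0-9]+ bp", locus[1]))
    if (length(m)) as.integer(sub(" bp", "", m)) else max(features$end)
  }
  ann <- annotation_table(features, genome_length = glen, circular = circular)
  out <- mito_genome(sequence = seq, annotation = ann,
                     identifier = identifier)
  attr(out, "transl_table") <- if (any(!is.na(tt))) tt[!is.na(tt)][1] else NA
  out
}

#' Write an annotated genome as a GenBank flat file
#'
#' @param genome a [mito_genome()] with sequence and annotation.
#' @param path output file path.
#' @param transl_table translation table recorded on CDS features.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(genome, path, transl_table = 5) {
  stopifnot(inherits(genome, "mito_genome"), !is.null(genome$sequence),
            !is.null(genome$annotation))
  ann <- genome$annotation
  n <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     %s   INV", genome$identifier, n,
    if (attr(ann, "circular")) "circular" else "linear")
  w("DEFINITION  %s mitochondrial genome.", genome$identifier)
  w("ACCESSION   %s", genome$identifier)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", n)
  for (i in seq_len(nrow(ann))) {
    key <- switch(ann$class[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop")
    loc <- sprintf("%d..%d", ann$start[i], ann$end[i])
    if (ann$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    w("     %-15s %s", key, loc)
    w("                     /gene=\"%s\"", ann$name[i])
    if (ann$class[i] == "PCG")
      w("                     /transl_table=%d", as.integer(transl_table))
    if (nzchar(ann$notes[i]))
      w("                     /note=\"%s\"", ann$notes[i])
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", p, paste(blocks, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Packaged annotation table of the K. wangi mitogenome
#'
#' The published annotation of the 16,179 nt circular mitogenome of the
#' stonefly \emph{Kamimuria wangi} (GenBank KC894944): 13 protein-coding
#' genes, 22 tRNAs, 2 rRNAs and the A+T-rich control region, with the printed
#' length and IGN cells kept in \code{length_printed} / \code{ign_printed}
#' for cross-checking against the coordinate arithmetic.
#'
#' @return an [annotation_table()] (circular, genome length 16,179).
#' @export
kwangi_annotation <- function() {
  read_annotation_tsv(
    system.file("extdata", "kwangi_annotation.tsv", package = "mitoscan",
                mustWork = TRUE),
    genome_length = 16179L, circular = TRUE)
}

#' Packaged codon usage counts for the K. wangi protein-coding genes
#'
#' Published per-codon counts (and printed RSCU values, kept for
#' cross-checking) over the 13 concatenated protein-coding genes of the
#' \emph{K. wangi} mitogenome.
#'
#' @return data frame with columns \code{codon} (RNA alphabet as printed),
#'   \code{aa}, \code{count}, \code{rscu_printed}.
#' @export
kwangi_codon_counts <- function() {
  utils::read.delim(
    system.file("extdata", "kwangi_codon_counts.tsv", package = "mitoscan",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' Packaged nucleotide-composition comparison table
#'
#' Published per-region nucleotide proportions, AT/GC content and strand
#' skews for the \emph{K. wangi} (Kw) and \emph{Pteronarcys princeps} (Pp)
#' mitogenomes: whole genome, pooled protein-coding genes, the three codon
#' positions, pooled tRNAs, the two rRNAs and the A+T-rich region.
#'
#' @return data frame with columns \code{region}, \code{genome}, \code{a},
#'   \code{t}, \code{g}, \code{c}, \code{at}, \code{gc},
#'   \code{at_skew_printed}, \code{gc_skew_printed}.
#' @export
kwangi_composition <- function() {
  utils::read.delim(
    system.file("extdata", "kwangi_composition.tsv", package = "mitoscan",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}
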