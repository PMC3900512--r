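#' Genetic code tables for mitochondrial analyses
#'
#' Wraps an NCBI translation table as used throughout the package: a 64-entry
#' codon-to-amino-acid map (DNA alphabet internally; RNA input is accepted
#' everywhere and normalised), the derived synonymous-codon families, and the
#' permitted initiator codons. The default is NCBI transl_table 5, the
#' invertebrate mitochondrial code, under which AUA encodes Met, UGA encodes
#' Trp and AGA/AGG encode Ser -- so serine has an eight-codon family and the
#' termination family is {UAA, UAG}.
#'
#' @param table_id NCBI translation table identifier (integer or character).
#'   Default 5, the invertebrate mitochondrial code.
#' @return An object of class \code{genetic_code}: a list with elements
#'   \code{table_id}, \code{codon_to_aa} (named character vector over the 64
#'   DNA codons), \code{families} (list mapping each amino acid, and \code{"*"}
#'   for termination, to its synonymous codon set) and \code{start_codons}.
#' @examples
#' code <- genetic_code(5)
#' code$codon_to_aa[c("ATA", "TGA", "AGA")]
#' length(code$families[["S"]])  # 8 under the invertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 5) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  aa <- as.character(map)
  names(aa) <- names(map)
  stopifnot(length(aa) == 64L)
  fams <- split(names(aa), aa)
  starts <- union("ATG", attr(map, "alt_init_codons"))
  # NCBI lists ATA among table-5 initiators; Biostrings' alt_init_codons
  # omits it, so add it back for that table.
  if (as.character(table_id) == "5") starts <- union(starts, "ATA")
  structure(
    list(table_id = as.character(table_id), codon_to_aa = aa,
         families = fams, start_codons = sort(starts)),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI transl_table ", x$table_id, ")\n", sep = "")
  cat("  stop codons:  ", paste(x$families[["*"]], collapse = ", "), "\n")
  cat("  start codons: ", paste(x$start_codons, collapse = ", "), "\n")
  invisible(x)
}

#' Normalise codon or nucleotide strings to the DNA alphabet
#'
#' Uppercases and maps U to T so that RNA-style input (as printed in codon
#' usage tables) and DNA input are interchangeable.
#'
#' @param x character vector of codons or sequences.
#' @return character vector in uppercase DNA alphabet.
#' @export
normalize_codon <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Display a DNA codon in RNA notation
#' @param x character vector of DNA codons.
#' @return codons with T replaced by U.
#' @export
rna_codon <- function(x) chartr("T", "U", normalize_codon(x))

# 4x16 codon-box order: first base U,C,A,G slowest; second base U,C,A,G;
# third base U,C,A,G fastest. Matches the usual printed codon table layout.
codon_box_order <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(vapply(b, function(p1)
    vapply(b, function(p2) paste0(p1, p2, b), character(4)), character(16)))
}
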