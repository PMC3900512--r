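#' Translate a coding sequence
#'
#' Codon-by-codon translation under the given genetic code. The terminal stop
#' codon, when present, is removed by default (concatenated protein matrices
#' are built without stop codons). Internal stop codons are reported in the
#' \code{internal_stops} attribute (1-based codon indices), not silently
#' dropped.
#'
#' @param seq nucleotide string, length divisible by 3.
#' @param code a [genetic_code()].
#' @param trim_terminal_stop logical.
#' @return amino-acid string, with attribute \code{internal_stops}.
#' @examples
#' translate_cds("ATGAAATAA", genetic_code(5))  # "MK"
#' @export
translate_cds <- function(seq, code = genetic_code(5),
                          trim_terminal_stop = TRUE) {
  seq <- normalize_codon(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " not divisible by 3", call. = FALSE)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"   # codons with ambiguity codes
  if (trim_terminal_stop && length(aa) && aa[length(aa)] == "*")
    aa <- aa[-length(aa)]
  internal <- which(aa == "*")
  out <- paste(aa, collapse = "")
  attr(out, "internal_stops") <- internal
  out
}

#' Construct a protein alignment
#'
#' @param rows named character vector of equal-length aligned amino-acid
#'   strings (gap symbol \code{"-"}); names are taxon labels.
#' @param partitions optional data frame with columns \code{gene},
#'   \code{start}, \code{end} giving the per-gene column blocks.
#' @return object of class \code{protein_alignment}: list with \code{taxa},
#'   \code{rows}, \code{partitions}, \code{length}.
#' @export
protein_alignment <- function(rows, partitions = NULL) {
  stopifnot(is.character(rows), !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  if (!is.null(partitions)) {
    stopifnot(all(c("gene", "start", "end") %in% names(partitions)))
    if (sum(partitions$end - partitions$start + 1L) != lens[1L])
      stop("partition lengths do not sum to alignment length", call. = FALSE)
  }
  structure(list(taxa = names(rows), rows = toupper(rows),
                 partitions = partitions, length = unname(lens[1L])),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d taxa x %d columns", length(x$taxa),
              x$length))
  if (!is.null(x$partitions))
    cat(sprintf(", %d partitions", nrow(x$partitions)))
  cat("\n")
  invisible(x)
}

# alignment as a taxa x columns character matrix
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

#' Canonical order of the 13 mitochondrial protein-coding genes
#' @return character vector of gene names in genome order.
#' @export
pcg_gene_order <- function() {
  c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3", "ND5", "ND4",
    "ND4L", "ND6", "CYTB", "ND1")
}

#' Concatenate per-gene protein alignments into a supermatrix
#'
#' Column-wise concatenation in canonical gene order (the genome order of the
#' 13 mitochondrial protein-coding genes; genes not in that list follow
#' alphabetically), independent of input order. A taxon missing from a gene
#' contributes an all-gap block for that gene and is reported in the
#' \code{findings} attribute.
#'
#' @param gene_alignments named list of [protein_alignment()] objects.
#' @param min_shared_taxa error if fewer taxa are common to all genes.
#' @return a [protein_alignment()] over the union of taxa, with
#'   \code{partitions} filled; attribute \code{findings} lists gap-filled
#'   taxon/gene pairs.
#' @export
concatenate_pcgs <- function(gene_alignments, min_shared_taxa = 3L) {
  stopifnot(is.list(gene_alignments), length(gene_alignments) >= 1L,
            !is.null(names(gene_alignments)))
  canon <- pcg_gene_order()
  genes <- names(gene_alignments)
  ord <- order(match(genes, canon, nomatch = length(canon) + 1L), genes)
  genes <- genes[ord]
  taxa <- sort(unique(unlist(lapply(gene_alignments,
                                    function(a) a$taxa))))
  shared <- Reduce(intersect, lapply(gene_alignments, function(a) a$taxa))
  if (length(shared) < min_shared_taxa)
    stop("only ", length(shared), " taxa shared by all gene alignments",
         call. = FALSE)
  findings <- character()
  blocks <- matrix("", length(taxa), length(genes),
                   dimnames = list(taxa, genes))
  plen <- integer(length(genes))
  for (j in seq_along(genes)) {
    a <- gene_alignments[[genes[j]]]
    plen[j] <- a$length
    gaps <- strrep("-", a$length)
    for (t in taxa) {
      if (t %in% a$taxa) blocks[t, j] <- a$rows[[match(t, a$taxa)]]
      else {
        blocks[t, j] <- gaps
        findings <- c(findings,
                      sprintf("taxon %s missing from gene %s: gap-filled",
                              t, genes[j]))
      }
    }
  }
  rows <- apply(blocks, 1L, paste, collapse = "")
  ends <- cumsum(plen)
  parts <- data.frame(gene = genes, start = ends - plen + 1L, end = ends,
                      stringsAsFactors = FALSE)
  out <- protein_alignment(rows, parts)
  attr(out, "findings") <- findings
  out
}

#' Uncorrected amino-acid distance matrix
#'
#' p-distance between every pair of rows: the proportion of mismatching
#' columns among columns where neither row carries a gap (\code{"-"} or
#' \code{"?"}). A pair with no comparable columns is an error.
#'
#' @param aln a [protein_alignment()].
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  m <- alignment_matrix(aln)
  p_distance_from_matrix(m)
}

p_distance_from_matrix <- function(m) {
  n <- nrow(m)
  gap <- m == "-" | m == "?"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    nc <- sum(ok)
    if (nc == 0L)
      stop("taxa ", rownames(m)[i], " and ", rownames(m)[j],
           " share no comparable columns", call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
  }
  d
}

#' Neighbor-joining tree
#'
#' The classic agglomeration on a distance matrix: at each step the pair
#' minimising \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} (with \eqn{r_i} the row
#' sum over active nodes) is joined, branch lengths
#' \eqn{v_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))} assigned, and distances updated
#' as \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2}. Ties in Q are broken by
#' the lowest (row, column) index pair, making the algorithm fully
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister edge (recorded in the tree's
#' \code{clamped_edges} attribute). The result is the unrooted tree that, on
#' an additive matrix, exactly reproduces the generating tree.
#'
#' @param D symmetric nonnegative matrix with zero diagonal (taxa as
#'   dimnames), or a \code{dist} object.
#' @return an unrooted \code{ape} \code{phylo} tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  if (max(abs(D - t(D))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(D < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12))
    stop("distance matrix diagonal is not zero", call. = FALSE)

  labels <- rownames(D)
  frag <- labels                       # newick fragment per active node
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  clamp2 <- function(v1, v2) {
    if (v1 < 0) { v2 <- v2 + v1; v1 <- 0; clamped <<- clamped + 1L }
    if (v2 < 0) { v1 <- v1 + v2; v2 <- 0; clamped <<- clamped + 1L }
    c(max(v1, 0), max(v2, 0))
  }
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp2(vi, vj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(v[1L]),
                       frag[j], fmt(v[2L]))
    k <- setdiff(1:m, c(i, j))
    dnew <- (D[i, k] + D[j, k] - D[i, j]) / 2
    D <- rbind(cbind(D[k, k, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[k], newfrag)
  }
  r12 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  r22 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  r32 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(r12, r22, r32), 0)
  clamped <- clamped + sum(c(r12, r22, r32) < 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(v[1]),
                 frag[2], fmt(v[2]), frag[3], fmt(v[3]))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_edges") <- clamped
  tree
}

# canonical bipartition strings of the non-trivial internal edges
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(tips)
  out <- character()
  for (cl in pp) {
    side <- sort(labs[cl])
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- sort(setdiff(tips, side))
    if (length(side) < 2L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (column-level over the whole
#' concatenated matrix), rebuilds the NJ tree on p-distances for each
#' replicate, and reports the percentage of replicates containing each
#' internal bipartition of the full-data tree. Taxa are put in canonical
#' (alphabetical) order before analysis so supports do not depend on input
#' order; replicates depend only on the seed. A 50% majority-rule consensus
#' of the replicate trees is also returned.
#'
#' @param aln a [protein_alignment()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed governing all resampling.
#' @return list of class \code{nj_bootstrap}: \code{tree} (full-data NJ tree
#'   with node labels holding supports in [0, 100]), \code{supports} (data
#'   frame of bipartitions and supports), \code{consensus} (50%
#'   majority-rule tree), \code{n_reps}, \code{seed}.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  m <- alignment_matrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]
  full <- neighbor_joining(p_distance_from_matrix(m))
  ref_splits <- tree_splits(full)
  counts <- stats::setNames(integer(length(ref_splits)), ref_splits)
  L <- ncol(m)
  trees <- vector("list", n_reps)
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    tr <- neighbor_joining(p_distance_from_matrix(m[, idx, drop = FALSE]))
    trees[[b]] <- tr
    hit <- intersect(tree_splits(tr), ref_splits)
    counts[hit] <- counts[hit] + 1L
  }
  support <- 100 * counts / n_reps
  # attach supports to the full tree's internal nodes
  tree <- full
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  tips <- sort(tree$tip.label)
  node_lab <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(labs[pp[[k]]])
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(support))
      node_lab[k] <- sprintf("%g", round_half_up(support[[key]], 1))
  }
  tree$node.label <- node_lab
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  structure(list(tree = tree,
                 supports = data.frame(bipartition = names(support),
                                       support = unname(support),
                                       stringsAsFactors = FALSE),
                 consensus = cons, n_reps = n_reps, seed = seed),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat(sprintf("NJ bootstrap: %d replicates (seed %s)\n", x$n_reps,
              format(x$seed)))
  print(x$supports)
  invisible(x)
}

#' Support for one clade on a bootstrapped tree
#'
#' @param boot an [bootstrap_support()] result.
#' @param taxa character vector naming one side of the bipartition.
#' @return support percentage, or \code{NA} if the clade is not an internal
#'   edge of the full-data tree.
#' @export
clade_support <- function(boot, taxa) {
  stopifnot(inherits(boot, "nj_bootstrap"))
  tips <- sort(boot$tree$tip.label)
  side <- sort(taxa)
  if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
  key <- paste(side, collapse = "|")
  hit <- match(key, boot$supports$bipartition)
  if (is.na(hit)) NA_real_ else boot$supports$support[hit]
}

#' Write a tree in newick format
#' @param tree an \code{ape} \code{phylo} tree.
#' @param path optional file; when \code{NULL} the newick string is returned.
#' @return newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse a newick tree
#' @param text newick string, or \code{NULL} to read from \code{path}.
#' @param path optional file path.
#' @return an \code{ape} \code{phylo} tree; malformed input is an error.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick input", call. = FALSE)
  tree
}

#' Export a supermatrix for external phylogenetics tools
#'
#' Writes the concatenated alignment as FASTA and/or relaxed (sequential)
#' PHYLIP, plus the gene partition table as TSV, for users who want to rerun
#' model-based analyses (maximum likelihood, Bayesian inference) outside
#' this package.
#'
#' @param aln a [protein_alignment()] with partitions.
#' @param fasta,phylip,partitions output paths (\code{NULL} to skip).
#' @return invisibly, the vector of files written.
#' @export
export_supermatrix <- function(aln, fasta = NULL, phylip = NULL,
                               partitions = NULL) {
  stopifnot(inherits(aln, "protein_alignment"))
  written <- character()
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", aln$taxa), unname(aln$rows))),
               fasta)
    written <- c(written, fasta)
  }
  if (!is.null(phylip)) {
    con <- file(phylip, "w")
    writeLines(sprintf("%d %d", length(aln$taxa), aln$length), con)
    writeLines(sprintf("%s  %s", aln$taxa, unname(aln$rows)), con)
    close(con)
    written <- c(written, phylip)
  }
  if (!is.null(partitions)) {
    if (is.null(aln$partitions))
      stop("alignment carries no partition map", call. = FALSE)
    utils::write.table(aln$partitions, partitions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, partitions)
  }
  invisible(written)
}
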