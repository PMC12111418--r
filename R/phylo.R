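# Distance-based phylogenetics on concatenated protein-coding genes:
# supermatrix assembly, Jukes-Cantor distances with pairwise masking of
# gaps/N, and neighbor-joining (Saitou-Nei, via ape) with negative-branch
# clamping. Alignment itself is out of scope: inputs must be pre-aligned
# (the simulator emits gap-free homologous sequences).

#' Concatenate protein-coding genes across records
#'
#' Builds the per-taxon supermatrix by concatenating coding-strand CDSs
#' in a fixed gene order. All records must carry every requested gene,
#' and per-gene lengths must agree across taxa (pre-aligned input).
#'
#' @param records Named list of `mitogenome` records with sequence, or of
#'   named character vectors (gene -> CDS).
#' @param gene_order Character vector of gene names; defaults to the PCG
#'   order of the first record.
#' @return Named character vector of concatenated sequences with
#'   attribute `partitions` (data.frame `gene`, `start`, `end`).
#' @export
concatenate_pcgs <- function(records, gene_order = NULL) {
  stopifnot(length(records) >= 2)
  taxa <- names(records) %||% paste0("taxon", seq_along(records))
  cds <- lapply(records, function(r) {
    if (inherits(r, "mitogenome")) extract_cds(r) else unlist(r)
  })
  gene_order <- gene_order %||% names(cds[[1]])
  for (t in seq_along(cds)) {
    missing <- setdiff(gene_order, names(cds[[t]]))
    if (length(missing)) {
      stop("taxon '", taxa[t], "' is missing gene(s): ",
           paste(missing, collapse = ", "))
    }
  }
  lens <- vapply(gene_order, function(g) nchar(cds[[1]][[g]]), integer(1))
  for (t in seq_along(cds)) {
    lt <- vapply(gene_order, function(g) nchar(cds[[t]][[g]]), integer(1))
    if (any(lt != lens)) {
      bad <- gene_order[lt != lens][1]
      stop("gene '", bad, "' has unequal length in taxon '", taxa[t],
           "': input must be pre-aligned")
    }
  }
  out <- vapply(cds, function(x) paste(x[gene_order], collapse = ""),
                character(1))
  names(out) <- taxa
  ends <- cumsum(lens)
  attr(out, "partitions") <- data.frame(
    gene = gene_order, start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  out
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise `d = -(3/4) log(1 - 4p/3)` where `p` is the proportion of
#' differing sites among sites that are plain `A/C/G/T` in both
#' sequences (gaps and `N` are excluded pairwise). Pairs at or beyond
#' the `p >= 0.75` saturation point get `NA` and are flagged in the
#' `saturated` attribute.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal; attribute
#'   `saturated` is a logical matrix marking saturated pairs.
#' @export
jc_distance_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2)
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences must be aligned to equal length")
  }
  labels <- names(seqs) %||% paste0("taxon", seq_len(n))
  mat <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  chars <- lapply(seqs, seq_chars)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    use <- a %in% BASES & b %in% BASES
    m <- sum(use)
    if (m == 0) stop("no comparable sites between '", labels[i],
                     "' and '", labels[j], "'")
    p <- sum(a[use] != b[use]) / m
    d <- jc_correct(p)
    if (is.na(d)) sat[i, j] <- sat[j, i] <- TRUE
    mat[i, j] <- mat[j, i] <- d
  }
  attr(mat, "saturated") <- sat
  mat
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]) on a symmetric
#' distance matrix; negative branch-length estimates (a known NJ
#' artifact on noisy matrices) are clamped to zero with a warning. On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param dm Symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (any(is.na(dm))) stop("distance matrix contains undefined (saturated) entries")
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
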