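# Nei-Gojobori (1986) Ka/Ks: fractional synonymous/nonsynonymous site
# counting, pathway-averaged difference counting, Jukes-Cantor correction.
# Mutations to stop codons are excluded from sites and from mutational
# pathways (the standard NG86 convention).

BASES <- c("A", "C", "G", "T")

# all permutations of 1..k (k <= 3)
perm_matrix <- function(k) {
  switch(k,
         matrix(1L, 1, 1),
         rbind(c(1L, 2L), c(2L, 1L)),
         {
           m <- NULL
           for (a in 1:3) for (b in setdiff(1:3, a)) {
             m <- rbind(m, c(a, b, setdiff(1:3, c(a, b))))
           }
           m
         })
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Each codon position contributes fractional sites according to its 3
#' single-nucleotide neighbors: a position with `s` synonymous and `x`
#' stop neighbors contributes `s/3` synonymous and `(3 - x - s)/3`
#' nonsynonymous sites, so `S + N <= 3` with equality when no neighbor is
#' a stop.
#'
#' @param codon A sense codon (no `N`).
#' @param code Genetic code id.
#' @return Named numeric vector `c(S = , N = )`.
#' @examples
#' count_sites("TTT")  # Phe: S = 1/3 (only TTC synonymous)
#' @export
count_sites <- function(codon, code = "2") {
  gc <- mito_genetic_code(code)
  codon <- toupper(codon)
  if (is.na(gc[codon])) stop("invalid codon '", codon, "'")
  if (gc[[codon]] == "*") stop("stop codon '", codon, "' has no sites")
  aa <- gc[[codon]]
  S <- 0; N <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      if (gc[[nb]] == "*") next
      if (gc[[nb]] == aa) S <- S + 1 / 3 else N <- N + 1 / 3
    }
  }
  c(S = S, N = N)
}

# site table over all sense codons of a code (computed once per analysis)
site_table <- function(gc) {
  sense <- sense_codons(gc)
  t(vapply(sense, function(cd) {
    aa <- gc[[cd]]
    S <- 0; N <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cd, pos, pos))) {
        nb <- cd
        substr(nb, pos, pos) <- b
        if (gc[[nb]] == "*") next
        if (gc[[nb]] == aa) S <- S + 1 / 3 else N <- N + 1 / 3
      }
    }
    c(S = S, N = N)
  }, c(S = 0, N = 0)))
}

# pathway-averaged synonymous/nonsynonymous differences between two sense
# codons: average over all orderings of the differing positions, excluding
# orderings that pass through a stop codon; if every ordering is blocked,
# fall back to all orderings with stop-passing steps counted as
# nonsynonymous (degenerate case, essentially unreachable for sense pairs)
codon_path_diffs <- function(c1, c2, gc) {
  diff_pos <- which(seq_chars(c1) != seq_chars(c2))
  k <- length(diff_pos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  perms <- perm_matrix(k)
  tot_s <- 0; tot_n <- 0; n_valid <- 0
  all_s <- 0; all_n <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- c1
    s <- 0; n <- 0
    valid <- TRUE
    for (pos in diff_pos[perms[r, ]]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[[nxt]] == "*") valid <- FALSE
      if (valid && gc[[nxt]] == gc[[cur]]) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    all_s <- all_s + s; all_n <- all_n + n
    if (valid) {
      tot_s <- tot_s + s; tot_n <- tot_n + n
      n_valid <- n_valid + 1
    }
  }
  if (n_valid > 0) c(Sd = tot_s / n_valid, Nd = tot_n / n_valid)
  else c(Sd = all_s / nrow(perms), Nd = all_n / nrow(perms))
}

# Jukes-Cantor correction of a proportion of differences
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Sites are counted fractionally per [count_sites()] and averaged over
#' the two sequences; differences in multi-hit codons are averaged over
#' all minimal mutational pathways with equal weights, excluding pathways
#' through stop codons. Proportions `pS = Sd/S` and `pN = Nd/N` receive
#' the Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`; a proportion
#' at or beyond the 0.75 saturation point yields an `NA` (flagged)
#' distance. Codon columns containing gaps or `N`, or where either codon
#' is a stop, are skipped.
#'
#' @param cds_a,cds_b Aligned coding-strand CDSs of equal length
#'   divisible by 3.
#' @param code Genetic code id.
#' @return Object of class `kaks_result`: a list with `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio` (Ka/Ks; `NA` when Ks is 0 or
#'   undefined), `codons_used`, `codons_skipped`.
#' @export
pairwise_kaks <- function(cds_a, cds_b, code = "2") {
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDSs must have equal length")
  if (nchar(cds_a) %% 3 != 0) stop("alignment length must be a multiple of 3")
  gc <- mito_genetic_code(code)
  ca <- split_codons(toupper(cds_a))
  cb <- split_codons(toupper(cds_b))
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- gc[ca[ok]] != "*" & gc[cb[ok]] != "*"
  skipped <- sum(!ok)
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  st <- site_table(gc)
  S <- sum((st[ca, "S"] + st[cb, "S"]) / 2)
  N <- sum((st[ca, "N"] + st[cb, "N"]) / 2)
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- codon_path_diffs(ca[i], cb[i], gc)
    Sd <- Sd + d[["Sd"]]
    Nd <- Nd + d[["Nd"]]
  }
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio,
                 codons_used = length(ca), codons_skipped = skipped),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> %d codons: Ka %.4f  Ks %.4f  Ka/Ks %s (S %.1f, N %.1f, Sd %.2f, Nd %.2f)\n",
    x$codons_used, x$Ka, x$Ks,
    if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
    x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}

#' Gene-wise mean Ka/Ks across a set of sequences
#'
#' For each gene, averages Ka and Ks over all `C(n,2)` pairwise
#' comparisons. Two ratio aggregations are reported -- `mean(Ka)/mean(Ks)`
#' and the mean of defined pairwise ratios -- since published per-gene
#' summaries rarely state which is used. Pairs with undefined (saturated)
#' distances are excluded from the means with their count logged.
#'
#' @param per_gene_cds_sets Named list; each element a named character
#'   vector of aligned coding-strand CDSs for one gene (>= 2 sequences).
#' @param code Genetic code id.
#' @return data.frame with one row per gene: `gene`, `n_seq`, `n_pairs`,
#'   `n_undefined`, `mean_Ka`, `mean_Ks`, `ratio_of_means`,
#'   `mean_of_ratios`.
#' @export
gene_mean_kaks <- function(per_gene_cds_sets, code = "2") {
  stopifnot(is.list(per_gene_cds_sets), length(per_gene_cds_sets) >= 1)
  genes <- names(per_gene_cds_sets) %||%
    paste0("gene", seq_along(per_gene_cds_sets))
  rows <- list()
  for (g in seq_along(per_gene_cds_sets)) {
    seqs <- per_gene_cds_sets[[g]]
    if (length(seqs) < 2) {
      warning("gene '", genes[g], "' has < 2 usable sequences; skipped")
      next
    }
    pairs <- utils::combn(length(seqs), 2)
    ka <- ks <- ratio <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      r <- pairwise_kaks(seqs[[pairs[1, p]]], seqs[[pairs[2, p]]], code)
      ka[p] <- r$Ka; ks[p] <- r$Ks; ratio[p] <- r$ratio
    }
    def <- !is.na(ka) & !is.na(ks)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = genes[g], n_seq = length(seqs), n_pairs = ncol(pairs),
      n_undefined = sum(!def),
      mean_Ka = mean(ka[def]), mean_Ks = mean(ks[def]),
      ratio_of_means = mean(ka[def]) / mean(ks[def]),
      mean_of_ratios = if (any(!is.na(ratio))) mean(ratio, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene had >= 2 usable sequences")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
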