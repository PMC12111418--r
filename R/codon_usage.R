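# Codon counting, relative synonymous codon usage (RSCU) and amino-acid
# usage for mitochondrial protein-coding genes.

#' Count sense codons across a CDS set
#'
#' CDSs must be in coding-strand orientation. Trailing incomplete codons
#' (the 1-2 bases of incomplete stop codons) are dropped, complete stop
#' codons are excluded from the counts, and codons containing `N` are
#' skipped. An internal stop codon raises a warning naming the gene and
#' codon index (alternative reading or misannotation), not an error.
#'
#' @param cds_set Named character vector of coding-strand CDSs.
#' @param code Genetic code id (default `"2"`, vertebrate mitochondrial).
#' @return Named integer vector over the sense codons of the code
#'   (zeros included).
#' @export
count_codons <- function(cds_set, code = "2") {
  gc <- mito_genetic_code(code)
  sense <- sense_codons(gc)
  counts <- stats::setNames(integer(length(sense)), sense)
  nm <- names(cds_set) %||% as.character(seq_along(cds_set))
  for (g in seq_along(cds_set)) {
    codons <- split_codons(cds_set[[g]])
    n <- length(codons)
    if (n == 0) next
    is_stop <- codons %in% stop_codons(gc)
    internal <- which(is_stop[-n])
    if (length(internal)) {
      warning("internal stop codon in '", nm[g], "' at codon ",
              paste(internal, collapse = ", "))
    }
    keep <- codons[!is_stop & !grepl("N", codons)]
    tab <- table(keep)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Relative synonymous codon usage
#'
#' For codon `c` in a synonymous family of size `k` with family total
#' `n`, `RSCU(c) = count(c) * k / n`: the observed count relative to the
#' expectation under uniform usage within the family. Families with zero
#' total have undefined (`NA`) RSCU; single-codon families are
#' identically 1.
#'
#' @param counts Named codon counts from [count_codons()].
#' @param code Genetic code id.
#' @return data.frame (class `codon_usage_table`) with columns `codon`,
#'   `aa`, `count`, `family_size`, `rscu`, sorted by amino acid.
#' @export
rscu <- function(counts, code = "2") {
  gc <- mito_genetic_code(code)
  sense <- sense_codons(gc)
  counts <- counts[sense]
  counts[is.na(counts)] <- 0L
  aa <- unname(gc[sense])
  fam_size <- ave(rep(1L, length(sense)), aa, FUN = sum)
  fam_total <- ave(as.numeric(counts), aa, FUN = sum)
  val <- ifelse(fam_total > 0, counts * fam_size / fam_total, NA_real_)
  df <- data.frame(codon = sense, aa = aa, count = as.integer(counts),
                   family_size = as.integer(fam_size), rscu = val,
                   stringsAsFactors = FALSE)
  df <- df[order(df$aa, df$codon), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("codon_usage_table", class(df))
  df
}

#' Amino-acid usage
#'
#' Totals and percentages of each encoded amino acid over all sense
#' codons counted.
#'
#' @param counts Named codon counts from [count_codons()].
#' @param code Genetic code id.
#' @return data.frame with columns `aa`, `count`, `pct`, sorted by
#'   decreasing count. Attribute `total` holds the total amino-acid
#'   (sense codon) count.
#' @export
amino_acid_usage <- function(counts, code = "2") {
  gc <- mito_genetic_code(code)
  counts <- counts[names(counts) %in% sense_codons(gc)]
  if (!length(counts) || sum(counts) == 0) {
    out <- data.frame(aa = character(0), count = integer(0), pct = numeric(0))
    attr(out, "total") <- 0L
    return(out)
  }
  agg <- tapply(as.integer(counts), unname(gc[names(counts)]), sum)
  total <- sum(agg)
  out <- data.frame(aa = names(agg), count = as.integer(agg),
                    pct = 100 * as.integer(agg) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
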