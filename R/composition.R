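# Base composition, A+T content and strand-asymmetry skews, per region and
# per codon position. Skews are always computed from raw counts; rounding
# to the published precision happens only in reports.

#' Compositional skew
#'
#' `(x - y) / (x + y)`: AT-skew with `x = A`, `y = T`; GC-skew with
#' `x = G`, `y = C`. Accepts counts or percentages (the ratio is scale
#' free). A zero denominator yields `NA` (undefined, e.g. a G+C-free
#' region).
#'
#' @param x,y Counts or percentages of the two bases.
#' @return Numeric skew in `[-1, 1]`, or `NA`.
#' @examples
#' skew(31.4, 25.1)  # AT-skew of a whole fish mitogenome, ~0.112
#' @export
skew <- function(x, y) {
  ifelse(x + y == 0, NA_real_, (x - y) / (x + y))
}

#' Base composition of one region
#'
#' Counts and percentages of T/C/A/G, A+T content, AT-skew and GC-skew.
#' `N` bases are excluded from all denominators; skews come from exact
#' counts, not rounded percentages.
#'
#' @param sequence Nucleotide string over `A/C/G/T/N`.
#' @param region Region label for the output row.
#' @return One-row data.frame (class `composition_profile`) with columns
#'   `region`, `size`, `n_T`/`n_C`/`n_A`/`n_G`/`n_N`, `T_pct` ... `G_pct`,
#'   `AT_pct`, `AT_skew`, `GC_skew`.
#' @export
base_composition <- function(sequence, region = "region") {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    stop("empty sequence for region '", region, "'")
  }
  chars <- seq_chars(sequence)
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("unexpected characters in sequence: ",
                        paste(bad, collapse = ""))
  cnt <- vapply(c("T", "C", "A", "G", "N"), function(b) sum(chars == b),
                integer(1))
  denom <- sum(cnt[c("T", "C", "A", "G")])
  if (denom == 0) {
    warning("region '", region, "' is all N: composition undefined")
    pct <- stats::setNames(rep(NA_real_, 4), c("T", "C", "A", "G"))
  } else {
    pct <- 100 * cnt[c("T", "C", "A", "G")] / denom
  }
  df <- data.frame(
    region = region, size = length(chars),
    n_T = cnt[["T"]], n_C = cnt[["C"]], n_A = cnt[["A"]], n_G = cnt[["G"]],
    n_N = cnt[["N"]],
    T_pct = pct[["T"]], C_pct = pct[["C"]], A_pct = pct[["A"]],
    G_pct = pct[["G"]],
    AT_pct = pct[["A"]] + pct[["T"]],
    AT_skew = skew(cnt[["A"]], cnt[["T"]]),
    GC_skew = skew(cnt[["G"]], cnt[["C"]]),
    stringsAsFactors = FALSE
  )
  class(df) <- c("composition_profile", class(df))
  df
}

# concatenated composition of a set of feature rows, in heavy-strand
# orientation; codon_trim drops trailing incomplete-stop bases (in coding
# orientation) before counting
concat_region <- function(record, idx, label, codon_trim = FALSE) {
  pieces <- vapply(idx, function(i) {
    s <- feature_seq(record, i)
    if (codon_trim) {
      keep <- 3L * (nchar(s) %/% 3L)
      if (record$features$strand[i] == "L") {
        # trailing coding bases sit at the heavy-strand 5' end
        s <- substr(s, nchar(s) - keep + 1L, nchar(s))
      } else {
        s <- substr(s, 1L, keep)
      }
    }
    s
  }, character(1))
  base_composition(paste(pieces, collapse = ""), label)
}

#' Per-region composition table
#'
#' The standard published layout: the full genome, the control region
#' (D-loop), the concatenated protein-coding genes, tRNAs and rRNAs, then
#' every individual PCG and rRNA. All rows count the heavy-strand
#' (genome) orientation, so light-strand genes such as ND6 show inverted
#' skews relative to their coding strand -- the convention of published
#' composition tables. The concatenated PCG row is codon-trimmed: the 1-2
#' overhanging bases of incomplete stop codons are excluded, so its size
#' equals 3 x the pooled codon count; bases shared by overlapping genes
#' are counted once per gene.
#'
#' @param record A `mitogenome` with sequence.
#' @return data.frame of composition profiles, one row per region.
#' @export
region_compositions <- function(record) {
  if (is.null(record$sequence)) stop("record has no sequence")
  f <- record$features
  rows <- list(base_composition(record$sequence, "Full genome"))
  ctl <- which(f$ftype == "control")
  if (length(ctl)) rows <- c(rows, list(concat_region(record, ctl, "D-loop")))
  pcg <- which(f$ftype == "PCG")
  if (length(pcg)) {
    rows <- c(rows, list(concat_region(record, pcg, "PCGs", codon_trim = TRUE)))
  }
  trna <- which(f$ftype == "tRNA")
  if (length(trna)) rows <- c(rows, list(concat_region(record, trna, "tRNAs")))
  rrna <- which(f$ftype == "rRNA")
  if (length(rrna)) rows <- c(rows, list(concat_region(record, rrna, "rRNAs")))
  for (i in pcg) rows <- c(rows, list(concat_region(record, i, f$name[i])))
  for (i in rrna) rows <- c(rows, list(concat_region(record, i, f$name[i])))
  do.call(rbind, rows)
}

#' Pooled composition by codon position
#'
#' Pools first, second and third codon positions across a set of CDSs
#' supplied in coding-strand orientation (trailing incomplete codons are
#' trimmed; complete stop codons are retained, as in published
#' per-position composition tables).
#'
#' @param cds_set Named character vector of coding-strand CDSs.
#' @param labels Row labels for the three profiles.
#' @return data.frame with three composition rows, each of size = pooled
#'   codon count.
#' @export
codon_position_composition <- function(cds_set,
                                       labels = c("PCGs-1st", "PCGs-2nd", "PCGs-3rd")) {
  if (length(cds_set) == 0) stop("empty CDS set")
  if (any(nchar(cds_set) < 3)) stop("CDS shorter than one codon")
  codons <- unlist(lapply(cds_set, split_codons), use.names = FALSE)
  pos_seq <- function(k) paste(substr(codons, k, k), collapse = "")
  do.call(rbind, lapply(1:3, function(k) base_composition(pos_seq(k), labels[k])))
}
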