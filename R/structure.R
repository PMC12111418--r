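# Genome-structure derivation on the circle: adjacency spacers/overlaps,
# strand census, start/stop codon classification, tRNA size range, and the
# light-strand replication-origin stem-loop search.

#' Adjacencies of consecutive features around the circle
#'
#' One record per consecutive pair of features in start order, plus the
#' wrap-around pair (last feature back to the first). The signed spacer is
#' positive for a gap, negative for an overlap and zero for abutting
#' features: `downstream$start - upstream$end - 1` for ordinary pairs and
#' `(genome length - upstream$end) + (downstream$start - 1)` for the wrap
#' pair.
#'
#' @param record A `mitogenome` with at least 2 features.
#' @return data.frame with columns `upstream`, `downstream`, `spacer`,
#'   `circular`.
#' @export
compute_adjacencies <- function(record) {
  f <- record$features
  n <- nrow(f)
  if (n < 2) stop("need at least 2 features to compute adjacencies")
  nxt <- c(2:n, 1L)
  spacer <- integer(n)
  spacer[-n] <- f$start[nxt[-n]] - f$end[-n] - 1L
  spacer[n] <- (record$length - f$end[n]) + (f$start[1] - 1L)
  data.frame(upstream = f$name, downstream = f$name[nxt],
             spacer = spacer, circular = c(rep(FALSE, n - 1L), TRUE),
             stringsAsFactors = FALSE)
}

# classify the stop of a coding-strand CDS string
classify_stop <- function(cds, gc) {
  r <- nchar(cds) %% 3L
  if (r == 1L) return(paste0(substr(cds, nchar(cds), nchar(cds)), "--"))
  if (r == 2L) return(paste0(substr(cds, nchar(cds) - 1L, nchar(cds)), "-"))
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (gc[[last]] == "*") last else "none"
}

#' Summarize mitogenome structure
#'
#' Derives the quantities of a standard mitogenome structure table:
#' adjacency spacers/overlaps with their extremes, strand census per
#' feature type, tRNA size range, and per-PCG start/stop codon classes.
#' Codon classes are extracted from the sequence (coding-strand
#' orientation; stops may be the complete TAA/TAG/AGA/AGG or the
#' incomplete `T--`/`TA-` forms finished by polyadenylation). On
#' coordinate-only records the printed codon annotations, when present in
#' the feature table, are used instead.
#'
#' @param record A `mitogenome`.
#' @param code Genetic code id (default vertebrate mitochondrial, `"2"`).
#' @return An object of class `structure_report`.
#' @export
summarize_structure <- function(record, code = "2") {
  f <- record$features
  adj <- compute_adjacencies(record)
  gaps <- adj[adj$spacer > 0, , drop = FALSE]
  overlaps <- adj[adj$spacer < 0, , drop = FALSE]
  longest_gap <- if (nrow(gaps)) gaps[which.max(gaps$spacer), ] else NULL
  longest_ovl <- if (nrow(overlaps)) overlaps[which.min(overlaps$spacer), ] else NULL

  strand_census <- table(ftype = f$ftype, strand = f$strand)

  trna <- f$size[f$ftype == "tRNA"]
  trna_range <- if (length(trna)) range(trna) else c(NA_integer_, NA_integer_)

  pcg <- f[f$ftype == "PCG", , drop = FALSE]
  if (!is.null(record$sequence) && nrow(pcg)) {
    if (any(pcg$size < 6)) {
      stop("PCG shorter than 6 bp: ", paste(pcg$name[pcg$size < 6], collapse = ", "))
    }
    gc <- mito_genetic_code(code)
    cds <- extract_cds(record)
    cds <- cds[pcg$name]
    starts <- substr(cds, 1, 3)
    stops <- vapply(cds, classify_stop, character(1), gc = gc)
  } else {
    starts <- stats::setNames(pcg$start_codon, pcg$name)
    stops <- stats::setNames(pcg$stop_codon, pcg$name)
  }

  structure(list(
    adjacencies = adj,
    n_spacers = nrow(gaps),
    n_overlaps = nrow(overlaps),
    longest_spacer = longest_gap,
    longest_overlap = longest_ovl,
    strand_census = strand_census,
    trna_size_range = trna_range,
    start_codons = starts,
    stop_codons = stops
  ), class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  cat("  spacers:", x$n_spacers)
  if (!is.null(x$longest_spacer)) {
    cat(sprintf(" (longest %d bp, %s/%s)", x$longest_spacer$spacer,
                x$longest_spacer$upstream, x$longest_spacer$downstream))
  }
  cat("\n  overlaps:", x$n_overlaps)
  if (!is.null(x$longest_overlap)) {
    cat(sprintf(" (longest %d bp, %s/%s)", -x$longest_overlap$spacer,
                x$longest_overlap$upstream, x$longest_overlap$downstream))
  }
  cat("\n  tRNA sizes:", x$trna_size_range[1], "-", x$trna_size_range[2], "bp\n")
  if (length(x$start_codons)) {
    cat("  start codons:", paste(names(table(x$start_codons)),
                                 table(x$start_codons), sep = ":", collapse = " "), "\n")
    cat("  stop codons: ", paste(names(table(x$stop_codons)),
                                 table(x$stop_codons), sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Find the best hairpin (stem-loop) in a sequence window
#'
#' Exhaustive search for the inverted repeat maximizing stem length, with
#' ties broken by smaller loop then leftmost position. Arms must be exact
#' Watson-Crick reverse complements; the loop must be at least 3 bases.
#' Intended for the short intergenic window that hosts the light-strand
#' replication origin in vertebrate mitogenomes (the gap in the WANCY
#' tRNA cluster).
#'
#' @param window Nucleotide string to scan.
#' @param min_stem Minimum stem arm length (>= 3).
#' @param max_loop Maximum loop length.
#' @return A list of class `stem_loop` (`start`, `end`, `stem`, `loop`,
#'   `arm5`, `arm3`, `loop_seq`; positions relative to the window), or
#'   `NULL` when no hairpin satisfies the constraints.
#' @export
find_stem_loop <- function(window, min_stem = 4, max_loop = 20) {
  stopifnot(min_stem >= 3)
  window <- toupper(window)
  n <- nchar(window)
  if (n < 2 * min_stem + 3) return(NULL)
  chars <- seq_chars(window)
  best <- NULL
  max_stem <- (n - 3L) %/% 2L
  for (s in max_stem:min_stem) {
    for (l in 3:min(max_loop, n - 2L * s)) {
      for (i in 1:(n - 2L * s - l + 1L)) {
        arm1 <- substr(window, i, i + s - 1L)
        arm2 <- substr(window, i + s + l, i + 2L * s + l - 1L)
        if (arm2 == revcomp(arm1)) {
          best <- structure(list(
            start = i, end = i + 2L * s + l - 1L,
            stem = s, loop = l,
            arm5 = arm1, arm3 = arm2,
            loop_seq = substr(window, i + s, i + s + l - 1L)
          ), class = "stem_loop")
          return(best)  # s descending, l ascending, i ascending: first hit wins
        }
      }
    }
  }
  NULL
}

#' @export
print.stem_loop <- function(x, ...) {
  cat(sprintf("<stem_loop> %d..%d stem %d bp, loop %d nt (%s / %s / %s)\n",
              x$start, x$end, x$stem, x$loop, x$arm5, x$loop_seq, x$arm3))
  invisible(x)
}
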