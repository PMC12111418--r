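# Core data model: annotated circular mitogenomes with 1-based, fully
# inclusive coordinates (the convention of published mitogenome tables).
# Features that wrap the origin of the circle are not supported: the
# standard vertebrate arrangement places the tRNA-Phe start at position 1
# so none of the 37 genes nor the control region needs to wrap.

FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "control", "origin")

#' Normalize a feature coordinate pair
#'
#' Published mitogenome tables print light-strand (L) genes with
#' descending coordinates (e.g. `3978-3908` for tRNA-Gln). This helper
#' returns ascending coordinates, inferring strand L from a descending
#' pair unless `strand_hint` overrides it, and computes the feature size.
#'
#' @param raw_start,raw_end Printed 1-based inclusive coordinates.
#' @param strand_hint Optional `"H"` or `"L"`; wins over the inference
#'   from coordinate order.
#' @return A list with `start`, `end`, `strand`, `size`.
#' @examples
#' normalize_feature(3978, 3908)   # tRNA-Gln: L strand, 71 bp
#' @export
normalize_feature <- function(raw_start, raw_end, strand_hint = NULL) {
  if (!is.numeric(raw_start) || !is.numeric(raw_end) ||
      raw_start < 1 || raw_end < 1) {
    stop("feature coordinates must be positive integers")
  }
  raw_start <- as.integer(raw_start)
  raw_end <- as.integer(raw_end)
  if (!is.null(strand_hint)) {
    strand_hint <- match.arg(strand_hint, c("H", "L"))
  }
  if (raw_start > raw_end) {
    strand <- strand_hint %||% "L"
    start <- raw_end
    end <- raw_start
  } else {
    strand <- strand_hint %||% "H"
    start <- raw_start
    end <- raw_end
  }
  list(start = start, end = end, strand = strand,
       size = end - start + 1L)
}

#' Build a feature table
#'
#' Assembles and validates the feature data frame used throughout the
#' package. Coordinates are normalized with [normalize_feature()] and rows
#' are sorted by `(start, end, name)`.
#'
#' @param name Character vector of feature names.
#' @param start,end Printed coordinates (descending pairs allowed).
#' @param strand Optional `"H"`/`"L"` vector (inferred when `NA`).
#' @param ftype Optional feature-type vector; inferred from names when
#'   missing (see [infer_ftype()]).
#' @param start_codon,stop_codon Optional printed codon annotations.
#' @return data.frame with columns `name`, `ftype`, `start`, `end`,
#'   `strand`, `size`, `start_codon`, `stop_codon`.
#' @export
gene_features <- function(name, start, end, strand = NA, ftype = NULL,
                          start_codon = NA, stop_codon = NA) {
  n <- length(name)
  strand <- rep_len(as.character(strand), n)
  start_codon <- rep_len(as.character(start_codon), n)
  stop_codon <- rep_len(as.character(stop_codon), n)
  norm <- mapply(function(s, e, h) {
    normalize_feature(s, e, if (is.na(h) || h == "") NULL else h)
  }, start, end, strand, SIMPLIFY = FALSE)
  ftype <- ftype %||% vapply(name, infer_ftype, character(1))
  if (!all(ftype %in% FEATURE_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(ftype, FEATURE_TYPES), collapse = ", "))
  }
  df <- data.frame(
    name = as.character(name),
    ftype = as.character(ftype),
    start = vapply(norm, `[[`, integer(1), "start"),
    end = vapply(norm, `[[`, integer(1), "end"),
    strand = vapply(norm, `[[`, character(1), "strand"),
    size = vapply(norm, `[[`, integer(1), "size"),
    start_codon = start_codon,
    stop_codon = stop_codon,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Infer a feature type from its name
#'
#' `tRNA-*` names are tRNAs, names containing `rRNA` (or the common
#' `12S`/`16S` shorthands) are rRNAs, `D-loop`/`control` is the control
#' region, `OL`/`O_L`/`rep_origin` is a replication origin, and anything
#' else is taken to be a protein-coding gene.
#'
#' @param name Feature name.
#' @return One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`, `"origin"`.
#' @export
infer_ftype <- function(name) {
  if (grepl("^tRNA", name, ignore.case = TRUE)) return("tRNA")
  if (grepl("rRNA|^1[26]S", name, ignore.case = TRUE)) return("rRNA")
  if (grepl("D-?loop|control", name, ignore.case = TRUE)) return("control")
  if (grepl("^O_?L$|rep_origin", name, ignore.case = TRUE)) return("origin")
  "PCG"
}

#' Construct a mitogenome record
#'
#' The central container: a circular nucleotide sequence (optional) plus
#' an ordered feature table. Coordinate-only records (no sequence) support
#' all structural analyses; sequence-based analyses require `sequence`.
#'
#' @param features A feature data.frame from [gene_features()] or
#'   [read_feature_table()].
#' @param sequence Optional nucleotide string over `A/C/G/T/N`.
#' @param id Record identifier.
#' @param length Genome length; defaults to `nchar(sequence)` or, in
#'   coordinate-only mode, to [genome_length_from_features()].
#' @return An object of class `mitogenome` with elements `id`,
#'   `sequence` (or `NULL`), `length`, `features`.
#' @export
mitogenome <- function(features, sequence = NULL, id = "mitogenome",
                       length = NULL) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (!grepl("^[ACGTN]*$", sequence)) {
      stop("sequence must contain only A/C/G/T/N")
    }
    if (is.null(length)) length <- nchar(sequence)
    if (length != nchar(sequence)) {
      stop("declared length disagrees with sequence length")
    }
  } else if (is.null(length)) {
    length <- genome_length_from_features(features)
  }
  if (any(features$end > length)) {
    bad <- features$name[features$end > length][1]
    stop("feature '", bad, "' extends beyond genome length ", length)
  }
  features <- features[order(features$start, features$end, features$name), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence,
                 length = as.integer(length), features = features),
            class = "mitogenome")
}

#' Genome length implied by a feature table
#'
#' In coordinate-only mode the circle's length is taken as the maximum
#' normalized end coordinate (for the standard vertebrate arrangement the
#' last feature, the control region, abuts position 1 of tRNA-Phe).
#'
#' @param features Feature data.frame.
#' @return Integer length in bp.
#' @export
genome_length_from_features <- function(features) {
  if (is.null(features) || nrow(features) == 0) {
    stop("cannot derive a genome length from an empty feature list")
  }
  as.integer(max(features$end))
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$id, ": ", x$length, " bp, ",
      nrow(x$features), " features",
      if (is.null(x$sequence)) " (coordinate-only)" else "", "\n", sep = "")
  tab <- table(x$features$ftype)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

# slice the heavy-strand sequence of a feature (1-based inclusive)
feature_seq <- function(record, i) {
  substr(record$sequence, record$features$start[i], record$features$end[i])
}

#' Extract coding-strand CDS sequences of the protein-coding genes
#'
#' Light-strand genes are reverse-complemented so every returned sequence
#' starts with its initiation codon.
#'
#' @param record A `mitogenome` with sequence.
#' @param trim Trim trailing bases so lengths are codon multiples
#'   (incomplete stop codons leave 1-2 overhanging bases).
#' @return Named character vector, one element per PCG.
#' @export
extract_cds <- function(record, trim = FALSE) {
  if (is.null(record$sequence)) stop("record has no sequence")
  idx <- which(record$features$ftype == "PCG")
  if (length(idx) == 0) stop("record has no protein-coding genes")
  out <- vapply(idx, function(i) {
    s <- feature_seq(record, i)
    if (record$features$strand[i] == "L") s <- revcomp(s)
    s
  }, character(1))
  names(out) <- record$features$name[idx]
  if (trim) {
    out <- vapply(out, function(s) substr(s, 1L, 3L * (nchar(s) %/% 3L)),
                  character(1))
  }
  out
}
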