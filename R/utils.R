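# Internal helpers shared across modules.

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper; handles `A/C/G/T/N` and gaps (`-`).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]])
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence string into single characters
seq_chars <- function(s) strsplit(toupper(s), "")[[1]]

# split a coding-strand CDS into codons, dropping the trailing partial codon
split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Genetic code table
#'
#' Returns a named character vector mapping codons to one-letter amino
#' acids (`*` for stops), as provided by [Biostrings::getGeneticCode()].
#' The package default is NCBI translation table 2 (vertebrate
#' mitochondrial), under which ATA = Met, TGA = Trp and AGA/AGG are stops.
#'
#' @param code NCBI genetic-code identifier (default `"2"`).
#' @return Named character vector of length 64.
#' @export
mito_genetic_code <- function(code = "2") {
  Biostrings::getGeneticCode(as.character(code))
}

# sense (non-stop) codons of a code table
sense_codons <- function(gc) names(gc)[gc != "*"]
stop_codons <- function(gc) names(gc)[gc == "*"]

`%||%` <- function(a, b) if (is.null(a)) b else a
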