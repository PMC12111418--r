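# Readers and writers: feature tables in the dialect of published
# mitogenome structure tables, minimal single-record GenBank flat files,
# FASTA (via Biostrings), and CSV/Newick reports.

# parse a printed location such as "15,662-16,606" (en-dash or hyphen,
# optional thousands separators); returns c(start, end) unnormalized
parse_location <- function(txt, row = NA) {
  txt <- gsub(",", "", trimws(txt))
  m <- regmatches(txt, regexec("^([0-9]+)\\s*[–-]\\s*([0-9]+)$", txt))[[1]]
  if (length(m) != 3) {
    stop("malformed location '", txt, "'",
         if (!is.na(row)) paste0(" in row ", row) else "")
  }
  as.integer(m[2:3])
}

# match a header name loosely (case/punctuation-insensitive)
match_col <- function(headers, patterns) {
  norm <- tolower(gsub("[^a-z0-9]", "", tolower(headers)))
  for (p in patterns) {
    hit <- which(grepl(p, norm))
    if (length(hit)) return(hit[1])
  }
  NA_integer_
}

#' Read a mitogenome feature table
#'
#' Reads a tab- or comma-separated gene table with columns for gene name,
#' location (`start-end`, en-dash or hyphen, thousands separators
#' allowed), and optionally size, intergenic spacer, coding strand and
#' start/stop codons -- the layout of published mitogenome structure
#' tables. Descending locations are normalized to the light strand.
#' Duplicate names (the two tRNA-Ser and tRNA-Leu genes) receive ordinal
#' suffixes. The spacer column, when present, is treated as derived
#' output: it is recomputed from the coordinates and mismatches trigger a
#' validation warning, never an error.
#'
#' @param path File path.
#' @param id Record identifier (defaults to the file name).
#' @return A coordinate-only [mitogenome()] record.
#' @export
read_feature_table <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("feature table '", path, "' is empty")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  headers <- trimws(cells[[1]])
  ci <- list(
    name = match_col(headers, c("^gene", "name")),
    loc = match_col(headers, c("location")),
    size = match_col(headers, c("^size")),
    spacer = match_col(headers, c("spacer")),
    strand = match_col(headers, c("strand")),
    start_codon = match_col(headers, c("startcodon|^start$|^condon$|^codon$")),
    stop_codon = match_col(headers, c("stopcodon|^stop$"))
  )
  if (is.na(ci$name) || is.na(ci$loc)) {
    stop("feature table must have gene-name and location columns")
  }
  body <- cells[-1]
  get <- function(row, j) {
    if (is.na(j) || j > length(row)) NA_character_ else trimws(row[j])
  }
  name <- vapply(body, get, character(1), ci$name)
  locs <- lapply(seq_along(body), function(k) {
    parse_location(get(body[[k]], ci$loc), row = k + 1L)
  })
  strand <- vapply(body, get, character(1), ci$strand)
  strand[!strand %in% c("H", "L")] <- NA_character_
  start_codon <- vapply(body, get, character(1), ci$start_codon)
  stop_codon <- vapply(body, get, character(1), ci$stop_codon)
  start_codon[start_codon == ""] <- NA_character_
  stop_codon[stop_codon == ""] <- NA_character_

  # disambiguate duplicated gene names (tRNA-Ser/tRNA-Leu pairs)
  dup <- name %in% name[duplicated(name)]
  if (any(dup)) {
    for (nm in unique(name[dup])) {
      k <- which(name == nm)
      name[k] <- paste0(nm, seq_along(k))
    }
  }

  feats <- gene_features(
    name = name,
    start = vapply(locs, `[`, integer(1), 1),
    end = vapply(locs, `[`, integer(1), 2),
    strand = strand,
    start_codon = start_codon,
    stop_codon = stop_codon
  )

  # validate printed size column against coordinates
  if (!is.na(ci$size)) {
    printed <- suppressWarnings(as.integer(gsub(",", "", vapply(body, get, character(1), ci$size))))
    chk <- merge(feats[, c("name", "size")],
                 data.frame(name = name, printed = printed), by = "name")
    bad <- chk$name[!is.na(chk$printed) & chk$printed != chk$size]
    if (length(bad)) {
      warning("printed size disagrees with coordinates for: ",
              paste(bad, collapse = ", "))
    }
  }

  rec <- mitogenome(feats, id = id %||% basename(path))

  # spacer column is derived output -- recompute and compare
  if (!is.na(ci$spacer)) {
    printed <- suppressWarnings(as.integer(vapply(body, get, character(1), ci$spacer)))
    names(printed) <- name
    adj <- compute_adjacencies(rec)
    cmp <- printed[adj$upstream]
    bad <- which(!is.na(cmp) & cmp != adj$spacer)
    if (length(bad)) {
      warning("printed intergenic spacer disagrees with coordinates after: ",
              paste(adj$upstream[bad], collapse = ", "))
    }
  }
  rec
}

#' Write a mitogenome feature table
#'
#' Tab-separated, light-strand rows printed with descending coordinates so
#' that [read_feature_table()] round-trips losslessly. The spacer column
#' is recomputed, never copied.
#'
#' @param record A `mitogenome`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(record, path) {
  f <- record$features
  adj <- compute_adjacencies(record)
  spacer <- adj$spacer[match(f$name, adj$upstream)]
  loc <- ifelse(f$strand == "L",
                paste0(f$end, "-", f$start),
                paste0(f$start, "-", f$end))
  df <- data.frame(
    Number = seq_len(nrow(f)),
    Genes = f$name,
    `Location (bp)` = loc,
    `Size (bp)` = f$size,
    `Intergenic Spacer (bp)` = spacer,
    `Coding Strand` = f$strand,
    `Start Codon` = ifelse(is.na(f$start_codon), "", f$start_codon),
    `Stop Codon` = ifelse(is.na(f$stop_codon), "", f$stop_codon),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The standard 38-feature fish mitogenome template
#'
#' The packaged coordinate fixture: 37 genes plus the control region of a
#' 16,606 bp cyprinid mitogenome in the canonical vertebrate order, with
#' printed sizes, strands and start/stop codons. Used as the default
#' simulation template and as the reference for structure tests.
#'
#' @return A coordinate-only `mitogenome`.
#' @export
fish_mito_template <- function() {
  path <- system.file("extdata", "fish_mitogenome_features.tsv", package = "mitochar")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "fish_mitogenome_features.tsv")
  }
  suppressWarnings(read_feature_table(path, id = "template"))
}

# ---- FASTA ----------------------------------------------------------------

#' Read/write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character
#' vectors, the currency of this package.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

# ---- GenBank flat files ---------------------------------------------------

genbank_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                 control = "D-loop", origin = "rep_origin")

#' Write a minimal GenBank flat file
#'
#' Single-record flat file with `source`, per-feature keys
#' (CDS/tRNA/rRNA/D-loop/rep_origin), `complement(a..b)` locations for
#' light-strand features, `/gene` qualifiers, and an ORIGIN block.
#'
#' @param record A `mitogenome` (sequence optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     circular     %s",
            record$id, record$length, format(Sys.Date(), "%d-%b-%Y")))
  w("DEFINITION  ", record$id, " mitochondrion, complete genome.")
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     %-16s%s", "source", paste0("1..", record$length)))
  w("                     /organelle=\"mitochondrion\"")
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- paste0(f$start[i], "..", f$end[i])
    if (f$strand[i] == "L") loc <- paste0("complement(", loc, ")")
    w(sprintf("     %-16s%s", genbank_key[[f$ftype[i]]], loc))
    w("                     /gene=\"", f$name[i], "\"")
  }
  if (!is.null(record$sequence)) {
    w("ORIGIN")
    s <- tolower(record$sequence)
    starts <- seq(1, nchar(s), by = 60)
    for (p in starts) {
      chunk <- substr(s, p, min(p + 59, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      w(sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
  }
  w("//")
  invisible(path)
}

#' Read a minimal GenBank flat file
#'
#' Parses the single-record dialect written by [write_genbank()] (and the
#' common subset of NCBI flat files: gene/CDS/tRNA/rRNA/D-loop features
#' with simple or `complement()` spans and `/gene` or `/product` names).
#' Multi-record files are rejected; a missing ORIGIN block yields a
#' coordinate-only record with a warning.
#'
#' @param path File path.
#' @return A [mitogenome()] record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) > 1) {
    stop("multi-record GenBank files are not supported")
  }
  id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grepl("^LOCUS", lines)][1])

  fstart <- which(grepl("^FEATURES", lines))
  ostart <- which(grepl("^ORIGIN", lines))
  fend <- if (length(ostart)) ostart - 1L else
    max(which(!grepl("^//", lines)))
  feat_lines <- lines[(fstart + 1L):fend]

  keep_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin", "gene")
  key_type <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                `D-loop` = "control", rep_origin = "origin")
  feats <- list()
  cur <- NULL
  for (ln in feat_lines) {
    key_m <- regmatches(ln, regexec("^ {2,8}(\\S+)\\s+(\\S.*)$", ln))[[1]]
    if (length(key_m) == 3 && !grepl("^ {10}", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- NULL
      key <- key_m[2]
      if (key %in% names(key_type)) {
        loc <- gsub("\\s", "", key_m[3])
        strand <- if (grepl("^complement\\(", loc)) "L" else "H"
        span <- regmatches(loc, regexec("([0-9]+)\\.\\.([0-9]+)", loc))[[1]]
        if (length(span) == 3) {
          cur <- list(ftype = key_type[[key]],
                      start = as.integer(span[2]), end = as.integer(span[3]),
                      strand = strand, name = NA_character_)
        }
      }
    } else if (!is.null(cur)) {
      q <- regmatches(ln, regexec("/(gene|product)=\"([^\"]+)\"", ln))[[1]]
      if (length(q) == 3 && is.na(cur$name)) cur$name <- q[3]
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  if (!length(feats)) stop("no features found in '", path, "'")
  for (i in seq_along(feats)) {
    if (is.na(feats[[i]]$name)) feats[[i]]$name <- paste0("feature", i)
  }

  sequence <- NULL
  if (length(ostart)) {
    seq_lines <- lines[(ostart + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }
  if (is.null(sequence)) {
    warning("no ORIGIN block in '", path, "': returning coordinate-only record")
  }

  fdf <- gene_features(
    name = vapply(feats, `[[`, character(1), "name"),
    start = vapply(feats, `[[`, integer(1), "start"),
    end = vapply(feats, `[[`, integer(1), "end"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    ftype = vapply(feats, `[[`, character(1), "ftype")
  )
  mitogenome(fdf, sequence = sequence, id = id)
}

# ---- reports --------------------------------------------------------------

fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.1f", x))
fmt3 <- function(x) ifelse(is.na(x), NA, sprintf("%.3f", x))

#' Write analysis reports
#'
#' Writes the standard report set to a directory: the gene table
#' (`gene_table.csv`, always), the per-region composition table
#' (`composition.csv`; percentages to 1 decimal, skews to 3, the usual
#' published precision), the RSCU table (`rscu.csv`), the per-gene Ka/Ks
#' table (`kaks.csv`) and a Newick tree (`tree.nwk`) -- each only when the
#' corresponding analysis is supplied. Composition is computed on demand
#' when the record carries sequence; for coordinate-only records it is
#' omitted with a message.
#'
#' @param record A `mitogenome`.
#' @param analyses Named list with optional elements `composition`
#'   (data.frame from [region_compositions()]), `rscu` (data.frame from
#'   [rscu()]), `kaks` (data.frame from [gene_mean_kaks()]), `tree`
#'   (an `ape::phylo`).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reports <- function(record, analyses = list(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  gt <- file.path(outdir, "gene_table.csv")
  f <- record$features
  adj <- compute_adjacencies(record)
  utils::write.csv(data.frame(
    gene = f$name, type = f$ftype, start = f$start, end = f$end,
    size = f$size, strand = f$strand,
    spacer_after = adj$spacer[match(f$name, adj$upstream)],
    start_codon = f$start_codon, stop_codon = f$stop_codon
  ), gt, row.names = FALSE, na = "")
  written <- c(written, gt)

  comp <- analyses$composition
  if (is.null(comp) && !is.null(record$sequence)) {
    comp <- rbind(region_compositions(record),
                  codon_position_composition(extract_cds(record)))
  }
  if (!is.null(comp)) {
    cf <- file.path(outdir, "composition.csv")
    out <- data.frame(
      region = comp$region, size = comp$size,
      T = fmt1(comp$T_pct), C = fmt1(comp$C_pct),
      A = fmt1(comp$A_pct), G = fmt1(comp$G_pct),
      AT = fmt1(comp$AT_pct),
      AT_skew = fmt3(comp$AT_skew), GC_skew = fmt3(comp$GC_skew))
    utils::write.csv(out, cf, row.names = FALSE, na = "")
    written <- c(written, cf)
  } else if (is.null(record$sequence)) {
    message("composition report omitted: record is coordinate-only")
  }

  if (!is.null(analyses$rscu)) {
    rf <- file.path(outdir, "rscu.csv")
    rs <- analyses$rscu
    rs$rscu <- sprintf("%.2f", rs$rscu)
    utils::write.csv(rs, rf, row.names = FALSE, na = "")
    written <- c(written, rf)
  }
  if (!is.null(analyses$kaks)) {
    kf <- file.path(outdir, "kaks.csv")
    utils::write.csv(analyses$kaks, kf, row.names = FALSE, na = "")
    written <- c(written, kf)
  }
  if (!is.null(analyses$tree)) {
    tf <- file.path(outdir, "tree.nwk")
    ape::write.tree(analyses$tree, file = tf, digits = 6)
    written <- c(written, tf)
  }
  invisible(written)
}
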