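# Independent oracles used to validate the implementation paths.

# --- NG86 oracle: straightforward enumeration, written independently of
# the package's vectorized site table / recursive pathway code.

oracle_codon_table <- function() Biostrings::getGeneticCode("2")

# fractional site counts by direct neighbor enumeration
oracle_sites <- function(codon, gc = oracle_codon_table()) {
  bases <- c("A", "C", "G", "T")
  S <- 0
  n_excluded <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in bases[bases != ref]) {
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (gc[[mut]] == "*") {
        n_excluded <- n_excluded + 1
      } else if (gc[[mut]] == gc[[codon]]) {
        S <- S + 1
      }
    }
  }
  c(S = S / 3, N = (9 - n_excluded - S) / 3)
}

# pathway-averaged differences by explicit permutation enumeration
oracle_path_diffs <- function(c1, c2, gc = oracle_codon_table()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  orders <- if (length(pos) == 1) list(pos) else {
    m <- expand.grid(rep(list(pos), length(pos)))
    m <- m[apply(m, 1, function(r) length(unique(r)) == length(pos)), , drop = FALSE]
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  }
  syn <- nsyn <- numeric(0)
  for (ord in orders) {
    cur <- c1
    s <- 0; n <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p), substr(cur, p + 1, 3))
      if (gc[[nxt]] == "*") { blocked <- TRUE; break }
      if (gc[[nxt]] == gc[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (!blocked) { syn <- c(syn, s); nsyn <- c(nsyn, n) }
  }
  if (length(syn) == 0) return(NULL)  # all pathways blocked
  c(Sd = mean(syn), Nd = mean(nsyn))
}

# --- stem-loop oracle: enumerate every (arm length, loop, offset) triple
# and keep the best under (stem max, loop min, position min) ordering.
oracle_stem_loop <- function(window, min_stem, max_loop = nchar(window)) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  n <- nchar(window)
  if (n < 2 * min_stem + 3) return(NULL)
  best <- NULL
  for (s in min_stem:((n - 3) %/% 2)) {
    for (i in 1:(n - 2 * s - 3 + 1)) {
      for (l in 3:min(max_loop, n - 2 * s - i + 1)) {
        if (i + 2 * s + l - 1 > n) break
        a1 <- substr(window, i, i + s - 1)
        a2 <- substr(window, i + s + l, i + 2 * s + l - 1)
        if (a2 == rc(a1)) {
          cand <- c(stem = s, loop = l, start = i)
          if (is.null(best) ||
              cand["stem"] > best["stem"] ||
              (cand["stem"] == best["stem"] && cand["loop"] < best["loop"]) ||
              (cand["stem"] == best["stem"] && cand["loop"] == best["loop"] &&
               cand["start"] < best["start"])) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

# random sense codon sampler for property tests
random_sense_codons <- function(n, gc = oracle_codon_table()) {
  sample(names(gc)[gc != "*"], n, replace = TRUE)
}
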