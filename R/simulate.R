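# Synthetic-data generation: fully annotated mitogenomes built on the
# packaged 38-feature template, and codon-model sequence evolution (HKY
# mutation kernel with nonsynonymous acceptance omega, stop codons
# rejected) along a guide tree. One explicit seed drives every stochastic
# call; no hidden generator state survives between calls.

#' Simulation configuration
#'
#' Defaults emulate a ~16.6 kb cyprinid mitogenome: the packaged gene
#' order/size template and genome-wide base probabilities
#' A .314 / T .251 / C .274 / G .161, with region-specific probabilities
#' for the AT-rich control region and the rRNA/tRNA fraction.
#'
#' @param template Coordinate-only `mitogenome` giving gene order, sizes,
#'   strands and start/stop codon forms.
#' @param base_probs Genome-wide base probabilities (named A/C/G/T),
#'   used for protein-coding genes and intergenic spacers.
#' @param region_probs Named list of base-probability vectors for
#'   `control`, `rRNA`, `tRNA` regions.
#' @param code Genetic code id.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(template = fish_mito_template(),
                       base_probs = c(A = 0.314, T = 0.251, C = 0.274, G = 0.161),
                       region_probs = list(
                         control = c(A = 0.335, T = 0.326, C = 0.211, G = 0.128),
                         rRNA = c(A = 0.347, T = 0.201, C = 0.245, G = 0.207),
                         tRNA = c(A = 0.280, T = 0.268, C = 0.214, G = 0.238)),
                       code = "2") {
  for (p in c(list(base_probs), region_probs)) {
    stopifnot(abs(sum(p) - 1) < 1e-6, all(p > 0))
  }
  structure(list(template = template, base_probs = base_probs,
                 region_probs = region_probs, code = code),
            class = "sim_config")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# genome positions of coding index j for a feature row (H ascending,
# L descending from the feature end)
coding_pos <- function(feat, j) {
  if (feat$strand == "L") feat$end - j + 1L else feat$start + j - 1L
}

# assign coding-orientation bases onto the genome vector, checking for
# conflicts with already-assigned bases
pin_bases <- function(seqv, feat, j, bases, what) {
  pos <- coding_pos(feat, j)
  if (feat$strand == "L") bases <- comp_base(bases)
  clash <- !is.na(seqv[pos]) & seqv[pos] != bases
  if (any(clash)) {
    stop("inconsistent template: ", what, " of '", feat$name,
         "' conflicts with already-placed bases at position ",
         pos[clash][1])
  }
  seqv[pos] <- bases
  seqv
}

#' Simulate an annotated mitogenome
#'
#' Builds a circular sequence realizing the template exactly: every
#' feature at its template coordinates, every protein-coding gene an open
#' reading frame on its coding strand with the template's start codon
#' (including the GTG start of COX1) and stop form (complete TAA/TAG or
#' the incomplete `T--`/`TA-` tails), light-strand genes materialized as
#' reverse complements. Overlapping gene pairs (ATP8/ATP6, ND4L/ND4,
#' ND5/ND6 and the abutting ATP6/COX3 base) are resolved by pinning all
#' start/stop codons first and sampling the remaining codons conditional
#' on the pinned bases; internal codons are drawn base-wise from the
#' genome-wide probabilities restricted to sense codons. RNA genes, the
#' control region and spacers are sampled i.i.d. from their region
#' probabilities on the heavy strand.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param id Record identifier.
#' @return A `mitogenome` with sequence, sharing the template's features.
#' @export
simulate_mitogenome <- function(config = sim_config(), seed = 1,
                                id = "sim_mitogenome") {
  if (!is.null(seed)) set.seed(seed)
  tpl <- config$template
  f <- tpl$features
  L <- tpl$length
  gc <- mito_genetic_code(config$code)
  sense <- sense_codons(gc)
  sense_mat <- do.call(rbind, strsplit(sense, ""))
  rownames(sense_mat) <- sense
  bp <- config$base_probs[BASES]

  seqv <- rep(NA_character_, L)
  pcg_rows <- which(f$ftype == "PCG")

  # 1. pin start and stop codons of every PCG
  for (i in pcg_rows) {
    feat <- as.list(f[i, ])
    n <- feat$size
    start_codon <- if (is.na(feat$start_codon)) "ATG" else feat$start_codon
    seqv <- pin_bases(seqv, feat, 1:3, strsplit(start_codon, "")[[1]],
                      "start codon")
    r <- n %% 3L
    stop_txt <- if (is.na(feat$stop_codon)) {
      switch(r + 1L, "TAA", "T--", "TA-")
    } else feat$stop_codon
    stop_bases <- strsplit(gsub("-", "", stop_txt), "")[[1]]
    expect_tail <- if (r == 0L) 3L else r
    if (length(stop_bases) != expect_tail) {
      stop("inconsistent template: stop '", stop_txt, "' of '", feat$name,
           "' does not fit a CDS of ", n, " bp")
    }
    j <- (n - length(stop_bases) + 1L):n
    seqv <- pin_bases(seqv, feat, j, stop_bases, "stop codon")
  }

  # 2. fill internal codons of each PCG, respecting pinned bases
  for (i in pcg_rows) {
    feat <- as.list(f[i, ])
    n <- feat$size
    ncod <- n %/% 3L
    last_internal <- if (n %% 3L == 0L) ncod - 1L else ncod
    if (last_internal < 2L) next
    for (k in 2:last_internal) {
      j <- (3L * k - 2L):(3L * k)
      pos <- coding_pos(feat, j)
      cur <- seqv[pos]
      if (feat$strand == "L") cur <- comp_base(cur)
      fixed <- !is.na(cur)
      cand <- rep(TRUE, nrow(sense_mat))
      for (q in which(fixed)) cand <- cand & sense_mat[, q] == cur[q]
      if (!any(cand)) {
        stop("generation error: no sense codon fits the pinned pattern ",
             paste(ifelse(fixed, cur, "."), collapse = ""), " in '",
             feat$name, "'")
      }
      w <- apply(sense_mat[cand, , drop = FALSE], 1, function(b) {
        prod(bp[b[!fixed]])
      })
      codon <- sample(sense[cand], 1, prob = w)
      seqv <- pin_bases(seqv, feat, j, strsplit(codon, "")[[1]],
                        "internal codon")
    }
  }

  # 3. RNA genes and control region with region-specific probabilities
  for (i in which(f$ftype != "PCG")) {
    probs <- config$region_probs[[f$ftype[i]]] %||% bp
    idx <- f$start[i]:f$end[i]
    na <- idx[is.na(seqv[idx])]
    if (length(na)) {
      seqv[na] <- sample(names(probs), length(na), replace = TRUE,
                         prob = probs)
    }
  }

  # 4. intergenic spacers with genome-wide probabilities
  na <- which(is.na(seqv))
  if (length(na)) {
    seqv[na] <- sample(names(bp), length(na), replace = TRUE, prob = bp)
  }

  mitogenome(f, sequence = paste(seqv, collapse = ""), id = id)
}

# one substitution process along a branch: expected `t` accepted
# substitutions per codon site; HKY-style proposals (transitions weighted
# kappa), stops rejected, nonsynonymous changes accepted with relative
# rate omega
mutate_codons <- function(codons, t, omega, kappa, gc) {
  L <- length(codons)
  n_sub <- stats::rpois(1, t * L)
  if (n_sub == 0) return(codons)
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in seq_len(n_sub)) {
    for (attempt in 1:10000) {
      site <- sample.int(L, 1)
      pos <- sample.int(3, 1)
      cur <- codons[site]
      base <- substr(cur, pos, pos)
      others <- setdiff(BASES, base)
      w <- ifelse(others == transit[[base]], kappa, 1)
      nb <- sample(others, 1, prob = w)
      nxt <- cur
      substr(nxt, pos, pos) <- nb
      if (gc[[nxt]] == "*") next
      if (gc[[nxt]] != gc[[cur]] && stats::runif(1) >= omega) next
      codons[site] <- nxt
      break
    }
    if (attempt == 10000) stop("substitution sampler failed to accept a change")
  }
  codons
}

#' Evolve a gene family along a guide tree
#'
#' Codon-substitution simulation: proposals follow an HKY-style
#' nucleotide kernel (transition/transversion ratio `kappa`), mutations
#' creating stop codons are rejected, synonymous changes are always
#' accepted and nonsynonymous changes are accepted with relative rate
#' `omega` (dN/dS). Branch lengths are expected accepted substitutions
#' per codon site. The returned tip sequences form a gap-free alignment.
#'
#' @param ancestor_cds Coding-strand ORF (length divisible by 3, no stop
#'   codons; strip the terminal stop first).
#' @param guide_tree An `ape::phylo` with edge lengths, or a Newick
#'   string.
#' @param omega dN/dS acceptance rate for nonsynonymous changes (> 0).
#' @param kappa Transition/transversion ratio of the proposal kernel.
#' @param seed Integer seed.
#' @param code Genetic code id.
#' @return Named character vector of tip sequences (one per tip label).
#' @export
evolve_family <- function(ancestor_cds, guide_tree, omega = 0.1, kappa = 2,
                          seed = 1, code = "2") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(omega > 0, kappa > 0)
  if (is.character(guide_tree)) guide_tree <- ape::read.tree(text = guide_tree)
  if (is.null(guide_tree$edge.length)) stop("guide tree must have branch lengths")
  gc <- mito_genetic_code(code)
  ancestor_cds <- toupper(ancestor_cds)
  if (nchar(ancestor_cds) %% 3 != 0) stop("ancestor length must be a multiple of 3")
  codons <- split_codons(ancestor_cds)
  if (any(gc[codons] == "*")) {
    stop("ancestor contains a stop codon at codon ",
         which(gc[codons] == "*")[1], "; supply a stop-free ORF")
  }
  ntip <- length(guide_tree$tip.label)
  node_seq <- vector("list", ntip + guide_tree$Nnode)
  node_seq[[ntip + 1L]] <- codons
  tree <- ape::reorder.phylo(guide_tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    node_seq[[child]] <- mutate_codons(node_seq[[parent]],
                                       tree$edge.length[e], omega, kappa, gc)
  }
  out <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""),
                character(1))
  names(out) <- guide_tree$tip.label
  out
}

# balanced clade guide tree: a star of clades, tips at depth
# b_between + b_within (a single clade degenerates to a star tree)
clade_guide_tree <- function(sizes, b_within, b_between) {
  if (length(sizes) == 1) {
    tips <- paste0("clade1_t", seq_len(sizes), ":", b_within)
    return(ape::read.tree(text = paste0("(", paste(tips, collapse = ","), ");")))
  }
  clades <- vapply(seq_along(sizes), function(c) {
    tips <- paste0("clade", c, "_t", seq_len(sizes[c]), ":", b_within)
    if (sizes[c] == 1) {
      paste0("clade", c, "_t1:", b_within + b_between)
    } else {
      paste0("(", paste(tips, collapse = ","), "):", b_between)
    }
  }, character(1))
  ape::read.tree(text = paste0("(", paste(clades, collapse = ","), ");"))
}

#' Simulate a clade-structured mitogenome dataset
#'
#' Generates an ancestral genome from the template, then evolves every
#' protein-coding gene along a common guide tree whose tips fall into
#' clades with between-clade divergence exceeding within-clade
#' divergence. Stop codons (and incomplete stop tails) are held fixed;
#' non-coding regions are shared across taxa. All taxa share the
#' template annotation, so downstream extraction and concatenation work
#' unmodified.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param clade_structure Number of clades, or an integer vector of clade
#'   sizes summing to `n_taxa`.
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @param b_within,b_between Within-/between-clade branch lengths
#'   (substitutions per codon site); defaults emulate congeneric fish
#'   mitogenome divergence.
#' @param omega,kappa Codon-model parameters (purifying default
#'   `omega = 0.1`).
#' @return Named list of `mitogenome` records, with attributes `clades`
#'   (list of tip-label vectors) and `guide_tree`.
#' @export
simulate_clade_dataset <- function(n_taxa, clade_structure = 3, seed = 1,
                                   config = sim_config(),
                                   b_within = 0.02, b_between = 0.15,
                                   omega = 0.1, kappa = 2) {
  if (n_taxa < 3) stop("need at least 3 taxa")
  if (length(clade_structure) == 1) {
    k <- as.integer(clade_structure)
    sizes <- rep(n_taxa %/% k, k)
    if (n_taxa %% k) sizes[seq_len(n_taxa %% k)] <- sizes[seq_len(n_taxa %% k)] + 1L
  } else {
    sizes <- as.integer(clade_structure)
    if (sum(sizes) != n_taxa) stop("clade sizes must sum to n_taxa")
  }
  tree <- clade_guide_tree(sizes, b_within, b_between)
  ancestor <- simulate_mitogenome(config, seed = seed, id = "ancestor")
  f <- ancestor$features
  cds <- extract_cds(ancestor)

  tips <- tree$tip.label
  genomes <- lapply(tips, function(t) seq_chars(ancestor$sequence))
  names(genomes) <- tips
  pcg_rows <- which(f$ftype == "PCG")
  for (gi in seq_along(pcg_rows)) {
    i <- pcg_rows[gi]
    feat <- as.list(f[i, ])
    s <- cds[[feat$name]]
    n <- nchar(s)
    # evolve only the sense portion; hold the stop tail fixed
    tail_len <- if (n %% 3L == 0L) 3L else n %% 3L
    core <- substr(s, 1L, n - tail_len)
    fam <- evolve_family(core, tree, omega = omega, kappa = kappa,
                         seed = seed + 1000L * gi, code = config$code)
    for (t in tips) {
      bases <- strsplit(fam[[t]], "")[[1]]
      pos <- coding_pos(feat, seq_len(n - tail_len))
      if (feat$strand == "L") bases <- comp_base(bases)
      genomes[[t]][pos] <- bases
    }
  }
  records <- lapply(tips, function(t) {
    mitogenome(f, sequence = paste(genomes[[t]], collapse = ""), id = t)
  })
  names(records) <- tips
  clades <- split(tips, sub("_t[0-9]+$", "", tips))
  attr(records, "clades") <- clades
  attr(records, "guide_tree") <- tree
  records
}
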