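# Independent oracles and small random-case builders used across the suite.

# Naive per-chromosome loop implementations of the asymmetry statistics,
# kept deliberately free of the package's vectorized code paths.
naive_mca <- function(k) {
  vals <- numeric(0)
  for (cc in chromosomes(k)) {
    vals <- c(vals, (cc$long_um - cc$short_um) / (cc$long_um + cc$short_um))
  }
  mean(vals) * 100
}

naive_cvcl <- function(k) {
  lens <- numeric(0)
  for (cc in chromosomes(k)) lens <- c(lens, cc$long_um + cc$short_um)
  m <- sum(lens) / length(lens)
  ss <- 0
  for (l in lens) ss <- ss + (l - m)^2
  sqrt(ss / (length(lens) - 1)) / m * 100
}

# A random (not necessarily balanced) complement for property tests.
random_karyotype <- function(n = NULL, with_sites = FALSE) {
  if (is.null(n)) n <- sample(4:16, 1)
  chroms <- lapply(seq_len(n), function(i) {
    a <- stats::runif(1, 0.5, 8)
    b <- stats::runif(1, 0.1, 8)
    s <- NULL
    if (with_sites && stats::runif(1) < 0.5) {
      frac <- stats::runif(1)
      s <- rdna_site(sample(c("5S", "45S"), 1), sample(c("LONG", "SHORT"), 1),
                     position_class_of(frac), frac)
    }
    chromosome(sprintf("K%d", i), max(a, b), min(a, b), sites = s)
  })
  karyotype("random", chroms, ploidy = 2L, basic_number = max(1L, n %/% 2L),
            unbalanced = TRUE)
}

total_len <- function(k) sum(k$chrom$long_um + k$chrom$short_um)

permute_karyotype <- function(k, perm) {
  karyotype(k$species, chromosomes(k)[perm], k$ploidy, k$basic_number,
            unbalanced = k$unbalanced)
}

scale_karyotype <- function(k, c) {
  k$chrom$long_um <- k$chrom$long_um * c
  k$chrom$short_um <- k$chrom$short_um * c
  k
}

# Exhaustive small-parsimony minimum: tries every internal-node labelling.
brute_force_parsimony <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  alphabet <- sort(unique(as.character(states)))
  internal <- n_tip + seq_len(tree$Nnode)
  grids <- rep(list(alphabet), length(internal))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  node_state <- character(n_tip + tree$Nnode)
  node_state[seq_len(n_tip)] <- as.character(states[tree$tip.label])
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    node_state[internal] <- as.character(combos[r, ])
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# Expected genome calls of the eight species fixtures (published karyotype
# table: genome formula and ploidy class).
expected_genome_calls <- function() {
  list(
    "P. brachystachys" = c("A", "DIPLOID"),
    "P. canariensis" = c("A", "DIPLOID"),
    "P. aquatica" = c("B/C", "ALLOPOLYPLOID"),
    "P. minor" = c("B/C", "ALLOPOLYPLOID"),
    "P. paradoxa" = c("B", "DIPLOID"),
    "P. caroliniana" = c("BB", "AUTOPOLYPLOID"),
    "P. coerulescens" = c("B", "DIPLOID"),
    "P. arundinacea" = c("BB", "AUTOPOLYPLOID")
  )
}

species_names <- function() names(expected_genome_calls())
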