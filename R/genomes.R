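# Rule-based genome signature matching (A/B/C) and polyploidy-type inference.
#
# The three Phalaris genomes are recognizable from qualitative karyotype
# signatures: genome A (x = 6) is strongly asymmetric with four sm/st
# chromosomes per diploid complement, one pair of distal 45S sites in the
# short arms and one pair of long-arm subtelomeric 5S double bands; genome B
# (x = 7) is more symmetric with one intercalary 45S pair and one
# (sub-)telomeric 5S pair; genome C (x = 7) carries one centromere-proximal
# short-arm 45S pair and the conspicuous 5-6 pairs of 5S sites. Each
# signature is encoded as four equally weighted rule families (basic number,
# morphology, 45S pattern, 5S pattern) evaluated on a diploid
# sub-complement.

#' Built-in genome signatures
#'
#' @return named list of `genome_signature` objects with labels A, B, C.
#' @export
#' @examples
#' builtin_signatures()$A$basic_number # 6
builtin_signatures <- function() {
  sig <- function(label, basic_number, morphology, rule_45s, rule_5s) {
    structure(list(label = label, basic_number = basic_number,
                   morphology = morphology, rule_45s = rule_45s,
                   rule_5s = rule_5s), class = "genome_signature")
  }
  # An rDNA rule: expected pair count (range), required arm, admissible
  # position classes (NULL = any).
  rule <- function(pairs, arm = NULL, classes = NULL) {
    list(pairs = range(pairs), arm = arm, classes = classes)
  }
  list(
    A = sig("A", 6L,
            morphology = list(kind = "sm_st_count", min_count = 4L),
            rule_45s = rule(1, arm = "SHORT",
                            classes = c("SUBTELOMERIC", "TELOMERIC")),
            rule_5s = rule(2, arm = "LONG",
                           classes = c("SUBTELOMERIC", "TELOMERIC"))),
    B = sig("B", 7L,
            morphology = list(kind = "mca_below", threshold = 20),
            rule_45s = rule(1, classes = "INTERCALARY"),
            rule_5s = rule(1, classes = c("SUBTELOMERIC", "TELOMERIC"))),
    C = sig("C", 7L,
            morphology = list(kind = "mca_below", threshold = 20),
            rule_45s = rule(1, arm = "SHORT",
                            classes = "CENTROMERIC_PROXIMAL"),
            rule_5s = rule(c(5, 6)))
  )
}

# Evaluate one rDNA rule on the site table of a diploid sub-complement.
# FISH signal counting on a single metaphase plate loses the odd signal, so
# counts are accepted one below the expected pair total and at most one
# stray signal of the family may sit off the stated arm/position.
rdna_rule_ok <- function(sites, family, rule) {
  s <- sites[sites$family == family, , drop = FALSE]
  match_ok <- rep(TRUE, nrow(s))
  if (!is.null(rule$arm)) match_ok <- match_ok & s$arm == rule$arm
  if (!is.null(rule$classes)) match_ok <- match_ok & s$position_class %in% rule$classes
  n_match <- sum(match_ok)
  n_stray <- nrow(s) - n_match
  lo <- max(1L, 2L * rule$pairs[1] - 1L)
  hi <- 2L * rule$pairs[2]
  n_match >= lo && n_match <= hi && n_stray <= 1L
}

#' Score a diploid sub-complement against a genome signature
#'
#' Returns the fraction of the four signature rule families satisfied
#' (basic number, morphology composition, 45S pattern, 5S pattern; equal
#' weights).
#'
#' @param complement list of [chromosome()] objects forming one diploid
#'   sub-complement (2x chromosomes), or a [karyotype()] whose complement is
#'   one diploid genome copy.
#' @param sig one signature from [builtin_signatures()].
#' @return score in `[0, 1]`.
#' @export
score_signature <- function(complement, sig) {
  stopifnot(inherits(sig, "genome_signature"))
  if (inherits(complement, "karyotype")) complement <- chromosomes(complement)
  if (length(complement) == 0) return(0)
  stopifnot(all(vapply(complement, inherits, TRUE, "chromosome")))
  kk <- karyotype("subcomplement", complement, ploidy = 2L,
                  basic_number = max(1L, length(complement) %/% 2L),
                  unbalanced = TRUE)
  ok_x <- length(complement) == 2L * sig$basic_number
  ok_morph <- switch(sig$morphology$kind,
    sm_st_count = {
      cls <- classify_ratio(vapply(complement, arm_ratio, 0))
      sum(cls %in% c("sm", "st")) >= sig$morphology$min_count
    },
    mca_below = mca(kk) < sig$morphology$threshold
  )
  ok_45s <- rdna_rule_ok(kk$sites, "45S", sig$rule_45s)
  ok_5s <- rdna_rule_ok(kk$sites, "5S", sig$rule_5s)
  mean(c(ok_x, ok_morph, ok_45s, ok_5s))
}

# Partition a karyotype into diploid sub-complements: chromosomes are
# grouped by genome label (NA labels form one anonymous group); within a
# genome, the i-th and (i+1)-th occurrence of each chromosome designation
# land in genome copy ceiling(i/2).
split_subcomplements <- function(k) {
  ch <- k$chrom
  n <- nrow(ch)
  if (n == 0) return(list())
  gen <- ifelse(is.na(ch$genome), "?", ch$genome)
  occ <- stats::ave(seq_len(n), paste(gen, ch$label), FUN = seq_along)
  copy <- ceiling(occ / 2)
  key <- paste(gen, copy, sep = "#")
  groups <- split(seq_len(n), key)
  groups[order(names(groups))]
}

#' Assign genome labels and polyploidy type to a karyotype
#'
#' Partitions the somatic complement into diploid sub-complements (one per
#' genome copy, using genome labels and homologue designations), scores each
#' against the built-in signatures, and assembles the genome formula and
#' polyploidy type. A sub-complement whose best score falls below
#' `threshold` is labelled `UNKNOWN`. Ties are broken in favour of the
#' earlier label in A, B, C order.
#'
#' @param k a [karyotype()].
#' @param signatures signature set, default [builtin_signatures()].
#' @param threshold minimum rule-satisfaction score for a call (default
#'   0.75).
#' @return an object of class `genome_assignment`: list with `formula`
#'   (e.g. `"A"`, `"BB"`, `"B/C"`), `polyploidy_type` (`"DIPLOID"`,
#'   `"AUTOPOLYPLOID"`, `"ALLOPOLYPLOID"` or `"UNKNOWN"`), and `copies`, a
#'   data.frame of per-copy labels and scores.
#' @export
#' @examples
#' assign_genomes(phalaris_fixtures()[["P. caroliniana"]])$formula # "BB"
assign_genomes <- function(k, signatures = builtin_signatures(),
                           threshold = 0.75) {
  stopifnot(inherits(k, "karyotype"))
  groups <- split_subcomplements(k)
  labels <- character(0)
  rows <- list()
  for (gi in seq_along(groups)) {
    comp <- lapply(groups[[gi]], function(i) get_chromosome(k, i))
    scores <- vapply(signatures, function(sig) score_signature(comp, sig), 0)
    best <- which.max(scores) # ties: first of A, B, C
    lab <- if (scores[best] >= threshold) names(signatures)[best] else "UNKNOWN"
    labels <- c(labels, lab)
    rows[[gi]] <- data.frame(
      copy = gi, n_chromosomes = length(comp), label = lab,
      score = unname(scores[best]),
      t(vapply(scores, identity, 0)), stringsAsFactors = FALSE
    )
  }
  known <- labels[labels != "UNKNOWN"]
  ptype <- if (k$ploidy <= 2) {
    "DIPLOID"
  } else if (length(unique(known)) == 1 && length(known) == length(labels)) {
    "AUTOPOLYPLOID"
  } else if (length(unique(known)) >= 2) {
    "ALLOPOLYPLOID"
  } else {
    "UNKNOWN"
  }
  # Table-style formula: same-label copies concatenated, distinct genomes
  # joined by "/": "A", "BB", "B/C".
  tab <- table(labels)
  formula <- paste(vapply(sort(names(tab)), function(lb) {
    paste(rep(lb, tab[[lb]]), collapse = "")
  }, ""), collapse = "/")
  structure(
    list(species = k$species, formula = formula, polyploidy_type = ptype,
         copies = do.call(rbind, rows), threshold = threshold),
    class = "genome_assignment"
  )
}

#' @export
print.genome_assignment <- function(x, ...) {
  cat(sprintf("%s: genome formula %s (%s)\n", x$species, x$formula,
              x$polyploidy_type))
  print(x$copies[, c("copy", "n_chromosomes", "label", "score")], row.names = FALSE)
  invisible(x)
}
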