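# Domain model: rDNA sites, chromosomes, karyotypes, Levan morphology.

#' Create an rDNA site annotation
#'
#' A single FISH signal of the 5S or 45S rDNA family on one chromosome arm.
#' Positions are fractions of the arm length measured from the centromere (0)
#' towards the telomere (1); qualitative position classes
#' (centromere-proximal, intercalary, subtelomeric, telomeric) are fixed bins
#' over that fraction. When `position_frac` is omitted it defaults to the
#' midpoint of the class bin.
#'
#' @param family `"5S"` or `"45S"`.
#' @param arm `"SHORT"` or `"LONG"`.
#' @param position_class one of `"CENTROMERIC_PROXIMAL"`, `"INTERCALARY"`,
#'   `"SUBTELOMERIC"`, `"TELOMERIC"`.
#' @param position_frac optional fraction in `[0, 1]`; must fall inside the
#'   bin of `position_class`.
#' @return a one-row data.frame with columns `family`, `arm`,
#'   `position_class`, `position_frac`.
#' @export
#' @examples
#' rdna_site("5S", "LONG", "SUBTELOMERIC", 0.85)
rdna_site <- function(family, arm, position_class, position_frac = NULL) {
  family <- match.arg(family, RDNA_FAMILIES)
  arm <- match.arg(arm, ARM_NAMES)
  position_class <- match.arg(position_class, POSITION_CLASSES)
  if (is.null(position_frac) || is.na(position_frac)) {
    position_frac <- position_class_midpoint(position_class)
  }
  stopifnot(is.numeric(position_frac), position_frac >= 0, position_frac <= 1)
  if (!frac_in_class(position_frac, position_class)) {
    stop(sprintf(
      "position_frac %.4f outside the %s bin", position_frac, position_class
    ))
  }
  data.frame(
    family = family, arm = arm, position_class = position_class,
    position_frac = position_frac, stringsAsFactors = FALSE
  )
}

#' Create a chromosome
#'
#' One mitotic chromosome described by its long- and short-arm lengths (um),
#' optional satellite (secondary constriction, metadata only: it contributes
#' no length), an ordered set of rDNA sites, and an optional genome label.
#' Arms are named by length: if the arguments arrive swapped, lengths are
#' exchanged and every site (and the satellite) is re-assigned to the other
#' arm, so construction is normalizing and idempotent.
#'
#' @param label chromosome designation, e.g. `"A2"`, `"B1"`.
#' @param long_um,short_um arm lengths in micrometres; `long_um + short_um`
#'   must be positive and `short_um` may be 0 (telocentric).
#' @param sites a data.frame of sites as built by [rdna_site()] (rows may be
#'   concatenated with `rbind`), or an empty list.
#' @param satellite `FALSE`, `TRUE`, or a list with elements `arm` and
#'   `position_frac` locating the secondary constriction.
#' @param genome optional genome label (`"A"`, `"B"`, `"C"`) or `NA`.
#' @return an object of class `"chromosome"`.
#' @export
#' @examples
#' chromosome("B1", 3.1, 2.2, sites = rdna_site("45S", "LONG", "INTERCALARY", 0.5))
chromosome <- function(label, long_um, short_um, sites = NULL,
                       satellite = FALSE, genome = NA_character_) {
  stopifnot(is.character(label), nchar(label) > 0)
  stopifnot(is.numeric(long_um), is.numeric(short_um),
            long_um >= 0, short_um >= 0, long_um + short_um > 0)
  if (is.null(sites) || (is.list(sites) && length(sites) == 0 && !is.data.frame(sites))) {
    sites <- empty_sites_df()[, c("family", "arm", "position_class", "position_frac")]
  }
  stopifnot(is.data.frame(sites))
  if (isTRUE(satellite)) satellite <- list(arm = NA_character_, position_frac = NA_real_)
  if (short_um > long_um) {
    tmp <- long_um; long_um <- short_um; short_um <- tmp
    if (nrow(sites)) {
      sites$arm <- ifelse(sites$arm == "LONG", "SHORT", "LONG")
    }
    if (is.list(satellite) && !is.na(satellite$arm)) {
      satellite$arm <- ifelse(satellite$arm == "LONG", "SHORT", "LONG")
    }
  }
  structure(
    list(label = label, long_um = long_um, short_um = short_um,
         sites = sites, satellite = satellite, genome = genome),
    class = "chromosome"
  )
}

#' Arm ratio of a chromosome
#'
#' `r = L / S`, always `>= 1` by arm naming. A zero-length short arm yields
#' `Inf` (classified telocentric).
#'
#' @param chrom a [chromosome()].
#' @return a single number `>= 1`, possibly `Inf`.
#' @export
arm_ratio <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome"))
  if (chrom$short_um == 0) return(Inf)
  chrom$long_um / chrom$short_um
}

# Levan et al. (1964) arm-ratio intervals; boundaries closed on the lower
# class: m [1, 1.7], sm (1.7, 3], st (3, 7], t (7, Inf).
MORPHOLOGY_LEVELS <- c("m", "sm", "st", "t")

classify_ratio <- function(r) {
  cls <- character(length(r))
  cls[r <= 1.7] <- "m"
  cls[r > 1.7 & r <= 3] <- "sm"
  cls[r > 3 & r <= 7] <- "st"
  cls[r > 7] <- "t"
  cls
}

#' Levan morphology class of a chromosome
#'
#' Classifies centromere position from the arm ratio using the Levan
#' intervals: metacentric `m` for r in `[1, 1.7]`, submetacentric `sm` for
#' `(1.7, 3]`, subtelocentric `st` for `(3, 7]`, telocentric `t` above 7.
#'
#' @param chrom a [chromosome()].
#' @return one of `"m"`, `"sm"`, `"st"`, `"t"`.
#' @export
classify_morphology <- function(chrom) {
  classify_ratio(arm_ratio(chrom))
}

#' Create a karyotype
#'
#' The full somatic chromosome complement of one accession: every chromosome
#' (homologues listed individually), the ploidy level, and the basic
#' chromosome number x. The somatic number 2n is derived as the chromosome
#' count. Balanced complements satisfy `2n == ploidy * x`; intermediates of
#' rearrangement scenarios may be flagged `unbalanced`.
#'
#' Internally chromosomes and sites are stored as two data.frames (`$chrom`
#' with one row per somatic chromosome, `$sites` with one row per rDNA signal
#' referencing `$chrom` by row index), which keeps whole-complement
#' statistics and noise simulation vectorized.
#'
#' @param species accession/species name.
#' @param chromosomes a list of [chromosome()] objects (may be empty).
#' @param ploidy integer ploidy level (2 for diploids).
#' @param basic_number basic chromosome number x of one monoploid set.
#' @param unbalanced set `TRUE` for scenario intermediates whose complement
#'   does not satisfy `2n == ploidy * x`.
#' @return an object of class `"karyotype"`.
#' @export
karyotype <- function(species, chromosomes, ploidy, basic_number,
                      unbalanced = FALSE) {
  stopifnot(is.character(species))
  stopifnot(is.list(chromosomes))
  n <- length(chromosomes)
  if (n > 0) stopifnot(all(vapply(chromosomes, inherits, TRUE, "chromosome")))
  stopifnot(ploidy >= 0, basic_number >= 0)
  chrom <- data.frame(
    label = vapply(chromosomes, `[[`, "", "label"),
    genome = vapply(chromosomes, function(c) as.character(c$genome %||% NA), ""),
    long_um = vapply(chromosomes, `[[`, 0, "long_um"),
    short_um = vapply(chromosomes, `[[`, 0, "short_um"),
    satellite = vapply(chromosomes, function(c) encode_satellite(c$satellite), ""),
    stringsAsFactors = FALSE
  )
  sites <- empty_sites_df()
  for (i in seq_len(n)) {
    s <- chromosomes[[i]]$sites
    if (nrow(s)) {
      sites <- rbind(sites, cbind(data.frame(chrom = i), s))
    }
  }
  new_karyotype(species, chrom, sites, ploidy, basic_number, unbalanced)
}

# Low-level constructor from the tabular representation.
new_karyotype <- function(species, chrom, sites, ploidy, basic_number,
                          unbalanced = FALSE) {
  rownames(chrom) <- NULL
  rownames(sites) <- NULL
  structure(
    list(species = species, chrom = chrom, sites = sites,
         ploidy = as.integer(ploidy), basic_number = as.integer(basic_number),
         unbalanced = isTRUE(unbalanced)),
    class = "karyotype"
  )
}

encode_satellite <- function(sat) {
  if (isFALSE(sat) || is.null(sat)) return("0")
  if (is.list(sat)) {
    if (is.na(sat$arm)) return("1")
    return(sprintf("1:%s:%.6f", sat$arm, sat$position_frac))
  }
  if (isTRUE(sat)) return("1")
  as.character(sat)
}

decode_satellite <- function(code) {
  if (code == "0") return(FALSE)
  if (code == "1") return(list(arm = NA_character_, position_frac = NA_real_))
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  list(arm = parts[2], position_frac = as.numeric(parts[3]))
}

#' Number of somatic chromosomes (2n)
#' @param k a [karyotype()].
#' @return integer somatic chromosome number.
#' @export
somatic_number <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  nrow(k$chrom)
}

#' Extract one chromosome from a karyotype
#' @param k a [karyotype()].
#' @param i row index into the somatic complement.
#' @return a [chromosome()] object.
#' @export
get_chromosome <- function(k, i) {
  stopifnot(inherits(k, "karyotype"), i >= 1, i <= nrow(k$chrom))
  s <- k$sites[k$sites$chrom == i, c("family", "arm", "position_class", "position_frac")]
  chromosome(
    label = k$chrom$label[i],
    long_um = k$chrom$long_um[i], short_um = k$chrom$short_um[i],
    sites = s, satellite = decode_satellite(k$chrom$satellite[i]),
    genome = k$chrom$genome[i]
  )
}

#' All chromosomes of a karyotype as a list
#' @param k a [karyotype()].
#' @return list of [chromosome()] objects in complement order.
#' @export
chromosomes <- function(k) {
  lapply(seq_len(somatic_number(k)), function(i) get_chromosome(k, i))
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf(
    "Karyotype of %s: 2n = %d (ploidy %d, x = %d)%s\n",
    x$species, somatic_number(x), x$ploidy, x$basic_number,
    if (x$unbalanced) " [unbalanced]" else ""
  ))
  cat(sprintf("  rDNA sites: %d x 45S, %d x 5S\n",
              sum(x$sites$family == "45S"), sum(x$sites$family == "5S")))
  invisible(x)
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("Chromosome %s: L = %.2f um, S = %.2f um (%s), %d rDNA site(s)\n",
              x$label, x$long_um, x$short_um, classify_morphology(x),
              nrow(x$sites)))
  invisible(x)
}

#' Validate a karyotype against the model invariants
#'
#' Checks arm-length normalization, positive chromosome lengths, position
#' fractions falling inside their class bins, site references, and (unless
#' the karyotype is flagged unbalanced) the balance condition
#' `2n == ploidy * x`. Validation never throws; it reports.
#'
#' @param k a [karyotype()].
#' @return character vector of violation messages; empty if the karyotype is
#'   valid.
#' @export
validate_karyotype <- function(k) {
  if (!inherits(k, "karyotype")) return("not a karyotype object")
  v <- character()
  ch <- k$chrom
  n <- nrow(ch)
  if (n > 0) {
    bad_len <- which(ch$long_um + ch$short_um <= 0)
    for (i in bad_len) v <- c(v, sprintf("%s: non-positive total length", ch$label[i]))
    bad_norm <- which(ch$short_um > ch$long_um)
    for (i in bad_norm) v <- c(v, sprintf("%s: short arm longer than long arm", ch$label[i]))
  }
  if (nrow(k$sites)) {
    s <- k$sites
    bad_ref <- which(s$chrom < 1 | s$chrom > n)
    for (i in bad_ref) v <- c(v, sprintf("site %d: dangling chromosome reference", i))
    ok_ref <- s$chrom >= 1 & s$chrom <= n
    bad_bin <- which(ok_ref & !frac_in_class(s$position_frac, s$position_class))
    for (i in bad_bin) {
      v <- c(v, sprintf("%s: site position_frac %.3f outside %s bin",
                        ch$label[s$chrom[i]], s$position_frac[i], s$position_class[i]))
    }
    bad_tok <- which(!(s$family %in% RDNA_FAMILIES) | !(s$arm %in% ARM_NAMES) |
                       !(s$position_class %in% POSITION_CLASSES))
    for (i in bad_tok) v <- c(v, sprintf("site %d: unknown vocabulary token", i))
  }
  if (!k$unbalanced && n > 0 && n != k$ploidy * k$basic_number) {
    v <- c(v, sprintf("balance: 2n = %d but ploidy * x = %d",
                      n, k$ploidy * k$basic_number))
  }
  v
}

#' Monoploid complement of a balanced karyotype
#'
#' Groups the somatic complement into homologue (or homoeologue) groups by
#' genome label and chromosome designation and returns one representative
#' chromosome per group, with arm lengths averaged over the group members and
#' the rDNA sites of the first member. For a diploid this is the x-chromosome
#' monoploid set; for an allotetraploid it returns x representatives per
#' genome present.
#'
#' @param k a balanced [karyotype()].
#' @return list of [chromosome()] objects, ordered by genome then label.
#' @export
monoploid_complement <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  if (k$unbalanced) stop("monoploid_complement() requires a balanced karyotype")
  ch <- k$chrom
  key <- paste(ch$genome, ch$label, sep = "\r")
  groups <- split(seq_len(nrow(ch)), key)
  sizes <- lengths(groups)
  if (length(unique(sizes)) > 1) {
    stop("homologue labels do not partition the complement into equal-size groups")
  }
  ord <- order(vapply(groups, function(ix) ch$genome[ix[1]], ""),
               vapply(groups, function(ix) ch$label[ix[1]], ""))
  lapply(groups[ord], function(ix) {
    first <- get_chromosome(k, ix[1])
    chromosome(
      label = first$label,
      long_um = mean(ch$long_um[ix]), short_um = mean(ch$short_um[ix]),
      sites = first$sites, satellite = first$satellite, genome = first$genome
    )
  })
}
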