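# Reconstructed Phalaris karyotypes and ancestral genome templates.
#
# Per-chromosome arm lengths were never published for these accessions; the
# fixtures reconstruct them deterministically so that the published, testable
# quantities are honoured exactly: 2n, ploidy, genome formula, the 45S/5S
# signal and bearing-chromosome counts, and the total monoploid length (TML).
# Chromosome lengths follow a symmetric linear series scaled to the target
# TML and interchromosomal CV; arm ratios are hand-chosen lists approximating
# the published mean centromeric asymmetry and the m/sm/st composition of the
# idiograms. These are reconstructions, not measurements.

# One monoploid set of x chromosome types, duplicated into `homologues`
# copies. `ratios` is aligned with `labels`; lengths descend from chromosome
# 1. `sites` is a list of fsite() entries.
make_genome_copy <- function(genome, labels, tml_mono, cv_pct, ratios,
                             sites = list(), satellites = character()) {
  x <- length(labels)
  stopifnot(length(ratios) == x)
  mean_len <- tml_mono / x
  if (x > 1 && cv_pct > 0) {
    u <- 1 - 2 * (seq_len(x) - 1) / (x - 1)
    a <- (cv_pct / 100) / stats::sd(u)
    len <- mean_len * (1 + a * u)
  } else {
    len <- rep(mean_len, x)
  }
  stopifnot(all(len > 0))
  out <- vector("list", 2 * x)
  for (i in seq_len(x)) {
    L <- len[i] * ratios[i] / (1 + ratios[i])
    S <- len[i] / (1 + ratios[i])
    for (hom in 1:2) {
      site_rows <- Filter(function(e) {
        e$label == labels[i] && (identical(e$hom, "both") || e$hom == hom)
      }, sites)
      sdf <- if (length(site_rows)) {
        do.call(rbind, lapply(site_rows, function(e) {
          rdna_site(e$family, e$arm, position_class_of(e$frac), e$frac)
        }))
      } else NULL
      out[[2 * (i - 1) + hom]] <- chromosome(
        label = labels[i], long_um = L, short_um = S, sites = sdf,
        satellite = labels[i] %in% satellites, genome = genome
      )
    }
  }
  out
}

fsite <- function(label, hom, family, arm, frac) {
  list(label = label, hom = hom, family = family, arm = arm, frac = frac)
}

assemble_fixture <- function(species, copies, x) {
  chroms <- do.call(c, copies)
  karyotype(species, chroms, ploidy = 2L * length(copies), basic_number = x)
}

#' Reconstructed karyotypes of the eight Phalaris study species
#'
#' Returns the packaged karyotype reconstructions for the four diploid and
#' four tetraploid canary grass species, plus two hypothetical ancestral
#' complements: `PROTO_A`, the fictive all-metacentric x = 7 ancestor of the
#' genome-A lineage on which the descending-dysploidy scenario operates, and
#' `ANCESTRAL_B`, the putatively ancient genome-B diploid karyotype
#' resembling extant P. coerulescens. rDNA signal counts, 2n, ploidy and
#' genome composition match the published observations; arm lengths are
#' documented reconstructions (see the package vignette).
#'
#' @return named list of [karyotype()] objects.
#' @export
#' @examples
#' fx <- phalaris_fixtures()
#' somatic_number(fx[["P. paradoxa"]]) # 14
phalaris_fixtures <- function() {
  fx <- list()

  # -- genome A diploids (x = 6): four sm/st chromosomes (pairs A2/A6), one
  #    45S pair subtelomeric in the short arms of satellite pair A1, one 5S
  #    double-band pair distal in the long arms of A2.
  a_sites <- list(
    fsite("A1", "both", "45S", "SHORT", 0.85),
    fsite("A2", "both", "5S", "LONG", 0.80),
    fsite("A2", "both", "5S", "LONG", 0.90)
  )
  fx[["P. brachystachys"]] <- assemble_fixture(
    "P. brachystachys",
    list(make_genome_copy("A", paste0("A", 1:6), tml_mono = 50.2, cv_pct = 18.4,
                          ratios = c(1.10, 3.80, 1.15, 1.20, 1.30, 4.20),
                          sites = a_sites, satellites = "A1")),
    x = 6L
  )
  fx[["P. canariensis"]] <- assemble_fixture(
    "P. canariensis",
    list(make_genome_copy("A", paste0("A", 1:6), tml_mono = 35.0, cv_pct = 13.3,
                          ratios = c(1.30, 4.20, 1.30, 1.40, 1.50, 4.60),
                          sites = a_sites, satellites = "A1")),
    x = 6L
  )

  # -- P. aquatica: B/C allotetraploid. B copy: intercalary 45S pair (B1),
  #    one subtelomeric + one intercalary 5S on the B2 pair. C copy:
  #    centromere-proximal 45S pair on satellite pair C1 and ten 5S signals
  #    on five chromosomes (C2/C3 pairs doubled, one C4 homologue doubled).
  fx[["P. aquatica"]] <- assemble_fixture(
    "P. aquatica",
    list(
      make_genome_copy("B", paste0("B", 1:7), tml_mono = 49.3, cv_pct = 15.0,
                       ratios = c(1.40, 1.20, 1.20, 1.25, 1.30, 1.30, 1.35),
                       sites = list(
                         fsite("B1", "both", "45S", "SHORT", 0.50),
                         fsite("B2", 1, "5S", "LONG", 0.85),
                         fsite("B2", 2, "5S", "LONG", 0.50)
                       ),
                       satellites = "B1"),
      make_genome_copy("C", paste0("C", 1:7), tml_mono = 49.9, cv_pct = 9.9,
                       ratios = c(1.30, 1.15, 1.20, 1.20, 1.25, 1.25, 1.30),
                       sites = list(
                         fsite("C1", "both", "45S", "SHORT", 0.12),
                         fsite("C2", "both", "5S", "LONG", 0.40),
                         fsite("C2", "both", "5S", "LONG", 0.15),
                         fsite("C3", "both", "5S", "LONG", 0.35),
                         fsite("C3", "both", "5S", "SHORT", 0.50),
                         fsite("C4", 1, "5S", "LONG", 0.45),
                         fsite("C4", 1, "5S", "LONG", 0.65)
                       ),
                       satellites = "C1")
    ),
    x = 7L
  )

  # -- P. minor: B/C allotetraploid after nucleolar dominance: the C copy has
  #    lost its 45S pair; 16 5S signals across 14 chromosomes (B2, B3, C2-C6,
  #    the C6 pair carrying the subtelomeric double site).
  fx[["P. minor"]] <- assemble_fixture(
    "P. minor",
    list(
      make_genome_copy("B", paste0("B", 1:7), tml_mono = 33.9, cv_pct = 18.0,
                       ratios = c(1.25, 1.15, 1.20, 1.20, 1.25, 1.30, 1.30),
                       sites = list(
                         fsite("B1", "both", "45S", "SHORT", 0.50),
                         fsite("B2", "both", "5S", "LONG", 0.50),
                         fsite("B3", "both", "5S", "SHORT", 0.45)
                       ),
                       satellites = "B1"),
      make_genome_copy("C", paste0("C", 1:7), tml_mono = 43.9, cv_pct = 18.0,
                       ratios = c(1.20, 1.15, 1.20, 1.25, 1.25, 1.30, 1.30),
                       sites = list(
                         fsite("C2", "both", "5S", "LONG", 0.40),
                         fsite("C3", "both", "5S", "LONG", 0.15),
                         fsite("C4", "both", "5S", "SHORT", 0.50),
                         fsite("C5", "both", "5S", "LONG", 0.60),
                         fsite("C6", "both", "5S", "LONG", 0.80),
                         fsite("C6", "both", "5S", "LONG", 0.90)
                       ))
    ),
    x = 7L
  )

  # -- P. paradoxa: genome B diploid; intercalary 45S in the long arms of
  #    B1, intercalary 5S in the short arms of B2.
  fx[["P. paradoxa"]] <- assemble_fixture(
    "P. paradoxa",
    list(make_genome_copy("B", paste0("B", 1:7), tml_mono = 30.3, cv_pct = 14.7,
                          ratios = c(1.10, 1.15, 1.20, 1.20, 1.25, 1.25, 1.35),
                          sites = list(
                            fsite("B1", "both", "45S", "LONG", 0.50),
                            fsite("B2", "both", "5S", "SHORT", 0.50)
                          ),
                          satellites = "B1")),
    x = 7L
  )

  # -- P. caroliniana: BB autotetraploid; intercalary 45S in short arms of
  #    B1; subtelomeric 5S on B2, in the short arms of one genome copy and
  #    the long arms of the other.
  caroliniana_copy <- function(s5_arm) {
    make_genome_copy("B", paste0("B", 1:7), tml_mono = 47.6, cv_pct = 13.1,
                     ratios = c(1.30, 1.10, 1.15, 1.15, 1.20, 1.20, 1.25),
                     sites = list(
                       fsite("B1", "both", "45S", "SHORT", 0.50),
                       fsite("B2", "both", "5S", s5_arm, 0.85)
                     ),
                     satellites = "B1")
  }
  fx[["P. caroliniana"]] <- assemble_fixture(
    "P. caroliniana", list(caroliniana_copy("SHORT"), caroliniana_copy("LONG")),
    x = 7L
  )

  # -- P. coerulescens: genome B diploid with the putatively ancient B
  #    pattern: intercalary 45S (B1), intercalary 5S pair (B2) plus one
  #    subtelomeric 5S on a single B3 homologue (3 signals on 3 chromosomes).
  fx[["P. coerulescens"]] <- assemble_fixture(
    "P. coerulescens",
    list(make_genome_copy("B", paste0("B", 1:7), tml_mono = 49.6, cv_pct = 12.6,
                          ratios = c(2.20, 1.20, 1.20, 1.30, 1.30, 1.40, 1.50),
                          sites = list(
                            fsite("B1", "both", "45S", "LONG", 0.50),
                            fsite("B2", "both", "5S", "LONG", 0.50),
                            fsite("B3", 1, "5S", "LONG", 0.85)
                          ),
                          satellites = "B1")),
    x = 7L
  )

  # -- P. arundinacea: BB autotetraploid; each B1 pair carries one mid-arm
  #    and one proximal 45S in the short arms (the proximal signal sits just
  #    inside the intercalary bin, next to the secondary constriction); the
  #    intercalary 5S pair on B2 survives in only one genome copy.
  arundinacea_copy <- function(with_5s) {
    sites <- list(
      fsite("B1", 1, "45S", "SHORT", 0.50),
      fsite("B1", 2, "45S", "SHORT", 0.32)
    )
    if (with_5s) sites <- c(sites, list(fsite("B2", "both", "5S", "LONG", 0.50)))
    make_genome_copy("B", paste0("B", 1:7), tml_mono = 46.0, cv_pct = 15.4,
                     ratios = c(1.50, 1.20, 1.20, 1.25, 1.30, 1.30, 1.40),
                     sites = sites, satellites = "B1")
  }
  fx[["P. arundinacea"]] <- assemble_fixture(
    "P. arundinacea", list(arundinacea_copy(TRUE), arundinacea_copy(FALSE)),
    x = 7L
  )

  fx[["PROTO_A"]] <- proto_a_karyotype()
  fx[["ANCESTRAL_B"]] <- ancestral_b_karyotype()
  fx
}

#' Hypothetical ancestral genome-A karyotype (PROTO_A)
#'
#' The fictive all-metacentric x = 7 diploid ancestor of the genome-A
#' lineage: seven metacentric chromosome pairs, a subtelomeric 45S pair in
#' the short arms of proto-A1, a subtelomeric 5S pair in the long arms of
#' proto-A2, and the centromere-proximal 5S pair in the long arms of
#' proto-A7 whose pericentromeric fission drives the descending-dysploidy
#' scenario. Arm lengths are chosen so that TML (40 um) stays within the
#' range observed across the extant species.
#'
#' @return a diploid [karyotype()], 2n = 14.
#' @export
proto_a_karyotype <- function() {
  arms <- c(A1 = 3.50, A2 = 2.50, A3 = 3.25, A4 = 2.90, A5 = 2.60,
            A6 = 2.25, A7 = 3.00)
  chroms <- list()
  for (lab in names(arms)) {
    sdf <- switch(lab,
      A1 = rdna_site("45S", "SHORT", "SUBTELOMERIC", 0.85),
      A2 = rdna_site("5S", "LONG", "SUBTELOMERIC", 0.85),
      A7 = rdna_site("5S", "LONG", "CENTROMERIC_PROXIMAL", 0.10),
      NULL
    )
    for (hom in 1:2) {
      chroms[[length(chroms) + 1]] <- chromosome(
        lab, long_um = arms[[lab]], short_um = arms[[lab]], sites = sdf,
        satellite = identical(lab, "A1"), genome = "A"
      )
    }
  }
  karyotype("PROTO_A", chroms, ploidy = 2L, basic_number = 7L)
}

ancestral_b_karyotype <- function() {
  copy <- make_genome_copy(
    "B", paste0("B", 1:7), tml_mono = 49.6, cv_pct = 13.0,
    ratios = c(1.40, 1.20, 1.20, 1.25, 1.30, 1.30, 1.35),
    sites = list(
      fsite("B1", "both", "45S", "LONG", 0.50),
      fsite("B2", "both", "5S", "LONG", 0.50),
      fsite("B3", "both", "5S", "LONG", 0.85)
    ),
    satellites = "B1"
  )
  assemble_fixture("ANCESTRAL_B", list(copy), x = 7L)
}

#' Diploid template karyotype of one genome signature
#'
#' Builds a minimal diploid complement that satisfies every rule of the
#' requested genome signature (see [builtin_signatures()]): the genome-A
#' template mirrors the x = 6 species, the genome-B template the symmetric
#' x = 7 pattern with intercalary 45S and subtelomeric 5S, and the genome-C
#' template the x = 7 pattern with centromere-proximal 45S and five 5S pairs.
#'
#' @param label `"A"`, `"B"` or `"C"`.
#' @return a diploid [karyotype()].
#' @export
genome_template <- function(label = c("A", "B", "C")) {
  label <- match.arg(label)
  copy <- switch(label,
    A = make_genome_copy("A", paste0("A", 1:6), tml_mono = 42.0, cv_pct = 15.0,
                         ratios = c(1.20, 4.00, 1.20, 1.30, 1.30, 4.00),
                         sites = list(
                           fsite("A1", "both", "45S", "SHORT", 0.85),
                           fsite("A2", "both", "5S", "LONG", 0.80),
                           fsite("A2", "both", "5S", "LONG", 0.90)
                         ),
                         satellites = "A1"),
    B = make_genome_copy("B", paste0("B", 1:7), tml_mono = 49.6, cv_pct = 13.0,
                         ratios = c(1.40, 1.20, 1.20, 1.25, 1.30, 1.30, 1.35),
                         sites = list(
                           fsite("B1", "both", "45S", "LONG", 0.50),
                           fsite("B2", "both", "5S", "LONG", 0.85)
                         ),
                         satellites = "B1"),
    C = make_genome_copy("C", paste0("C", 1:7), tml_mono = 49.9, cv_pct = 10.0,
                         ratios = c(1.30, 1.15, 1.20, 1.20, 1.25, 1.25, 1.30),
                         sites = list(
                           fsite("C1", "both", "45S", "SHORT", 0.12),
                           fsite("C2", "both", "5S", "LONG", 0.40),
                           fsite("C2", "both", "5S", "LONG", 0.15),
                           fsite("C3", "both", "5S", "LONG", 0.35),
                           fsite("C3", "both", "5S", "SHORT", 0.50),
                           fsite("C4", "both", "5S", "LONG", 0.45)
                         ),
                         satellites = "C1")
  )
  assemble_fixture(paste0("GENOME_", label, "_TEMPLATE"), list(copy),
                   x = if (label == "A") 6L else 7L)
}
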