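# Chromosome rearrangement events and scenario replay.
#
# Every event maps a karyotype to a karyotype and conserves total chromatin
# length (acentric segments in flight included); only rDNA gain/loss events
# change the site inventory, and no event changes arm lengths except through
# explicit exchange of material. Within-arm coordinates are fractions from
# the centromere (0) to the telomere (1); position classes are recomputed
# from the fractions after every event.

# ---- internal karyotype surgery -------------------------------------------

k_sites_of <- function(k, i) which(k$sites$chrom == i)

# Remove chromosomes by row index, remapping site references.
k_remove_chroms <- function(k, idx) {
  keep <- setdiff(seq_len(nrow(k$chrom)), idx)
  map <- integer(nrow(k$chrom))
  map[keep] <- seq_along(keep)
  sites <- k$sites[k$sites$chrom %in% keep, , drop = FALSE]
  sites$chrom <- map[sites$chrom]
  new_karyotype(k$species, k$chrom[keep, , drop = FALSE], sites,
                k$ploidy, k$basic_number, unbalanced = TRUE)
}

# Replace chromosome i by a chromosome object (sites replaced too).
k_replace_chrom <- function(k, i, cc) {
  k$chrom$label[i] <- cc$label
  k$chrom$genome[i] <- cc$genome
  k$chrom$long_um[i] <- cc$long_um
  k$chrom$short_um[i] <- cc$short_um
  k$chrom$satellite[i] <- encode_satellite(cc$satellite)
  sites <- k$sites[k$sites$chrom != i, , drop = FALSE]
  if (nrow(cc$sites)) {
    sites <- rbind(sites, cbind(data.frame(chrom = i), cc$sites))
  }
  k$sites <- sites[order(sites$chrom), , drop = FALSE]
  rownames(k$sites) <- NULL
  k
}

homologue_indices <- function(k, label, apply_to_homologues = TRUE) {
  idx <- which(k$chrom$label == label)
  if (length(idx) == 0) stop(sprintf("no chromosome labelled '%s'", label))
  if (!apply_to_homologues) {
    if (length(idx) > 1) {
      stop(sprintf("label '%s' is ambiguous with homologue application off", label))
    }
  }
  idx
}

reclass_sites <- function(sites) {
  if (nrow(sites)) sites$position_class <- position_class_of(sites$position_frac)
  sites
}

# ---- events ----------------------------------------------------------------

#' Pericentromeric fission of a chromosome
#'
#' Breaks the chromosome at the centromere: the chromosome leaves the
#' complement (the centromere is modelled as lost with zero length) and its
#' two arms survive as acentric segments whose site positions are
#' re-expressed as fractions from the former centromeric end. The resulting
#' karyotype is flagged unbalanced until the segments are fused elsewhere.
#' A paracentromeric break offset is accepted for forward compatibility but
#' ignored: the break is placed exactly at the centromere.
#'
#' @param k a [karyotype()].
#' @param label chromosome designation to break.
#' @param break_frac accepted and ignored (break at the centromere).
#' @param apply_to_homologues operate on every chromosome with this label
#'   (default), producing one segment pair per homologue.
#' @return list with elements `karyotype` (unbalanced) and `segments`
#'   (list of acentric segments, former long arm then former short arm per
#'   homologue).
#' @export
fission_pericentromeric <- function(k, label, break_frac = 0,
                                    apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  idx <- homologue_indices(k, label, apply_to_homologues)
  segments <- list()
  for (i in idx) {
    cc <- get_chromosome(k, i)
    for (part in c("long", "short")) {
      len <- if (part == "long") cc$long_um else cc$short_um
      arm <- toupper(part)
      s <- cc$sites[cc$sites$arm == arm, c("family", "position_class", "position_frac"),
                    drop = FALSE]
      rownames(s) <- NULL
      segments[[length(segments) + 1]] <- structure(
        list(origin_label = cc$label, part = part, length_um = len, sites = s),
        class = "acentric_segment"
      )
    }
  }
  list(karyotype = k_remove_chroms(k, idx), segments = segments)
}

#' Telomere-to-telomere (end-to-end) fusion of an acentric segment
#'
#' Appends an acentric segment distal to the telomere of the chosen
#' recipient arm. The segment joins by its former telomeric end, so its
#' former centromeric end becomes the new arm terminus and the original
#' centromere-telomere polarity of the material is maintained. Recipient arm
#' length grows by the segment length; all site positions on the fused arm
#' are re-expressed over the new length and re-binned. Arm naming is
#' re-normalized (the fused arm usually becomes the long arm).
#'
#' @param k a [karyotype()].
#' @param recipient_label designation of the recipient chromosome.
#' @param segments one acentric segment, or a list with one segment per
#'   recipient homologue.
#' @param recipient_arm `"LONG"` or `"SHORT"`.
#' @param apply_to_homologues fuse one segment onto every homologue of the
#'   recipient (default).
#' @return the karyotype with the fused chromosomes (still unbalanced if it
#'   was before).
#' @export
end_to_end_fusion <- function(k, recipient_label, segments,
                              recipient_arm = c("LONG", "SHORT"),
                              apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  recipient_arm <- match.arg(recipient_arm)
  if (inherits(segments, "acentric_segment")) segments <- list(segments)
  idx <- homologue_indices(k, recipient_label, apply_to_homologues)
  if (length(segments) != length(idx)) {
    stop(sprintf("need %d segment(s) for %d recipient homologue(s), got %d",
                 length(idx), length(idx), length(segments)))
  }
  for (j in seq_along(idx)) {
    i <- idx[j]
    seg <- segments[[j]]
    stopifnot(inherits(seg, "acentric_segment"))
    cc <- get_chromosome(k, i)
    a <- if (recipient_arm == "LONG") cc$long_um else cc$short_um
    new_len <- a + seg$length_um
    s <- cc$sites
    if (nrow(s)) {
      on_arm <- s$arm == recipient_arm
      s$position_frac[on_arm] <- s$position_frac[on_arm] * a / new_len
    }
    if (nrow(seg$sites)) {
      d <- a + seg$length_um * (1 - seg$sites$position_frac)
      s <- rbind(s, data.frame(
        family = seg$sites$family, arm = recipient_arm,
        position_class = NA_character_, position_frac = d / new_len,
        stringsAsFactors = FALSE
      ))
    }
    s <- reclass_sites(s)
    long_um <- if (recipient_arm == "LONG") new_len else cc$long_um
    short_um <- if (recipient_arm == "SHORT") new_len else cc$short_um
    k <- k_replace_chrom(k, i, chromosome(
      cc$label, long_um, short_um, sites = s, satellite = cc$satellite,
      genome = cc$genome
    ))
  }
  k
}

#' Pericentric inversion
#'
#' Inverts the segment spanning the centromere between a breakpoint on each
#' arm (fractions of the respective arm length from the centromere). Material
#' and sites proximal to each breakpoint change sides; distal material stays
#' in place. Total chromosome length is conserved, arm lengths generally
#' change, and arm names are re-normalized. Breakpoints at both telomeres
#' invert the entire chromosome, which is observationally the identity.
#'
#' @param k a [karyotype()].
#' @param label chromosome designation.
#' @param frac_short,frac_long breakpoint fractions in `[0, 1]` on the short
#'   and long arm.
#' @param apply_to_homologues operate on every homologue (default).
#' @return the modified karyotype.
#' @export
pericentric_inversion <- function(k, label, frac_short, frac_long,
                                  apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  stopifnot(frac_short >= 0, frac_short <= 1, frac_long >= 0, frac_long <= 1)
  idx <- homologue_indices(k, label, apply_to_homologues)
  for (i in idx) {
    cc <- get_chromosome(k, i)
    S <- cc$short_um; L <- cc$long_um
    ds <- frac_short * S; dl <- frac_long * L
    side_s <- S - ds + dl   # side holding the former short-arm distal material
    side_l <- L - dl + ds
    s <- cc$sites
    if (nrow(s)) {
      d <- ifelse(s$arm == "SHORT", s$position_frac * S, s$position_frac * L)
      new_arm <- s$arm
      new_d <- d
      on_short <- s$arm == "SHORT"
      in_seg <- ifelse(on_short, d <= ds, d <= dl)
      # proximal sites swap sides, keeping their distance from the centromere
      new_arm[in_seg & on_short] <- "LONG"
      new_arm[in_seg & !on_short] <- "SHORT"
      # distal sites keep their side; distance shifts by the segment exchange
      new_d[!in_seg & on_short] <- d[!in_seg & on_short] - ds + dl
      new_d[!in_seg & !on_short] <- d[!in_seg & !on_short] - dl + ds
      new_len <- ifelse(new_arm == "SHORT", side_s, side_l)
      s$arm <- new_arm
      s$position_frac <- pmin(1, new_d / new_len)
      s <- reclass_sites(s)
    }
    sat <- cc$satellite
    k <- k_replace_chrom(k, i, chromosome(
      cc$label, long_um = side_l, short_um = side_s, sites = s,
      satellite = sat, genome = cc$genome
    ))
  }
  k
}

#' Paracentric inversion
#'
#' Inverts an interval `[frac_a, frac_b]` within one arm (the centromere is
#' not involved): site positions inside the interval are mirrored,
#' `p -> frac_a + frac_b - p`, arm lengths are unchanged, and position
#' classes are recomputed. Applying the same inversion twice is the
#' identity.
#'
#' @param k a [karyotype()].
#' @param label chromosome designation.
#' @param arm `"LONG"` or `"SHORT"`.
#' @param frac_a,frac_b interval bounds with `0 <= frac_a < frac_b <= 1`.
#' @param apply_to_homologues operate on every homologue (default).
#' @return the modified karyotype.
#' @export
paracentric_inversion <- function(k, label, arm = c("LONG", "SHORT"),
                                  frac_a, frac_b, apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  arm <- match.arg(arm)
  if (!(frac_a >= 0 && frac_b <= 1 && frac_a < frac_b)) {
    stop("need 0 <= frac_a < frac_b <= 1")
  }
  idx <- homologue_indices(k, label, apply_to_homologues)
  sel_chrom <- k$sites$chrom %in% idx & k$sites$arm == arm &
    k$sites$position_frac >= frac_a & k$sites$position_frac <= frac_b
  k$sites$position_frac[sel_chrom] <- frac_a + frac_b - k$sites$position_frac[sel_chrom]
  k$sites <- reclass_sites(k$sites)
  k
}

#' Reciprocal translocation of terminal segments
#'
#' Exchanges the material distal to a breakpoint on one arm of each of two
#' chromosomes. The chromosome count is unchanged, total length is
#' conserved, and sites travel with their segments (distance from the
#' breakpoint preserved). Homologues are translocated pairwise in complement
#' order.
#'
#' @param k a [karyotype()].
#' @param label1,label2 designations of the two (distinct) chromosomes.
#' @param arm1,arm2 arm of each chromosome (`"LONG"`/`"SHORT"`).
#' @param frac1,frac2 breakpoint fractions in `[0, 1]` (1 = empty distal
#'   segment).
#' @param apply_to_homologues operate on every homologue pair (default).
#' @return the modified karyotype.
#' @export
reciprocal_translocation <- function(k, label1, arm1 = "LONG", frac1,
                                     label2, arm2 = "LONG", frac2,
                                     apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  if (identical(label1, label2)) stop("reciprocal translocation needs two distinct chromosomes")
  stopifnot(frac1 >= 0, frac1 <= 1, frac2 >= 0, frac2 <= 1)
  arm1 <- match.arg(arm1, ARM_NAMES); arm2 <- match.arg(arm2, ARM_NAMES)
  idx1 <- homologue_indices(k, label1, apply_to_homologues)
  idx2 <- homologue_indices(k, label2, apply_to_homologues)
  if (length(idx1) != length(idx2)) {
    stop("homologue counts of the two chromosomes differ")
  }
  cut_arm <- function(cc, arm, frac) {
    a <- if (arm == "LONG") cc$long_um else cc$short_um
    d <- frac * a
    s <- cc$sites
    on <- s$arm == arm & s$position_frac * a > d
    list(keep_len = d, seg_len = a - d,
         seg_sites = transform(s[on, , drop = FALSE], dist = position_frac * a - d),
         keep_sites = s[!on, , drop = FALSE], arm_len = a)
  }
  rebuild <- function(cc, arm, cut, incoming) {
    new_len <- cut$keep_len + incoming$seg_len
    s <- cut$keep_sites
    on <- s$arm == arm
    # retained sites keep their absolute distance from the centromere
    s$position_frac[on] <- (s$position_frac[on] * cut$arm_len) / new_len
    if (nrow(incoming$seg_sites)) {
      s <- rbind(s, data.frame(
        family = incoming$seg_sites$family, arm = arm,
        position_class = NA_character_,
        position_frac = (cut$keep_len + incoming$seg_sites$dist) / new_len,
        stringsAsFactors = FALSE
      ))
    }
    s <- reclass_sites(s)
    long_um <- if (arm == "LONG") new_len else cc$long_um
    short_um <- if (arm == "SHORT") new_len else cc$short_um
    chromosome(cc$label, long_um, short_um, sites = s,
               satellite = cc$satellite, genome = cc$genome)
  }
  for (j in seq_along(idx1)) {
    c1 <- get_chromosome(k, idx1[j]); c2 <- get_chromosome(k, idx2[j])
    cut1 <- cut_arm(c1, arm1, frac1); cut2 <- cut_arm(c2, arm2, frac2)
    k <- k_replace_chrom(k, idx1[j], rebuild(c1, arm1, cut1, cut2))
    k <- k_replace_chrom(k, idx2[j], rebuild(c2, arm2, cut2, cut1))
  }
  k
}

#' Whole-genome duplication (autopolyploidy)
#'
#' Replicates every somatic chromosome so that ploidy and 2n multiply by
#' `factor`. All karyological asymmetry statistics and TML are invariant
#' under this operation.
#'
#' @param k a balanced [karyotype()].
#' @param factor integer multiplication factor, at least 2.
#' @return the polyploidized karyotype.
#' @export
autopolyploidize <- function(k, factor) {
  stopifnot(inherits(k, "karyotype"))
  if (!is.numeric(factor) || factor != round(factor) || factor < 2) {
    stop("autopolyploidize() needs an integer factor >= 2")
  }
  if (k$unbalanced) stop("autopolyploidize() requires a balanced karyotype")
  factor <- as.integer(factor)
  n <- nrow(k$chrom)
  chrom <- k$chrom[rep(seq_len(n), factor), , drop = FALSE]
  sites <- do.call(rbind, lapply(seq_len(factor) - 1L, function(rep_i) {
    s <- k$sites
    s$chrom <- s$chrom + rep_i * n
    s
  }))
  if (is.null(sites)) sites <- empty_sites_df()
  new_karyotype(k$species, chrom, sites, k$ploidy * factor, k$basic_number)
}

#' Allopolyploid (amphidiploid) genome merger
#'
#' Unites the somatic complements of two balanced karyotypes with the same
#' basic number into one nucleus: ploidy levels add, genome labels are
#' preserved, and the rDNA complements of both parents are retained.
#' Chromosomes of both parents must carry genome labels, or parental
#' provenance would be lost.
#'
#' @param k1,k2 balanced [karyotype()] objects.
#' @param species name of the merged karyotype (default
#'   `"<sp1> x <sp2>"`).
#' @return the merged karyotype.
#' @export
allopolyploid_merge <- function(k1, k2, species = NULL) {
  stopifnot(inherits(k1, "karyotype"), inherits(k2, "karyotype"))
  if (somatic_number(k2) == 0) return(k1)
  if (somatic_number(k1) == 0) return(k2)
  if (k1$unbalanced || k2$unbalanced) stop("both parents must be balanced")
  if (k1$basic_number != k2$basic_number) {
    stop("parents differ in basic number; amphidiploid bookkeeping undefined")
  }
  if (anyNA(k1$chrom$genome) || anyNA(k2$chrom$genome) ||
      any(k1$chrom$genome == "NA") || any(k2$chrom$genome == "NA")) {
    stop("all chromosomes must carry genome labels before an allopolyploid merge")
  }
  if (is.null(species)) species <- paste(k1$species, "x", k2$species)
  n1 <- nrow(k1$chrom)
  s2 <- k2$sites
  s2$chrom <- s2$chrom + n1
  new_karyotype(species, rbind(k1$chrom, k2$chrom), rbind(k1$sites, s2),
                k1$ploidy + k2$ploidy, k1$basic_number)
}

#' Remove rDNA sites matching a selector
#'
#' Models locus loss (e.g. nucleolar dominance in an allopolyploid): all
#' sites of the family matching the selector are removed; chromosome lengths
#' are untouched. The selector may restrict by chromosome label, genome,
#' arm, and position class; `limit` keeps the loss to the first `limit`
#' matching chromosomes in complement order (a single pair for
#' `limit = 2`).
#'
#' @param k a [karyotype()].
#' @param family `"5S"` or `"45S"`.
#' @param label,genome,arm,position_class optional selector components.
#' @param limit optional cap on the number of chromosomes stripped.
#' @param strict error when nothing matches (default); set `FALSE` for a
#'   silent no-op.
#' @return the karyotype without the matching sites.
#' @export
rdna_loss <- function(k, family, label = NULL, genome = NULL, arm = NULL,
                      position_class = NULL, limit = NULL, strict = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  family <- match.arg(family, RDNA_FAMILIES)
  s <- k$sites
  sel <- s$family == family
  if (!is.null(label)) sel <- sel & k$chrom$label[s$chrom] %in% label
  if (!is.null(genome)) sel <- sel & k$chrom$genome[s$chrom] %in% genome
  if (!is.null(arm)) sel <- sel & s$arm == match.arg(arm, ARM_NAMES)
  if (!is.null(position_class)) {
    sel <- sel & s$position_class == match.arg(position_class, POSITION_CLASSES)
  }
  if (!any(sel)) {
    if (strict) stop("rdna_loss selector matched no site")
    return(k)
  }
  if (!is.null(limit)) {
    keep_chroms <- utils::head(sort(unique(s$chrom[sel])), limit)
    sel <- sel & s$chrom %in% keep_chroms
  }
  k$sites <- s[!sel, , drop = FALSE]
  rownames(k$sites) <- NULL
  k
}

#' Add an rDNA site to a chromosome (and its homologues)
#'
#' @param k a [karyotype()].
#' @param label chromosome designation.
#' @param family,arm,position_class,position_frac site description as in
#'   [rdna_site()].
#' @param apply_to_homologues add to every homologue (default).
#' @return the karyotype with the added sites.
#' @export
rdna_gain <- function(k, label, family, arm, position_class,
                      position_frac = NULL, apply_to_homologues = TRUE) {
  stopifnot(inherits(k, "karyotype"))
  idx <- homologue_indices(k, label, apply_to_homologues)
  site <- rdna_site(family, arm, position_class, position_frac)
  add <- do.call(rbind, lapply(idx, function(i) cbind(data.frame(chrom = i), site)))
  k$sites <- rbind(k$sites, add)
  k$sites <- k$sites[order(k$sites$chrom), , drop = FALSE]
  rownames(k$sites) <- NULL
  k
}

total_chromatin <- function(k, pool = list()) {
  sum(k$chrom$long_um + k$chrom$short_um) +
    sum(vapply(pool, `[[`, 0, "length_um"))
}
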