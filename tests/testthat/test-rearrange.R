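test_that("pericentromeric fission removes the chromosome and frees its arms", {
  k <- proto_a_karyotype()
  res <- fission_pericentromeric(k, "A7")
  expect_identical(somatic_number(res$karyotype), 12L)
  expect_true(res$karyotype$unbalanced)
  expect_length(res$segments, 4) # long + short per homologue
  long_segs <- Filter(function(s) s$part == "long", res$segments)
  expect_equal(vapply(long_segs, `[[`, 0, "length_um"), c(3, 3))
  # the proximal 5S travels on the long-arm segment, position kept from the
  # former centromeric end
  expect_identical(nrow(long_segs[[1]]$sites), 1L)
  expect_equal(long_segs[[1]]$sites$position_frac, 0.1)
  expect_error(fission_pericentromeric(k, "Z9"), "no chromosome")
})

test_that("end-to-end fusion appends the segment distally with kept polarity", {
  k <- karyotype("t", list(chromosome("R", 2, 2, sites = rdna_site("5S", "LONG", "SUBTELOMERIC", 0.8))),
                 ploidy = 1, basic_number = 1)
  seg <- structure(list(origin_label = "D", part = "long", length_um = 3,
                        sites = data.frame(family = "5S", position_class = "CENTROMERIC_PROXIMAL",
                                           position_frac = 0.1, stringsAsFactors = FALSE)),
                   class = "acentric_segment")
  k2 <- end_to_end_fusion(k, "R", seg, "LONG")
  cc <- get_chromosome(k2, 1)
  expect_equal(cc$long_um, 5)
  expect_equal(cc$short_um, 2)
  expect_identical(classify_morphology(cc), "sm") # r = 2.5
  # recipient site compressed onto the proximal part, segment site distal
  # (former centromeric end of the segment becomes the terminus)
  expect_equal(sort(cc$sites$position_frac), c(0.8 * 2 / 5, (2 + 3 * 0.9) / 5))
  expect_equal(total_len(k2), total_len(k) + 3)
})

test_that("pericentric inversion conserves length and moves proximal material", {
  k <- karyotype("t", list(
    chromosome("P", 5, 2, sites = rbind(
      rdna_site("5S", "SHORT", "CENTROMERIC_PROXIMAL", 0.2), # d = 0.4, inside
      rdna_site("45S", "LONG", "TELOMERIC", 0.98)            # d = 4.9, outside
    ))
  ), ploidy = 1, basic_number = 1)
  # breakpoints at 0.5 on each arm: ds = 1, dl = 2.5
  k2 <- pericentric_inversion(k, "P", 0.5, 0.5)
  cc <- get_chromosome(k2, 1)
  expect_equal(total_len(k2), 7)
  expect_equal(sort(c(cc$long_um, cc$short_um)), c(3.5, 3.5))
  s5 <- cc$sites[cc$sites$family == "5S", ]
  # proximal site swapped sides, keeping its 0.4 um distance
  expect_equal(s5$position_frac * 3.5, 0.4)
  s45 <- cc$sites[cc$sites$family == "45S", ]
  # distal site kept its side; distance shifted by the exchanged proximal parts
  expect_equal(s45$position_frac * 3.5, 4.9 - 2.5 + 1)
  # zero-fraction breakpoints are the identity
  k3 <- pericentric_inversion(k, "P", 0, 0)
  expect_equal(k3$chrom, k$chrom)
  expect_equal(k3$sites, k$sites)
  expect_error(pericentric_inversion(k, "P", -0.1, 0.5))
})

test_that("whole-chromosome pericentric inversion is observationally the identity", {
  k <- karyotype("t", list(chromosome("P", 5, 2, sites = rdna_site("5S", "SHORT", "INTERCALARY", 0.5))),
                 ploidy = 1, basic_number = 1)
  k2 <- pericentric_inversion(k, "P", 1, 1)
  cc <- get_chromosome(k2, 1)
  expect_equal(c(cc$long_um, cc$short_um), c(5, 2))
  expect_identical(cc$sites$arm, "SHORT")
  expect_equal(cc$sites$position_frac, 0.5)
})

test_that("paracentric inversion mirrors site positions and is an involution", {
  k <- karyotype("t", list(chromosome("P", 5, 2, sites = rdna_site("5S", "LONG", "SUBTELOMERIC", 0.9))),
                 ploidy = 1, basic_number = 1)
  k2 <- paracentric_inversion(k, "P", "LONG", 0.5, 1.0)
  expect_equal(k2$sites$position_frac, 0.6)
  expect_identical(k2$sites$position_class, "INTERCALARY")
  expect_equal(k2$chrom, k$chrom) # arm lengths untouched
  # interval without sites: no-op
  k3 <- paracentric_inversion(k, "P", "SHORT", 0.1, 0.4)
  expect_equal(k3$sites, k$sites)
  # involution
  k4 <- paracentric_inversion(k2, "P", "LONG", 0.5, 1.0)
  expect_equal(k4$sites$position_frac, k$sites$position_frac)
  expect_error(paracentric_inversion(k, "P", "LONG", 0.8, 0.2), "frac")
})

test_that("reciprocal translocation exchanges distal segments conservatively", {
  mk <- function() karyotype("t", list(
    chromosome("X", 4, 2, sites = rdna_site("5S", "LONG", "TELOMERIC", 0.96)),
    chromosome("Y", 5, 3, sites = rdna_site("45S", "LONG", "SUBTELOMERIC", 0.9))
  ), ploidy = 1, basic_number = 2)
  k <- mk()
  # equal-length distal segments (1 um each) swap the sites only
  k2 <- reciprocal_translocation(k, "X", "LONG", 0.75, "Y", "LONG", 0.8)
  expect_equal(k2$chrom$long_um, k$chrom$long_um)
  expect_identical(k2$sites$family[k2$sites$chrom == 1], "45S")
  expect_identical(k2$sites$family[k2$sites$chrom == 2], "5S")
  expect_equal(total_len(k2), total_len(k))
  # empty distal segments: identity
  k3 <- reciprocal_translocation(k, "X", "LONG", 1, "Y", "LONG", 1)
  expect_equal(k3$chrom, k$chrom)
  expect_equal(k3$sites, k$sites)
  expect_error(reciprocal_translocation(k, "X", "LONG", 0.5, "X", "LONG", 0.5), "distinct")
})

test_that("random inversions and translocations conserve chromatin and sites", {
  set.seed(99)
  for (rep in 1:1000) {
    k <- random_karyotype(n = 6, with_sites = TRUE)
    len0 <- total_len(k)
    n_sites0 <- nrow(k$sites)
    op <- rep %% 3
    k2 <- if (op == 0) {
      pericentric_inversion(k, "K2", stats::runif(1), stats::runif(1))
    } else if (op == 1) {
      f <- sort(stats::runif(2))
      paracentric_inversion(k, "K3", sample(c("LONG", "SHORT"), 1), f[1], f[2])
    } else {
      reciprocal_translocation(k, "K1", sample(c("LONG", "SHORT"), 1), stats::runif(1),
                               "K4", sample(c("LONG", "SHORT"), 1), stats::runif(1))
    }
    expect_equal(total_len(k2), len0, tolerance = 1e-9)
    expect_identical(nrow(k2$sites), n_sites0)
    expect_identical(validate_karyotype(k2), character(0))
  }
})

test_that("autopolyploidization multiplies ploidy and 2n", {
  b <- genome_template("B")
  k4 <- autopolyploidize(b, 2)
  expect_identical(somatic_number(k4), 28L)
  expect_identical(k4$ploidy, 4L)
  k6 <- autopolyploidize(b, 3)
  expect_identical(somatic_number(k6), 42L)
  expect_error(autopolyploidize(b, 1), "factor")
})

test_that("allopolyploid merge unites complements and bookkeeping", {
  b <- genome_template("B"); c_ <- genome_template("C")
  m <- allopolyploid_merge(b, c_, species = "BxC")
  expect_identical(somatic_number(m), 28L)
  expect_identical(m$ploidy, 4L)
  expect_identical(unname(count_rdna(m, "45S")), c(4L, 4L))
  expect_identical(unname(count_rdna(m, "5S")),
                   unname(count_rdna(b, "5S") + count_rdna(c_, "5S")))
  # octoploid: two tetraploids
  fx <- phalaris_fixtures()
  oct <- allopolyploid_merge(fx[["P. arundinacea"]], fx[["P. aquatica"]])
  expect_identical(somatic_number(oct), 56L)
  expect_identical(oct$ploidy, 8L)
  # merge with an empty karyotype is the identity
  empty <- karyotype("none", list(), ploidy = 0, basic_number = 0, unbalanced = TRUE)
  expect_identical(allopolyploid_merge(b, empty), b)
  # unlabelled chromosomes lose provenance: refused
  anon <- karyotype("anon", lapply(1:14, function(i) {
    chromosome(sprintf("z%d", ceiling(i / 2)), 2, 1)
  }), ploidy = 2, basic_number = 7)
  expect_error(allopolyploid_merge(b, anon), "genome label")
})

test_that("rdna loss and gain edit only the site inventory", {
  m <- allopolyploid_merge(genome_template("B"), genome_template("C"))
  lost <- rdna_loss(m, "45S", genome = "C")
  expect_identical(unname(count_rdna(lost, "45S")), c(2L, 2L))
  expect_equal(total_len(lost), total_len(m))
  b <- genome_template("B")
  b2 <- rdna_loss(b, "5S", label = "B2")
  expect_identical(unname(count_rdna(b2, "5S")), c(0L, 0L))
  expect_error(rdna_loss(b, "5S", label = "B9"), "matched no site")
  expect_identical(rdna_loss(b, "5S", label = "B9", strict = FALSE), b)
  # limit restricts the loss to the first matching pair
  k4 <- autopolyploidize(b, 2)
  half <- rdna_loss(k4, "5S", label = "B2", limit = 2)
  expect_identical(unname(count_rdna(half, "5S")), c(2L, 2L))
  gained <- rdna_gain(b, "B5", "5S", "LONG", "TELOMERIC")
  expect_identical(unname(count_rdna(gained, "5S")), c(4L, 4L))
})

test_that("the dysploidy scenario replay reproduces the derived x = 6 karyotype", {
  proto <- proto_a_karyotype()
  res <- replay(proto, packaged_scenario("FIG4_DYSPLOIDY"))
  k <- res$karyotype
  expect_identical(somatic_number(k), 12L)
  expect_identical(k$basic_number, 6L)
  expect_false(k$unbalanced)
  cls <- vapply(chromosomes(k), classify_morphology, "")
  expect_identical(sum(cls %in% c("sm", "st")), 4L)
  expect_identical(unname(count_rdna(k, "5S")), c(4L, 2L))
  expect_identical(unname(count_rdna(k, "45S")), c(2L, 2L))
  # both 5S of the fused A2 pair end distal in the long arm
  a2 <- k$sites[k$chrom$label[k$sites$chrom] == "A2" & k$sites$family == "5S", ]
  expect_identical(a2$arm, rep("LONG", 4))
  expect_true(all(a2$position_class %in% c("SUBTELOMERIC", "TELOMERIC")))
  # chromatin conserved through the whole replay
  expect_equal(res$log$len_before, res$log$len_after, tolerance = 1e-9)
  expect_equal(total_len(k), total_len(proto), tolerance = 1e-9)
  # asymmetrization: the derived karyotype is strictly more asymmetric
  expect_gt(mca(k), mca(proto))
})

test_that("replay is deterministic, logs every event, and an empty scenario is identity", {
  proto <- proto_a_karyotype()
  sc <- packaged_scenario("FIG4_DYSPLOIDY")
  r1 <- replay(proto, sc); r2 <- replay(proto, sc)
  expect_identical(r1$karyotype, r2$karyotype)
  expect_identical(nrow(r1$log), length(sc$events))
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  write_karyotypes(r1$karyotype, t1); write_karyotypes(r2$karyotype, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)), readBin(t2, "raw", file.size(t2)))
  id <- replay(proto, scenario("EMPTY", list()))
  expect_identical(id$karyotype$chrom, proto$chrom)
  expect_identical(id$karyotype$sites, proto$sites)
})

test_that("segment re-use across fusions is rejected", {
  sc_bad <- scenario("BAD", list(
    rearrangement_event("fission_pericentromeric", label = "A7"),
    rearrangement_event("end_to_end_fusion", origin = "A7", part = "long",
                        recipient = "A2", recipient_arm = "LONG"),
    rearrangement_event("end_to_end_fusion", origin = "A7", part = "long",
                        recipient = "A6", recipient_arm = "LONG")
  ))
  expect_error(replay(proto_a_karyotype(), sc_bad), "re-use")
})

test_that("the nucleolar-dominance scenario leaves one 45S pair", {
  res <- replay(genome_template("B"), packaged_scenario("P_MINOR"))
  expect_identical(unname(count_rdna(res$karyotype, "45S")), c(2L, 2L))
  expect_identical(somatic_number(res$karyotype), 28L)
})

test_that("the species derivation scenarios reproduce the observed karyotypes", {
  fx <- phalaris_fixtures()
  # P. paradoxa from the ancestral B karyotype: one 5S pair lost, the other
  # relocated to the short arms by pericentric inversion
  pd <- replay(fx$ANCESTRAL_B, packaged_scenario("P_PARADOXA"))$karyotype
  expect_identical(somatic_number(pd), 14L)
  expect_identical(unname(count_rdna(pd, "5S")), c(2L, 2L))
  s5 <- pd$sites[pd$sites$family == "5S", ]
  expect_identical(s5$arm, rep("SHORT", 2))
  expect_identical(s5$position_class, rep("INTERCALARY", 2))
  # P. arundinacea by autopolyploidy of a genome-B diploid
  ar <- replay(genome_template("B"), packaged_scenario("P_ARUNDINACEA"))$karyotype
  expect_identical(somatic_number(ar), 28L)
  expect_identical(ar$ploidy, 4L)
  expect_identical(unname(count_rdna(ar, "45S")), c(4L, 4L))
  expect_identical(unname(count_rdna(ar, "5S")), c(2L, 2L))
  # P. aquatica as a B + C amphidiploid
  aq <- replay(genome_template("B"), packaged_scenario("P_AQUATICA"))$karyotype
  expect_identical(somatic_number(aq), 28L)
  expect_identical(unname(count_rdna(aq, "45S")), c(4L, 4L))
  expect_identical(unname(count_rdna(aq, "5S"))[1], 12L)
  expect_identical(assign_genomes(aq)$polyploidy_type, "ALLOPOLYPLOID")
})

test_that("scenario JSON round-trips through files", {
  sc <- packaged_scenario("FIG4_DYSPLOIDY")
  tf <- tempfile(fileext = ".json")
  write_scenario(sc, tf)
  sc2 <- read_scenario(tf)
  expect_identical(sc2$name, sc$name)
  expect_identical(length(sc2$events), length(sc$events))
  r1 <- replay(proto_a_karyotype(), sc)
  r2 <- replay(proto_a_karyotype(), sc2)
  expect_identical(r1$karyotype, r2$karyotype)
})
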