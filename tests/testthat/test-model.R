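test_that("arm ratio follows L/S with a telocentric sentinel", {
  expect_equal(arm_ratio(chromosome("a", 2, 2)), 1.0)
  expect_equal(arm_ratio(chromosome("a", 3, 1)), 3.0)
  expect_equal(arm_ratio(chromosome("a", 5.1, 1.5)), 3.4)
  expect_identical(arm_ratio(chromosome("a", 4, 0)), Inf)
  expect_identical(classify_morphology(chromosome("a", 4, 0)), "t")
})

test_that("Levan classification uses closed lower boundaries and is monotone", {
  expect_identical(classify_morphology(chromosome("a", 1, 1)), "m")
  expect_identical(classify_morphology(chromosome("a", 1.7, 1)), "m")
  expect_identical(classify_morphology(chromosome("a", 3, 1)), "sm")
  expect_identical(classify_morphology(chromosome("a", 4, 1)), "st")
  expect_identical(classify_morphology(chromosome("a", 7, 1)), "st")
  expect_identical(classify_morphology(chromosome("a", 7.01, 1)), "t")
  # monotone in the ratio
  set.seed(11)
  r <- sort(c(stats::runif(200, 1, 10), 1.7, 3, 7))
  cls <- factor(sapply(r, function(ri) classify_morphology(chromosome("a", ri, 1))),
                levels = c("m", "sm", "st", "t"), ordered = TRUE)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("chromosome construction normalizes arm order idempotently", {
  s <- rdna_site("5S", "SHORT", "SUBTELOMERIC", 0.9)
  a <- chromosome("c1", 5, 2, sites = s, satellite = list(arm = "SHORT", position_frac = 0.8))
  b <- chromosome("c1", 2, 5, sites = rdna_site("5S", "LONG", "SUBTELOMERIC", 0.9),
                  satellite = list(arm = "LONG", position_frac = 0.8))
  expect_equal(a, b)
  expect_equal(a$long_um, 5)
  expect_identical(b$sites$arm, "SHORT") # site followed its material
  expect_identical(b$satellite$arm, "SHORT")
})

test_that("rdna_site enforces the position bins and derives missing fractions", {
  expect_error(rdna_site("5S", "LONG", "SUBTELOMERIC", 0.1), "bin")
  s <- rdna_site("45S", "SHORT", "INTERCALARY")
  expect_equal(s$position_frac, 0.5)
  expect_identical(position_class_of(c(0, 0.24, 0.25, 0.74, 0.75, 0.94, 0.95, 1)),
                   c("CENTROMERIC_PROXIMAL", "CENTROMERIC_PROXIMAL",
                     "INTERCALARY", "INTERCALARY",
                     "SUBTELOMERIC", "SUBTELOMERIC",
                     "TELOMERIC", "TELOMERIC"))
})

test_that("validation reports balance and bin violations without throwing", {
  ok <- karyotype("sp", lapply(1:14, function(i) {
    chromosome(sprintf("B%d", ceiling(i / 2)), 3, 2)
  }), ploidy = 2, basic_number = 7)
  expect_identical(validate_karyotype(ok), character(0))

  unbal <- karyotype("sp", lapply(1:13, function(i) chromosome(sprintf("c%d", i), 3, 2)),
                     ploidy = 2, basic_number = 7)
  expect_match(validate_karyotype(unbal), "balance", all = FALSE)
  unbal$unbalanced <- TRUE
  expect_identical(validate_karyotype(unbal), character(0))

  bad <- ok
  bad$sites <- rbind(bad$sites, data.frame(
    chrom = 1L, family = "5S", arm = "LONG",
    position_class = "SUBTELOMERIC", position_frac = 0.1
  ))
  expect_match(validate_karyotype(bad), "bin", all = FALSE)
})

test_that("every packaged fixture validates cleanly", {
  for (k in phalaris_fixtures()) {
    expect_identical(validate_karyotype(k), character(0))
  }
  for (g in c("A", "B", "C")) {
    expect_identical(validate_karyotype(genome_template(g)), character(0))
  }
})

test_that("monoploid complement groups homologues by label", {
  fx <- phalaris_fixtures()
  reps <- monoploid_complement(fx[["P. paradoxa"]])
  expect_length(reps, 7)
  reps4 <- monoploid_complement(fx[["P. aquatica"]])
  expect_length(reps4, 14) # 7 per genome
  expect_setequal(unique(vapply(reps4, `[[`, "", "genome")), c("B", "C"))
  # representative arm lengths are group means
  k <- fx[["P. paradoxa"]]
  k$chrom$long_um[1] <- k$chrom$long_um[1] + 0.4 # desync one homologue
  r <- monoploid_complement(k)
  lab1 <- k$chrom$label[1]
  got <- Filter(function(cc) cc$label == lab1, r)[[1]]
  expect_equal(got$long_um, mean(k$chrom$long_um[k$chrom$label == lab1]))
  # unequal group sizes are an error
  bad <- karyotype("sp", c(
    lapply(1:2, function(i) chromosome("c1", 3, 2)),
    lapply(1:3, function(i) chromosome("c2", 3, 2))
  ), ploidy = 1, basic_number = 5)
  expect_error(monoploid_complement(bad), "equal-size")
})
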