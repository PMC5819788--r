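make_k <- function(arms, ploidy = 2, x = NULL, species = "t") {
  chroms <- lapply(seq_along(arms), function(i) {
    chromosome(sprintf("c%d", i), arms[[i]][1], arms[[i]][2])
  })
  if (is.null(x)) x <- length(arms) %/% ploidy
  karyotype(species, chroms, ploidy = ploidy, basic_number = max(1, x),
            unbalanced = length(arms) != ploidy * x)
}

test_that("TML divides total chromatin by ploidy", {
  # two homologue pairs of total lengths 4 and 6
  k <- make_k(list(c(2, 2), c(2, 2), c(4, 2), c(4, 2)), ploidy = 2)
  expect_equal(tml(k), 10)
  # tetraploid, 28 chromosomes of 5 um
  k4 <- make_k(rep(list(c(3, 2)), 28), ploidy = 4, x = 7)
  expect_equal(tml(k4), 35)
  # fixture whose somatic lengths sum to 100.4 at ploidy 2
  fx <- phalaris_fixtures()[["P. brachystachys"]]
  expect_equal(sum(fx$chrom$long_um + fx$chrom$short_um), 100.4)
  expect_equal(tml(fx), 50.2)
  # unbalanced complements are refused
  unb <- make_k(list(c(2, 2), c(2, 2), c(4, 2)), ploidy = 2, x = 2)
  expect_error(tml(unb), "balanced")
})

test_that("per-genome TML splits an allotetraploid into its sub-complements", {
  aq <- phalaris_fixtures()[["P. aquatica"]]
  by_gen <- tml_by_genome(aq)
  expect_equal(unname(by_gen[c("B", "C")]), c(49.3, 49.9))
  expect_equal(tml(aq), mean(by_gen))
})

test_that("M_CA matches hand arithmetic and its degenerate case", {
  expect_equal(mca(make_k(list(c(2, 2), c(3, 3), c(1, 1), c(5, 5)))), 0)
  expect_equal(mca(make_k(list(c(3, 1), c(1, 1)))), 25)
  expect_equal(mca(make_k(list(c(7, 1)), ploidy = 1, x = 1)), 75)
  # set-total variant pools arm sums
  k <- make_k(list(c(3, 1), c(1, 1)))
  expect_equal(mca(k, "set-total"), (4 - 2) / 6 * 100)
})

test_that("CV_CL matches the sample-sd oracle values", {
  expect_equal(cvcl(make_k(list(c(2, 2), c(2.5, 1.5), c(3, 1)))), 0)
  # lengths {4, 6}: sd = sqrt(2), mean = 5
  expect_equal(cvcl(make_k(list(c(2, 2), c(4, 2)), ploidy = 1, x = 2)),
               sqrt(2) / 5 * 100, tolerance = 1e-12)
  expect_equal(cvcl(make_k(list(c(2, 2), c(4, 2)), ploidy = 1, x = 2)),
               28.2842712, tolerance = 1e-6)
  # lengths {1, 2, 3}: sample sd = 1, mean = 2 -> 50%
  expect_equal(cvcl(make_k(list(c(0.5, 0.5), c(1, 1), c(2, 1)), ploidy = 1, x = 3)),
               50, tolerance = 1e-12)
  # population variant
  expect_equal(cvcl(make_k(list(c(2, 2), c(4, 2)), ploidy = 1, x = 2), "population"),
               1 / 5 * 100, tolerance = 1e-12)
  expect_error(cvcl(make_k(list(c(2, 2)), ploidy = 1, x = 1)), "two chromosomes")
})

test_that("vectorized statistics agree with the naive loop oracle", {
  set.seed(20240301)
  for (rep in 1:1000) {
    k <- random_karyotype()
    expect_equal(mca(k), naive_mca(k), tolerance = 1e-9)
    expect_equal(cvcl(k), naive_cvcl(k), tolerance = 1e-9)
  }
})

test_that("asymmetry statistics are scale- and permutation-invariant, TML scales", {
  set.seed(77)
  for (rep in 1:25) {
    k <- generate_karyotype(generator_params(seed = rep, cv_target = 10 + rep))
    c0 <- stats::runif(1, 0.2, 5)
    ks <- scale_karyotype(k, c0)
    expect_equal(mca(ks), mca(k), tolerance = 1e-12)
    expect_equal(cvcl(ks), cvcl(k), tolerance = 1e-12)
    expect_equal(tml(ks), c0 * tml(k), tolerance = 1e-12)
    perm <- sample(somatic_number(k))
    kp <- permute_karyotype(k, perm)
    expect_equal(mca(kp), mca(k), tolerance = 1e-12)
    expect_equal(cvcl(kp), cvcl(k), tolerance = 1e-12)
    expect_equal(tml(kp), tml(k), tolerance = 1e-12)
    expect_identical(count_rdna(kp, "5S"), count_rdna(k, "5S"))
  }
})

test_that("autopolyploidization leaves M_CA, CV_CL and TML unchanged", {
  for (sp in c("P. paradoxa", "P. coerulescens")) {
    k <- phalaris_fixtures()[[sp]]
    k2 <- autopolyploidize(k, 2)
    expect_equal(mca(k2), mca(k), tolerance = 1e-12)
    expect_equal(tml(k2), tml(k), tolerance = 1e-12)
    # population CV is exactly invariant; the sample CV shifts by the known
    # degrees-of-freedom factor when every length is duplicated
    expect_equal(cvcl(k2, "population"), cvcl(k, "population"), tolerance = 1e-12)
    n <- somatic_number(k)
    corr <- sqrt(2 * (n - 1) / (2 * n - 1))
    expect_equal(cvcl(k2), cvcl(k) * corr, tolerance = 1e-12)
  }
})

test_that("rDNA counting returns signals and bearing chromosomes", {
  fx <- phalaris_fixtures()
  expect_identical(unname(count_rdna(fx[["P. brachystachys"]], "5S")), c(4L, 2L))
  expect_identical(unname(count_rdna(fx[["P. minor"]], "5S")), c(16L, 14L))
  empty <- karyotype("none", list(), ploidy = 0, basic_number = 0, unbalanced = TRUE)
  expect_identical(unname(count_rdna(empty, "45S")), c(0L, 0L))
})

test_that("stats_table aggregates the published count columns over all fixtures", {
  expect_identical(nrow(stats_table(list())), 0L)
  fx <- phalaris_fixtures()[species_names()]
  one <- stats_table(fx[1])
  expect_identical(nrow(one), 1L)
  expect_false(anyNA(one))
  st <- stats_table(fx)
  expect_identical(nrow(st), 8L)
  # published karyotype table: 2n and signal/chromosome count columns
  expected <- data.frame(
    species = species_names(),
    n_2n = c(12L, 12L, 28L, 28L, 14L, 28L, 14L, 28L),
    `45S` = c("2/2", "2/2", "4/4", "2/2", "2/2", "4/4", "2/2", "4/4"),
    `5S` = c("4/2", "4/2", "12/7", "16/14", "2/2", "4/4", "3/3", "2/2"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  expect_identical(st[, c("species", "n_2n", "45S", "5S")], expected)
  # TML within 2% of the published values
  tml_published <- c(50.2, 35.0, 49.6, 38.9, 30.3, 47.6, 49.6, 46.0)
  expect_true(all(abs(st$TML - tml_published) / tml_published <= 0.02))
})
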