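# Synthetic karyotype generation and microscopy-style measurement noise.

#' Parameters for the synthetic karyotype generator
#'
#' @param basic_number basic chromosome number x of one monoploid set.
#' @param ploidy ploidy level (homologues are generated identically).
#' @param mean_chrom_len_um mean chromosome total length in micrometres.
#' @param cv_target target interchromosomal CV of chromosome length, in
#'   percent (the generated complement hits it exactly before noise).
#' @param arm_ratio_meanlog,arm_ratio_sdlog parameters of the shifted
#'   log-normal arm-ratio distribution `r = 1 + lognormal(meanlog, sdlog)`;
#'   the defaults give mostly metacentric/submetacentric chromosomes.
#' @param rdna_plan data.frame with columns `family`, `pairs`, `arm`,
#'   `position_class`: each row places `pairs` homologous site pairs of the
#'   family, one pair per chromosome type, position drawn uniformly within
#'   the class bin. Default: one intercalary 45S pair and one subtelomeric
#'   5S pair (a genome-B-like plan).
#' @param genome genome label written on the chromosomes.
#' @param species karyotype name.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(basic_number = 7L, ploidy = 2L,
                             mean_chrom_len_um = 7, cv_target = 13,
                             arm_ratio_meanlog = log(0.25),
                             arm_ratio_sdlog = 0.25,
                             rdna_plan = default_rdna_plan(),
                             genome = "B", species = "synthetic",
                             seed = 1L) {
  stopifnot(basic_number >= 1, ploidy >= 1, mean_chrom_len_um > 0,
            cv_target >= 0, is.data.frame(rdna_plan))
  stopifnot(all(c("family", "pairs", "arm", "position_class") %in% names(rdna_plan)))
  stopifnot(all(rdna_plan$pairs >= 0))
  structure(
    list(basic_number = as.integer(basic_number), ploidy = as.integer(ploidy),
         mean_chrom_len_um = mean_chrom_len_um, cv_target = cv_target,
         arm_ratio_meanlog = arm_ratio_meanlog,
         arm_ratio_sdlog = arm_ratio_sdlog, rdna_plan = rdna_plan,
         genome = genome, species = species, seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' @rdname generator_params
#' @export
default_rdna_plan <- function() {
  data.frame(
    family = c("45S", "5S"), pairs = c(1L, 1L), arm = c("SHORT", "LONG"),
    position_class = c("INTERCALARY", "SUBTELOMERIC"), stringsAsFactors = FALSE
  )
}

#' Measurement-noise parameters
#'
#' Emulates the variability of chromosome measurements and FISH signal
#' detection on squashed metaphase plates: multiplicative log-normal noise
#' on each arm length, independent per-signal dropout, and Gaussian jitter
#' of within-arm signal positions. Homologues are perturbed independently
#' (they are separate physical measurements).
#'
#' @param length_noise_cv CV of the per-arm multiplicative log-normal noise
#'   (default 0.05).
#' @param site_dropout_prob probability that an individual signal goes
#'   undetected (default 0.02).
#' @param position_jitter_sd standard deviation of the additive jitter on
#'   `position_frac` (default 0.03); jittered positions are clamped to
#'   `[0, 1]` and re-binned.
#' @return a list of class `noise_params`.
#' @export
noise_params <- function(length_noise_cv = 0.05, site_dropout_prob = 0.02,
                         position_jitter_sd = 0.03) {
  stopifnot(length_noise_cv >= 0, position_jitter_sd >= 0,
            site_dropout_prob >= 0, site_dropout_prob <= 1)
  structure(list(length_noise_cv = length_noise_cv,
                 site_dropout_prob = site_dropout_prob,
                 position_jitter_sd = position_jitter_sd),
            class = "noise_params")
}

#' Generate a synthetic karyotype
#'
#' Builds a balanced complement of `ploidy * basic_number` chromosomes:
#' chromosome total lengths follow a standardized normal spread rescaled so
#' the empirical CV equals `cv_target` exactly; arm ratios are drawn from
#' the shifted log-normal; rDNA pairs are placed per plan on successive
#' chromosome types (type 1 first), with the site position drawn uniformly
#' within the position-class bin. Homologues are identical before noise and
#' the output is deterministic given `params$seed`.
#'
#' @param params a [generator_params()] object.
#' @return a balanced [karyotype()].
#' @export
#' @examples
#' k <- generate_karyotype(generator_params(seed = 42))
#' somatic_number(k) # 14
generate_karyotype <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  x <- params$basic_number
  plan <- params$rdna_plan
  if (sum(plan$pairs) > 0 && max(cumsum(plan$pairs)) > x) {
    stop("rdna_plan places more site-bearing pairs than chromosome types")
  }
  with_seed(params$seed, {
    if (x > 1 && params$cv_target > 0) {
      z <- stats::rnorm(x)
      while (stats::sd(z) == 0) z <- stats::rnorm(x)
      zs <- (z - mean(z)) / stats::sd(z)
      len <- params$mean_chrom_len_um * (1 + (params$cv_target / 100) * zs)
      if (any(len <= 0)) {
        stop("cv_target too large for a positive length series at this x")
      }
    } else {
      len <- rep(params$mean_chrom_len_um, x)
    }
    len <- sort(len, decreasing = TRUE)
    ratios <- 1 + stats::rlnorm(x, params$arm_ratio_meanlog, params$arm_ratio_sdlog)
    # assign plan rows to successive chromosome types
    type_sites <- rep(list(NULL), x)
    next_type <- 1L
    for (pi in seq_len(nrow(plan))) {
      np <- plan$pairs[pi]
      if (np == 0) next
      for (tt in seq.int(next_type, next_type + np - 1L)) {
        frac <- stats::runif(1, POSITION_BINS$lo[match(plan$position_class[pi], POSITION_CLASSES)],
                             POSITION_BINS$hi[match(plan$position_class[pi], POSITION_CLASSES)])
        site <- rdna_site(plan$family[pi], plan$arm[pi], plan$position_class[pi], frac)
        type_sites[[tt]] <- rbind(type_sites[[tt]], site)
      }
      next_type <- next_type + np
    }
    chroms <- list()
    for (tt in seq_len(x)) {
      L <- len[tt] * ratios[tt] / (1 + ratios[tt])
      S <- len[tt] / (1 + ratios[tt])
      for (hom in seq_len(params$ploidy)) {
        chroms[[length(chroms) + 1]] <- chromosome(
          sprintf("%s%d", params$genome %||% "K", tt), L, S,
          sites = type_sites[[tt]], genome = params$genome
        )
      }
    }
    karyotype(params$species, chroms, ploidy = params$ploidy, basic_number = x)
  })
}

#' Perturb a karyotype with measurement noise
#'
#' Applies the [noise_params()] model: every arm length is multiplied by an
#' independent log-normal factor, each rDNA signal is dropped independently
#' with the stated probability, and surviving signal positions are jittered,
#' clamped to `[0, 1]` and re-binned. Arm naming is re-normalized per
#' chromosome afterwards (noise can flip which arm is longer).
#'
#' @param k a [karyotype()].
#' @param noise a [noise_params()] object.
#' @param seed integer seed; the perturbation is deterministic given it.
#' @return the perturbed karyotype.
#' @export
perturb_karyotype <- function(k, noise = noise_params(), seed = 1L) {
  stopifnot(inherits(k, "karyotype"), inherits(noise, "noise_params"))
  with_seed(seed, {
    n <- nrow(k$chrom)
    if (n > 0 && noise$length_noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise$length_noise_cv^2))
      fac <- matrix(stats::rlnorm(2 * n, -sdlog^2 / 2, sdlog), ncol = 2)
      k$chrom$long_um <- k$chrom$long_um * fac[, 1]
      k$chrom$short_um <- k$chrom$short_um * fac[, 2]
    }
    s <- k$sites
    if (nrow(s)) {
      if (noise$site_dropout_prob > 0) {
        keep <- stats::runif(nrow(s)) >= noise$site_dropout_prob
        s <- s[keep, , drop = FALSE]
      }
      if (nrow(s) && noise$position_jitter_sd > 0) {
        s$position_frac <- pmin(1, pmax(0, s$position_frac +
          stats::rnorm(nrow(s), 0, noise$position_jitter_sd)))
      }
      s <- reclass_sites(s)
      k$sites <- s
      rownames(k$sites) <- NULL
    }
    # re-normalize arm naming where noise flipped the longer arm
    flip <- which(k$chrom$short_um > k$chrom$long_um)
    if (length(flip)) {
      tmp <- k$chrom$long_um[flip]
      k$chrom$long_um[flip] <- k$chrom$short_um[flip]
      k$chrom$short_um[flip] <- tmp
      swap <- k$sites$chrom %in% flip
      k$sites$arm[swap] <- ifelse(k$sites$arm[swap] == "LONG", "SHORT", "LONG")
    }
    k
  })
}
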