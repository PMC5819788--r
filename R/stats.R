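# Karyological parameters: TML, M_CA, CV_CL, rDNA signal counts.

#' Total monoploid length (TML)
#'
#' Summed chromosome length of one monoploid set, computed as the total
#' somatic chromatin length divided by the ploidy level. For allopolyploids
#' this averages over the monoploid sub-complements; see [tml_by_genome()]
#' for per-genome totals.
#'
#' @param k a balanced [karyotype()].
#' @return TML in micrometres.
#' @export
tml <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  if (k$unbalanced) stop("tml() requires a balanced karyotype")
  if (somatic_number(k) == 0) return(0)
  sum(k$chrom$long_um + k$chrom$short_um) / k$ploidy
}

#' Per-genome total monoploid length
#'
#' @param k a balanced [karyotype()] whose chromosomes carry genome labels.
#' @return named numeric vector: for each genome label, the summed length of
#'   one monoploid set of that genome.
#' @export
tml_by_genome <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  if (k$unbalanced) stop("tml_by_genome() requires a balanced karyotype")
  len <- k$chrom$long_um + k$chrom$short_um
  tot <- tapply(len, k$chrom$genome, sum)
  cnt <- tapply(len, k$chrom$genome, length)
  # copies of genome g present = chromosomes of g / basic number
  copies <- cnt / k$basic_number
  res <- as.numeric(tot / copies)
  names(res) <- names(tot)
  res
}

#' Mean centromeric asymmetry (M_CA)
#'
#' Mean over the somatic chromosomes of `(L - S) / (L + S) * 100`, where L
#' and S are the long- and short-arm lengths of each chromosome. 0 for a
#' fully metacentric complement; approaches 100 for telocentrics. The
#' set-total variant (arm-length sums pooled over the complement before the
#' ratio) is available via `variant = "set-total"`.
#'
#' @param k a [karyotype()] with at least one chromosome.
#' @param variant `"per-chromosome"` (the mean centromeric asymmetry proper,
#'   default) or `"set-total"`.
#' @return asymmetry in percent, in `[0, 100)`.
#' @export
mca <- function(k, variant = c("per-chromosome", "set-total")) {
  stopifnot(inherits(k, "karyotype"), somatic_number(k) > 0)
  variant <- match.arg(variant)
  L <- k$chrom$long_um
  S <- k$chrom$short_um
  stopifnot(all(L + S > 0))
  if (variant == "per-chromosome") {
    mean((L - S) / (L + S)) * 100
  } else {
    (sum(L) - sum(S)) / (sum(L) + sum(S)) * 100
  }
}

#' Interchromosomal asymmetry (CV_CL)
#'
#' Coefficient of variation of somatic chromosome total lengths, in percent:
#' `sd(length) / mean(length) * 100`. The sample standard deviation (n - 1
#' denominator) is used by default.
#'
#' @param k a [karyotype()] with at least two chromosomes.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return CV of chromosome length in percent.
#' @export
cvcl <- function(k, sd_type = c("sample", "population")) {
  stopifnot(inherits(k, "karyotype"))
  sd_type <- match.arg(sd_type)
  len <- k$chrom$long_um + k$chrom$short_um
  if (length(len) < 2) stop("cvcl() requires at least two chromosomes")
  s <- stats::sd(len)
  if (sd_type == "population") s <- s * sqrt((length(len) - 1) / length(len))
  s / mean(len) * 100
}

#' Count rDNA signals of one family
#'
#' @param k a [karyotype()].
#' @param family `"5S"` or `"45S"`.
#' @return named integer vector `c(signals, bearing_chromosomes)`: the total
#'   signal count of the family over the somatic complement and the number
#'   of chromosomes carrying at least one such signal.
#' @export
#' @examples
#' k <- phalaris_fixtures()[["P. brachystachys"]]
#' count_rdna(k, "5S") # 4 signals on 2 chromosomes
count_rdna <- function(k, family) {
  stopifnot(inherits(k, "karyotype"))
  family <- match.arg(family, RDNA_FAMILIES)
  s <- k$sites[k$sites$family == family, , drop = FALSE]
  c(signals = nrow(s), bearing_chromosomes = length(unique(s$chrom)))
}

#' Karyological parameter table
#'
#' Computes, for each karyotype, the parameters of a standard karyotype
#' table: 2n, ploidy, basic number, TML, M_CA, CV_CL and the 45S/5S signal
#' counts formatted as `signals/chromosomes`.
#'
#' @param karyotypes a list of [karyotype()] objects (possibly named).
#' @param sd_type passed to [cvcl()].
#' @param mca_variant passed to [mca()].
#' @return a data.frame with one row per karyotype.
#' @export
stats_table <- function(karyotypes, sd_type = "sample",
                        mca_variant = "per-chromosome") {
  stopifnot(is.list(karyotypes))
  rows <- lapply(karyotypes, function(k) {
    c45 <- count_rdna(k, "45S")
    c5 <- count_rdna(k, "5S")
    data.frame(
      species = k$species,
      genome = paste(sort(unique(k$chrom$genome[!is.na(k$chrom$genome)])), collapse = "/"),
      n_2n = somatic_number(k),
      ploidy = k$ploidy,
      x = k$basic_number,
      TML = tml(k),
      M_CA = mca(k, mca_variant),
      CV_CL = cvcl(k, sd_type),
      s45_signals = unname(c45[1]),
      s45_chromosomes = unname(c45[2]),
      s5_signals = unname(c5[1]),
      s5_chromosomes = unname(c5[2]),
      `45S` = sprintf("%d/%d", c45[1], c45[2]),
      `5S` = sprintf("%d/%d", c5[1], c5[2]),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      species = character(), genome = character(), n_2n = integer(),
      ploidy = integer(), x = integer(), TML = numeric(), M_CA = numeric(),
      CV_CL = numeric(), s45_signals = integer(), s45_chromosomes = integer(),
      s5_signals = integer(), s5_chromosomes = integer(),
      `45S` = character(), `5S` = character(),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
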