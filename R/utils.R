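# Internal helpers shared across modules.

# Controlled vocabularies for rDNA site annotation. Tokens are the same ones
# used in the karyotype TSV format, so no mapping layer is needed at I/O time.
RDNA_FAMILIES <- c("5S", "45S")
ARM_NAMES <- c("SHORT", "LONG")
POSITION_CLASSES <- c("CENTROMERIC_PROXIMAL", "INTERCALARY", "SUBTELOMERIC", "TELOMERIC")

# Within-arm position bins, as fractions of arm length from centromere (0) to
# telomere (1). Lower bound inclusive, upper bound exclusive except the last.
POSITION_BINS <- data.frame(
  position_class = POSITION_CLASSES,
  lo = c(0.00, 0.25, 0.75, 0.95),
  hi = c(0.25, 0.75, 0.95, 1.00),
  stringsAsFactors = FALSE
)

#' Bin a within-arm fraction into a position class
#'
#' @param frac numeric vector of fractions in `[0, 1]`, measured from the
#'   centromere towards the telomere.
#' @return character vector of position class tokens.
#' @export
#' @examples
#' position_class_of(c(0.1, 0.5, 0.85, 0.99))
position_class_of <- function(frac) {
  stopifnot(all(is.finite(frac)), all(frac >= 0), all(frac <= 1))
  idx <- findInterval(frac, POSITION_BINS$lo)
  POSITION_CLASSES[idx]
}

# Midpoint of a position-class bin, used when a site has a class but no
# measured fraction.
position_class_midpoint <- function(position_class) {
  i <- match(position_class, POSITION_CLASSES)
  (POSITION_BINS$lo[i] + POSITION_BINS$hi[i]) / 2
}

# Does frac fall inside the bin of the given class?
frac_in_class <- function(frac, position_class) {
  i <- match(position_class, POSITION_CLASSES)
  ok <- frac >= POSITION_BINS$lo[i] &
    (frac < POSITION_BINS$hi[i] | (position_class == "TELOMERIC" & frac <= 1))
  ok
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

empty_sites_df <- function(n_rows = 0L) {
  data.frame(
    chrom = integer(n_rows),
    family = character(n_rows),
    arm = character(n_rows),
    position_class = character(n_rows),
    position_frac = numeric(n_rows),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
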