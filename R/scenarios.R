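# Rearrangement scenarios: typed event lists, JSON (de)serialization, replay.

#' Create a rearrangement event
#'
#' A typed chromosome-level mutation. Recognized kinds and their parameters:
#' \describe{
#'   \item{fission_pericentromeric}{`label`, optional `break_frac`}
#'   \item{end_to_end_fusion}{`origin`, `part` (`"long"`/`"short"`, which
#'     half of the fissioned chromosome), `recipient`, `recipient_arm`}
#'   \item{pericentric_inversion}{`label`, `frac_short`, `frac_long`}
#'   \item{paracentric_inversion}{`label`, `arm`, `frac_a`, `frac_b`}
#'   \item{reciprocal_translocation}{`label1`, `arm1`, `frac1`, `label2`,
#'     `arm2`, `frac2`}
#'   \item{autopolyploidy}{`factor`}
#'   \item{allopolyploid_merge}{`partner` (name of a packaged karyotype, see
#'     [phalaris_fixtures()] and [genome_template()]), optional `species`}
#'   \item{rdna_loss}{`family` plus optional `label`, `genome`, `arm`,
#'     `position_class`, `limit`, `strict`}
#'   \item{rdna_gain}{`label`, `family`, `arm`, `position_class`, optional
#'     `position_frac`}
#' }
#'
#' @param kind one of the event kinds above.
#' @param ... event parameters.
#' @return an object of class `"rearrangement_event"`.
#' @export
rearrangement_event <- function(kind, ...) {
  kinds <- c("fission_pericentromeric", "end_to_end_fusion",
             "pericentric_inversion", "paracentric_inversion",
             "reciprocal_translocation", "autopolyploidy",
             "allopolyploid_merge", "rdna_loss", "rdna_gain")
  kind <- match.arg(kind, kinds)
  params <- list(...)
  required <- switch(kind,
    fission_pericentromeric = "label",
    end_to_end_fusion = c("origin", "part", "recipient", "recipient_arm"),
    pericentric_inversion = c("label", "frac_short", "frac_long"),
    paracentric_inversion = c("label", "arm", "frac_a", "frac_b"),
    reciprocal_translocation = c("label1", "arm1", "frac1", "label2", "arm2", "frac2"),
    autopolyploidy = "factor",
    allopolyploid_merge = "partner",
    rdna_loss = "family",
    rdna_gain = c("label", "family", "arm", "position_class")
  )
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop(sprintf("event '%s' missing parameter(s): %s", kind,
                 paste(missing, collapse = ", ")))
  }
  structure(list(kind = kind, params = params), class = "rearrangement_event")
}

#' Create a rearrangement scenario
#'
#' An ordered list of events replayed on a karyotype. With
#' `apply_to_homologues = TRUE` (the default, matching somatic FISH
#' observations) every event acts symmetrically on all chromosomes sharing
#' the target label.
#'
#' @param name scenario name.
#' @param events list of [rearrangement_event()] objects.
#' @param apply_to_homologues logical, default `TRUE`.
#' @param note optional free-text annotation.
#' @return an object of class `"scenario"`.
#' @export
scenario <- function(name, events, apply_to_homologues = TRUE, note = NULL) {
  stopifnot(is.character(name), is.list(events))
  stopifnot(all(vapply(events, inherits, TRUE, "rearrangement_event")))
  structure(
    list(name = name, events = events,
         apply_to_homologues = isTRUE(apply_to_homologues), note = note),
    class = "scenario"
  )
}

#' Read / write a scenario as JSON
#'
#' The on-disk form is a JSON object `{name, apply_to_homologues, note,
#' events: [{kind, ...params}]}`. Scenario files shipped with the package
#' live under `system.file("extdata", "scenarios", package = "karyokit")`.
#'
#' @param path file path.
#' @return `read_scenario()` returns a [scenario()]; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  events <- lapply(obj$events, function(e) {
    do.call(rearrangement_event, c(list(kind = e$kind), e[names(e) != "kind"]))
  })
  scenario(obj$name, events,
           apply_to_homologues = isTRUE(obj$apply_to_homologues),
           note = obj$note %||% NULL)
}

#' @rdname read_scenario
#' @param sc a [scenario()].
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  obj <- list(
    name = sc$name, apply_to_homologues = sc$apply_to_homologues,
    note = sc$note,
    events = lapply(sc$events, function(e) c(list(kind = e$kind), e$params))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a scenario shipped with the package
#'
#' @param name one of `"FIG4_DYSPLOIDY"`, `"P_PARADOXA"`, `"P_ARUNDINACEA"`,
#'   `"P_AQUATICA"`, `"P_MINOR"`, `"HYBRID_ARUN_X_AQUA"`.
#' @return a [scenario()].
#' @export
packaged_scenario <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(tolower(name), ".json"),
                      package = "karyokit")
  if (!nzchar(path)) stop(sprintf("no packaged scenario '%s'", name))
  read_scenario(path)
}

#' Replay a scenario on a karyotype
#'
#' Applies the events in order, tracking acentric segments produced by
#' fissions in a pool that fusion events consume (re-using a consumed
#' segment is an error). Intermediate karyotypes may be unbalanced; after
#' the last event the basic number is re-derived from the chromosome count
#' when the complement is balanced again. The replay is deterministic and
#' returns an event log recording, for every event, the chromosome, length
#' and site inventories before and after.
#'
#' @param k a [karyotype()].
#' @param sc a [scenario()].
#' @param partners named list of karyotypes resolvable by
#'   `allopolyploid_merge` events; defaults to the packaged fixtures and
#'   genome templates.
#' @return list with elements `karyotype` and `log` (a data.frame).
#' @export
#' @examples
#' res <- replay(proto_a_karyotype(), packaged_scenario("FIG4_DYSPLOIDY"))
#' somatic_number(res$karyotype) # 12
replay <- function(k, sc, partners = NULL) {
  stopifnot(inherits(k, "karyotype"), inherits(sc, "scenario"))
  hom <- sc$apply_to_homologues
  pool <- list()
  log <- list()
  for (ei in seq_along(sc$events)) {
    ev <- sc$events[[ei]]
    p <- ev$params
    before <- c(n = somatic_number(k), len = total_chromatin(k, pool),
                sites = nrow(k$sites))
    detail <- ""
    k <- switch(ev$kind,
      fission_pericentromeric = {
        res <- fission_pericentromeric(k, p$label, p$break_frac %||% 0, hom)
        pool <- c(pool, res$segments)
        detail <- sprintf("%s -> %d acentric segment(s)", p$label,
                          length(res$segments))
        res$karyotype
      },
      end_to_end_fusion = {
        avail <- which(vapply(pool, function(s) {
          s$origin_label == p$origin && s$part == p$part
        }, TRUE))
        n_rec <- length(which(k$chrom$label == p$recipient))
        if (n_rec == 0) stop(sprintf("no chromosome labelled '%s'", p$recipient))
        if (length(avail) < n_rec) {
          stop(sprintf(
            "event %d: %d '%s/%s' segment(s) available for %d recipient(s) (segment re-use?)",
            ei, length(avail), p$origin, p$part, n_rec))
        }
        use <- avail[seq_len(n_rec)]
        segs <- pool[use]
        pool <- pool[-use]
        detail <- sprintf("%s/%s arm onto %s (%s arm)", p$origin, p$part,
                          p$recipient, p$recipient_arm)
        end_to_end_fusion(k, p$recipient, segs, p$recipient_arm, hom)
      },
      pericentric_inversion =
        pericentric_inversion(k, p$label, p$frac_short, p$frac_long, hom),
      paracentric_inversion =
        paracentric_inversion(k, p$label, p$arm, p$frac_a, p$frac_b, hom),
      reciprocal_translocation =
        reciprocal_translocation(k, p$label1, p$arm1, p$frac1,
                                 p$label2, p$arm2, p$frac2, hom),
      autopolyploidy = autopolyploidize(k, p$factor),
      allopolyploid_merge = {
        if (is.null(partners)) {
          partners <- c(phalaris_fixtures(),
                        list(GENOME_A_TEMPLATE = genome_template("A"),
                             GENOME_B_TEMPLATE = genome_template("B"),
                             GENOME_C_TEMPLATE = genome_template("C")))
        }
        partner <- partners[[p$partner]]
        if (is.null(partner)) stop(sprintf("unknown merge partner '%s'", p$partner))
        detail <- sprintf("merge with %s", p$partner)
        allopolyploid_merge(k, partner, species = p$species %||% NULL)
      },
      rdna_loss = rdna_loss(k, p$family, label = p$label %||% NULL,
                            genome = p$genome %||% NULL, arm = p$arm %||% NULL,
                            position_class = p$position_class %||% NULL,
                            limit = p$limit %||% NULL,
                            strict = p$strict %||% TRUE),
      rdna_gain = rdna_gain(k, p$label, p$family, p$arm, p$position_class,
                            p$position_frac %||% NULL, hom),
      stop(sprintf("unknown event kind '%s'", ev$kind))
    )
    log[[ei]] <- data.frame(
      event = ei, kind = ev$kind, detail = detail,
      n_before = before[["n"]], n_after = somatic_number(k),
      len_before = before[["len"]], len_after = total_chromatin(k, pool),
      sites_before = before[["sites"]], sites_after = nrow(k$sites),
      segments_pooled = length(pool), stringsAsFactors = FALSE
    )
  }
  if (length(pool) == 0 && k$ploidy > 0 &&
      somatic_number(k) %% k$ploidy == 0) {
    k$basic_number <- as.integer(somatic_number(k) / k$ploidy)
    k$unbalanced <- FALSE
  } else {
    k$unbalanced <- TRUE
  }
  v <- validate_karyotype(k)
  if (length(v)) {
    stop(sprintf("replay of '%s' produced an invalid karyotype: %s",
                 sc$name, paste(v, collapse = "; ")))
  }
  list(karyotype = k,
       log = if (length(log)) do.call(rbind, log) else data.frame())
}
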