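# Karyotype TSV format and SVG idiogram rendering.
#
# TSV dialect: UTF-8, tab-separated, header required, '.' decimal separator.
# Columns: species, chrom_label, genome, long_um, short_um, satellite, sites.
# `satellite` is 0, 1, or 1:ARM:frac; `sites` is a semicolon-separated list
# of family:ARM:POSITION_CLASS:frac entries (fraction printed at 6
# decimals), empty for a chromosome without signals.

KARYOTYPE_TSV_COLUMNS <- c("species", "chrom_label", "genome", "long_um",
                           "short_um", "satellite", "sites")

encode_sites <- function(k, i) {
  s <- k$sites[k$sites$chrom == i, , drop = FALSE]
  if (!nrow(s)) return("")
  paste(sprintf("%s:%s:%s:%.6f", s$family, s$arm, s$position_class,
                s$position_frac), collapse = ";")
}

decode_sites <- function(txt, line) {
  if (is.na(txt) || txt == "") {
    return(empty_sites_df()[, c("family", "arm", "position_class", "position_frac")])
  }
  entries <- strsplit(txt, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(entries, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3 || length(parts) > 4) {
      stop(sprintf("line %d: malformed site entry '%s'", line, e))
    }
    frac <- if (length(parts) == 4) parse_decimal(parts[4], line, "site position") else NULL
    tryCatch(rdna_site(parts[1], parts[2], parts[3], frac),
             error = function(err) {
               stop(sprintf("line %d: %s", line, conditionMessage(err)))
             })
  }))
}

parse_decimal <- function(txt, line, what) {
  if (grepl(",", txt, fixed = TRUE)) {
    stop(sprintf("line %d: %s '%s' uses a comma decimal separator; use '.'",
                 line, what, txt))
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) stop(sprintf("line %d: non-numeric %s '%s'", line, what, txt))
  val
}

#' Write karyotypes to a TSV file
#'
#' @param karyotypes a [karyotype()] or list thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_karyotypes <- function(karyotypes, path) {
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  rows <- list()
  for (k in karyotypes) {
    for (i in seq_len(somatic_number(k))) {
      rows[[length(rows) + 1]] <- data.frame(
        species = k$species,
        chrom_label = k$chrom$label[i],
        genome = ifelse(is.na(k$chrom$genome[i]), "", k$chrom$genome[i]),
        long_um = format(k$chrom$long_um[i], digits = 15, scientific = FALSE),
        short_um = format(k$chrom$short_um[i], digits = 15, scientific = FALSE),
        satellite = k$chrom$satellite[i],
        sites = encode_sites(k, i),
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    stats::setNames(as.data.frame(matrix(character(), ncol = 7)),
                    KARYOTYPE_TSV_COLUMNS)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read karyotypes from a TSV file
#'
#' Rows are grouped by species; ploidy and basic number are re-derived from
#' the complement: x is the number of distinct chromosome designations
#' within one genome and ploidy is 2n / x. Malformed rows are reported with
#' their line number; every loaded karyotype is validated.
#'
#' @param path TSV file path.
#' @return named list of [karyotype()] objects, in file order.
#' @export
read_karyotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(KARYOTYPE_TSV_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!nrow(df)) return(list())
  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    lines <- as.integer(rownames(sub)) + 1L # header is line 1
    chroms <- lapply(seq_len(nrow(sub)), function(j) {
      ln <- lines[j]
      chromosome(
        label = sub$chrom_label[j],
        long_um = parse_decimal(sub$long_um[j], ln, "long arm length"),
        short_um = parse_decimal(sub$short_um[j], ln, "short arm length"),
        sites = decode_sites(sub$sites[j], ln),
        satellite = decode_satellite(sub$satellite[j]),
        genome = if (sub$genome[j] == "") NA_character_ else sub$genome[j]
      )
    })
    labels <- vapply(chroms, `[[`, "", "label")
    genomes <- vapply(chroms, function(cc) ifelse(is.na(cc$genome), "?", cc$genome), "")
    x_per_genome <- tapply(labels, genomes, function(l) length(unique(l)))
    x <- as.integer(max(x_per_genome))
    n <- length(chroms)
    ploidy <- if (n %% x == 0) n %/% x else 2L
    k <- karyotype(sp, chroms, ploidy = ploidy, basic_number = x,
                   unbalanced = n %% x != 0)
    v <- validate_karyotype(k)
    if (length(v)) {
      stop(sprintf("karyotype '%s' failed validation: %s", sp,
                   paste(v, collapse = "; ")))
    }
    out[[sp]] <- k
  }
  out
}

#' Idiogram rendering specification
#'
#' @param um_per_px vertical scale (micrometres per pixel).
#' @param colours named list of band/fill colours.
#' @return list of class `idiogram_spec`.
#' @export
idiogram_spec <- function(um_per_px = 0.05,
                          colours = list(`45S` = "#2ca02c", `5S` = "#d62728",
                                         satellite = "#9467bd",
                                         A = "#1f77b4", B = "#e377c2",
                                         C = "#17becf", default = "#7f7f7f")) {
  structure(list(um_per_px = um_per_px, colours = colours),
            class = "idiogram_spec")
}

#' Render a karyotype as an SVG idiogram
#'
#' Draws one column per homologue group (chromosomes sharing genome and
#' label), centromere-aligned, with chromosome height proportional to total
#' length, arm boxes filled in the genome colour, and one band per rDNA
#' signal at its within-arm position (45S green, 5S red by default). Output
#' bytes are deterministic for fixed input and spec.
#'
#' @param k a [karyotype()].
#' @param spec an [idiogram_spec()].
#' @param file optional path; when given the SVG is written there.
#' @return the SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
render_idiogram <- function(k, spec = idiogram_spec(), file = NULL) {
  stopifnot(inherits(k, "karyotype"), inherits(spec, "idiogram_spec"))
  px <- function(um) um / spec$um_per_px
  ch <- k$chrom
  key <- paste(ifelse(is.na(ch$genome), "?", ch$genome), ch$label)
  groups <- split(seq_len(nrow(ch)), key)
  groups <- groups[order(names(groups))]
  col_w <- 26; chrom_w <- 14; gap <- 6
  max_long <- if (nrow(ch)) max(ch$long_um) else 1
  max_short <- if (nrow(ch)) max(ch$short_um) else 1
  cen_y <- 30 + px(max_long)
  height <- ceiling(cen_y + px(max_short) + 40)
  elems <- character()
  xpos <- 10
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    for (m in seq_along(idx)) {
      i <- idx[m]
      x <- xpos + (m - 1) * (chrom_w + gap)
      colr <- spec$colours[[ch$genome[i]]] %||% spec$colours$default
      L <- px(ch$long_um[i]); S <- px(ch$short_um[i])
      elems <- c(elems,
        sprintf('<rect class="arm" x="%.1f" y="%.1f" width="%d" height="%.1f" fill="%s" stroke="black" stroke-width="0.5"/>',
                x, cen_y - L, chrom_w, max(L, 0.5), colr),
        sprintf('<rect class="arm" x="%.1f" y="%.1f" width="%d" height="%.1f" fill="%s" stroke="black" stroke-width="0.5"/>',
                x, cen_y, chrom_w, max(S, 0.5), colr))
      sat <- decode_satellite(ch$satellite[i])
      if (!isFALSE(sat)) {
        elems <- c(elems,
          sprintf('<circle class="satellite" cx="%.1f" cy="%.1f" r="2.5" fill="%s"/>',
                  x + chrom_w / 2, cen_y - L - 4, spec$colours$satellite))
      }
      s <- k$sites[k$sites$chrom == i, , drop = FALSE]
      if (nrow(s)) {
        for (r in seq_len(nrow(s))) {
          arm_px <- if (s$arm[r] == "LONG") L else S
          y <- if (s$arm[r] == "LONG") cen_y - s$position_frac[r] * arm_px
               else cen_y + s$position_frac[r] * arm_px
          elems <- c(elems,
            sprintf('<rect class="band band-%s" x="%.1f" y="%.1f" width="%d" height="2" fill="%s"/>',
                    s$family[r], x, y - 1, chrom_w, spec$colours[[s$family[r]]]))
        }
      }
    }
    lab <- names(groups)[g]
    elems <- c(elems,
      sprintf('<text x="%.1f" y="%.1f" font-size="8" text-anchor="middle">%s</text>',
              xpos + chrom_w, height - 20, sub("^[^ ]* ", "", lab)))
    xpos <- xpos + length(idx) * (chrom_w + gap) + col_w
  }
  width <- ceiling(xpos + 10)
  svg <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">\n',
            width, height),
    sprintf('<title>Idiogram of %s</title>\n', k$species),
    paste(elems, collapse = "\n"), "\n</svg>\n"
  )
  if (!is.null(file)) {
    writeLines(svg, file, sep = "")
    return(invisible(svg))
  }
  svg
}
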