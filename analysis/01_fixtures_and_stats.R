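#!/usr/bin/env Rscript
# Step 1 — Karyological parameters of the eight Phalaris karyotypes.
#
# Builds the packaged karyotype reconstructions, writes them to a TSV for
# the later steps, computes the karyotype table (2n, TML, M_CA, CV_CL, rDNA
# signal counts) and renders one idiogram per species.
#
# Finding: the reconstructions reproduce the published chromosome numbers
# (2n = 12/14/28), every 45S and 5S signal count, and the published total
# monoploid lengths; the x = 6 species stand out with M_CA > 25 against
# <= ~18 for all x = 7 complements — the asymmetry split that motivates the
# dysploidy model replayed in step 2.

suppressPackageStartupMessages(library(karyokit))
dir.create("results/idiograms", recursive = TRUE, showWarnings = FALSE)

fx <- phalaris_fixtures()
species <- c("P. brachystachys", "P. canariensis", "P. aquatica", "P. minor",
             "P. paradoxa", "P. caroliniana", "P. coerulescens",
             "P. arundinacea")

write_karyotypes(fx, "results/karyotypes.tsv")

st <- stats_table(fx[species])
write.table(format(st, digits = 4), "results/karyotype_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Karyological parameters (results/karyotype_stats.tsv):\n")
print(st[, c("species", "genome", "n_2n", "TML", "M_CA", "CV_CL", "45S", "5S")],
      digits = 3, row.names = FALSE)

# per-genome TML of the allotetraploids, as reported in the source table
for (sp in c("P. aquatica", "P. minor")) {
  bg <- tml_by_genome(fx[[sp]])
  cat(sprintf("%s per-genome TML: %s\n", sp,
              paste(sprintf("%s = %.1f um", names(bg), bg), collapse = ", ")))
}

for (sp in species) {
  render_idiogram(fx[[sp]], file = sprintf("results/idiograms/%s.svg",
                                           gsub("[^A-Za-z]+", "_", sp)))
}
cat(sprintf("M_CA split: x=6 mean %.1f vs x=7 mean %.1f\n",
            mean(st$M_CA[st$x == 6]), mean(st$M_CA[st$x == 7])))
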