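#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Design mirrored from the experiment the pipeline is built for: 4 paired
# human-fibroblast-like cell lines, control vs treated, measured in five
# layers (proteomics intensities; total, free, monosome and polysome RNA).
# Four regulation groups are planted, 200 features each:
#   group 1  protein up   | mRNA up     | M-to-P shift
#   group 4  protein up   | mRNA stable | M-to-P shift
#   group 13 protein stable | mRNA stable | M-to-P shift
#   group 14 stable on all three axes
# Group-4 transcripts additionally carry the 20-nt GA-rich consensus motif
# in their CDS (rate 0.9) and uORFs are planted uniformly at rate 0.3
# across all groups, so downstream motif/uORF stages have known truth.

suppressMessages(library(riboshift))

seed <- 20260924L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_units = 4L,
                  features_per_group = c("1" = 200, "4" = 200,
                                         "13" = 200, "14" = 200),
                  effect_up = 2.0, replicate_cv = 0.1,
                  polysome_fraction_base = 0.5,
                  polysome_fraction_m_to_p = 0.8,
                  utr5_start_free = TRUE,
                  seed = seed)
d <- generate_dataset(cfg)

set.seed(seed + 1L)
g4 <- d$truth$feature[d$truth$group == 4]
tx <- plant_motif(d$transcripts, group4_motif(), g4, region = "cds",
                  rate = 0.9)
pm <- attr(tx, "placements")
d$truth$motif_planted <- d$truth$feature %in% pm$feature
d$truth$motif_start[match(pm$feature, d$truth$feature)] <- pm$start
d$truth$motif_region[match(pm$feature, d$truth$feature)] <- pm$region

tx <- plant_uorf(tx, d$truth$feature, rate = 0.3)
pu <- attr(tx, "placements")
d$truth$uorf_planted <- d$truth$feature %in% pu$feature
d$truth$uorf_start[match(pu$feature, d$truth$feature)] <- pu$start

for (layer in names(d$tables))
  write_abundance(d$tables[[layer]],
                  file.path(out, paste0(layer, ".tsv")),
                  file.path(out, paste0(layer, "_meta.tsv")),
                  seed = seed, config = cfg)
write_transcripts(tx, file.path(out, "transcripts.fa"),
                  file.path(out, "regions.tsv"), seed = seed, config = cfg)
write_tsv <- riboshift:::write_tsv
write_tsv(d$truth, file.path(out, "truth.tsv"),
          header = riboshift:::rs_header(seed = seed, config = cfg))

cat(sprintf("simulated %d features x %d samples/layer across %d layers\n",
            nrow(d$truth), 2L * cfg$n_units, length(d$tables)))
cat(sprintf("planted motif in %d group-4 transcripts, uORFs in %d transcripts\n",
            nrow(pm), nrow(pu)))
cat("tables under", out, "\n")
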