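#!/usr/bin/env Rscript
# Stage 5: common-motif discovery and localization.
#
# ZOOPS EM over widths 10-25 on the CDS sequences of called group-4
# transcripts (subsampled for speed), then a PWM scan of all transcripts
# and a per-group occurrence/region table. With the motif planted in the
# CDS of group-4 transcripts, discovery should return the planted 20-mer
# and the occurrence table should concentrate on group 4 / CDS.

suppressMessages(library(riboshift))

seed <- 20260924L
read_tsv <- riboshift:::read_tsv
tx <- read_transcripts("results/data/transcripts.fa",
                       "results/data/regions.tsv")
groups <- read_tsv("results/groups.tsv")
called4 <- groups$feature[!is.na(groups$group) & groups$group == 4]

set.seed(seed)
train <- sample(called4, min(25L, length(called4)))
cds_of <- function(id) {
  r <- tx[tx$id == id, ]
  substr(r$seq, r$utr5_length + 1L, r$utr5_length + r$cds_length)
}
seqs <- vapply(train, cds_of, character(1))

disc <- discover(seqs, W_min = 10, W_max = 25, seed = seed)
cat(sprintf("best width %d, consensus %s (planted %s)\n",
            disc$best$width, disc$best$consensus, group4_motif()))
write_meme_motif(disc$best, "results/group4_motif.meme", name = "group4")

hits <- log_odds_scan(disc$best, tx, p_threshold = 1e-4)
riboshift:::write_tsv(hits, "results/motif_hits.tsv")
gg <- data.frame(feature = groups$feature,
                 group = ifelse(is.na(groups$group), 0L, groups$group))
occ <- region_occurrence_table(disc$best, tx, gg, p_threshold = 1e-4)
riboshift:::write_tsv(occ, "results/motif_occurrence.tsv")
print(occ[, c("group", "n", "frac_with_hit", "frac_cds")])
cat("motif model, hits and occurrence table under results/\n")
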