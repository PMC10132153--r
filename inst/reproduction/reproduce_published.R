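#!/usr/bin/env Rscript
# Optional reproduction against the deposited study data. This script
# needs network access and several hundred MB of downloads; it is a
# convenience driver, not part of the test suite.
#
# Inputs it fetches:
#   - GEO series GSE201506: total / monosome / polysome RNA-Seq count
#     tables for 4 human lung fibroblast lines, control vs TGF-beta1
#   - MassIVE MSV000089217: proteomics intensity table
#   - a RefSeq human NEU3 mRNA (e.g. NM_006656) for the motif-coordinate
#     check; record the accession actually used alongside the output
#
# What it recomputes with the package:
#   - direction calls on the protein and total-RNA layers (call_layer)
#   - monosome/polysome shift calls, including the NEU3 X statistic
#     (shift_layer; the study reports X = 5.92 for NEU3)
#   - the 27-group classification and group sizes (classify_dataset)
#   - exact positions of the two group-4 motif instances in the NEU3 CDS
#     (exact_substring_scan; printed CDS-local starts 315 and 1041)

suppressMessages(library(riboshift))

args <- commandArgs(trailingOnly = TRUE)
data_dir <- if (length(args)) args[[1]] else "published_data"
if (!dir.exists(data_dir))
  stop("download the deposited tables into '", data_dir, "' first; ",
       "see the comments at the top of this script")

# Expected (user-prepared) layout, after formatting the downloads as the
# package's tab-delimited convention:
#   <data_dir>/protein.tsv + protein_meta.tsv
#   <data_dir>/total.tsv + total_meta.tsv
#   <data_dir>/monosome.tsv + monosome_meta.tsv
#   <data_dir>/polysome.tsv + polysome_meta.tsv
#   <data_dir>/neu3.fa + neu3_regions.tsv
layer <- function(nm) read_abundance(file.path(data_dir, paste0(nm, ".tsv")),
                                     file.path(data_dir,
                                               paste0(nm, "_meta.tsv")))
prot <- layer("protein"); tot <- layer("total")
mono <- layer("monosome"); poly <- layer("polysome")

pc <- call_layer(prot, "protein")
rc <- call_layer(tot, "total")
sh <- shift_layer(mono, poly)
cl <- classify_dataset(pc, rc, sh)

cat("direction calls (total RNA):\n")
print(table(rc$call))
cat("group sizes:\n")
print(cl$summary)

neu3 <- grep("NEU3", sh$feature, value = TRUE)
if (length(neu3))
  cat(sprintf("NEU3 X = %.2f (p = %.3g)\n",
              sh$X[sh$feature == neu3[1]],
              sh$p_value[sh$feature == neu3[1]]))

fa <- file.path(data_dir, "neu3.fa")
if (file.exists(fa)) {
  tx <- read_transcripts(fa, file.path(data_dir, "neu3_regions.tsv"))
  for (inst in c("CCTGAAGCCACTGATGGAAG", "ACTGAGGCTGGAGGAGGAAG")) {
    hit <- exact_substring_scan(inst, tx)
    cat(sprintf("motif instance %s: CDS-local start(s) %s\n", inst,
                paste(hit$local_start, collapse = ", ")))
  }
}
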