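#!/usr/bin/env Rscript
# Stage 2: per-feature direction calls on the protein and total-RNA layers.
#
# Two-tailed t tests (unpaired, pooled variance), raw p < 0.05 gate,
# treated/control ratio of means for direction, and the CI-containment
# equivalence rule (95% CI; 70%/130% band) for "stable". The BH flag at
# q = 0.05 is recorded alongside every call.

suppressMessages(library(riboshift))

data_dir <- "results/data"
out <- "results"
read_layer <- function(nm)
  read_abundance(file.path(data_dir, paste0(nm, ".tsv")),
                 file.path(data_dir, paste0(nm, "_meta.tsv")))

for (layer in c("protein", "total")) {
  calls <- call_layer(read_layer(layer), layer, alpha = 0.05, gate = "raw")
  riboshift:::write_tsv(calls, file.path(out, paste0("calls_", layer,
                                                     ".tsv")))
  tab <- table(calls$call)
  cat(sprintf("%s layer: %s\n", layer,
              paste(sprintf("%s=%d", names(tab), tab), collapse = "  ")))
}
cat("call tables under", out, "\n")
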