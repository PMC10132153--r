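# riboshift

Classification of transcriptional versus translational regulation from
matched proteomics, total-mRNA, monosome and polysome abundance tables —
plus the sequence analyses that follow from it (common-motif discovery and
localization, uORF scanning) and a fully specified synthetic-data
generator with known ground truth.

## Who this is for

Groups doing polysome profiling alongside proteomics and RNA-Seq: the
question is, for each gene, whether a treatment changed its protein level
by changing transcript abundance, by changing translation of the existing
transcripts, or neither. riboshift turns matched control/treated replicate
tables into per-gene verdicts on three axes and a 27-group taxonomy built
from them.

## The method in brief

For each feature and layer (protein, total RNA), control vs treated
replicates are compared by a two-tailed t test; significant features are
**up**/**down** by the treated/control ratio of means. Non-significant
features are **stable** only if they pass equivalence by CI containment:
the treated 95% CI must lie inside

```
[ 0.70 x max(control CI low, 0),  1.30 x control CI high ]
```

otherwise they are **other** and excluded from grouping.

Translation is read from per-sample polysome/monosome ratios
PM = (P + ε)/(M + ε). For features whose PM ratios differ significantly
between conditions,

```
X = mean(PM_treated) / mean(PM_control)
```

calls **m_to_p** (X > 1, more translation) or **p_to_m** (X < 1); the same
containment rule on PM ratios gives **stable**/**other**.

The triple (protein, RNA, shift) maps to group `g = 9p + 3r + s + 1`
(indices 0 = up/m_to_p, 1 = stable, 2 = down/p_to_m). Group 4 is the
translational-upregulation signature: protein up, mRNA stable, M→P shift.
The 18 groups where the protein and RNA directions disagree are
{4–12} ∪ {16–24}.

Sequence follow-up: ZOOPS (zero-or-one occurrence per sequence) EM motif
discovery over widths 10–25 with BIC-type width selection, sense-strand
PWM scanning with *exact* score p-values (dynamic programming over the
integer score distribution, equal to 4^W enumeration), hit localization to
5′UTR/CDS/3′UTR, and uORF detection under ATG-only and
alternative-initiation-codon modes with per-group prevalence tests.

## Worked example

```r
library(riboshift)

# a synthetic study: 4 paired cell lines, control vs treated,
# 200 features each in groups 1, 4, 13, 14
cfg <- sim_config(features_per_group = c("1" = 200, "4" = 200,
                                         "13" = 200, "14" = 200),
                  seed = 20260924)
d  <- generate_dataset(cfg)

pc <- call_layer(d$tables$protein, "protein")   # protein axis
rc <- call_layer(d$tables$total, "total")       # mRNA axis
sh <- shift_layer(d$tables$monosome, d$tables$polysome)  # translation axis
cl <- classify_dataset(pc, rc, sh)

table(sh$call)
#  m_to_p   other  p_to_m  stable
#     601      11       8     180
mean(sh$X[d$truth$group == 4])
# [1] 3.92          # generator-implied allocation odds ratio is 4
m <- match(d$truth$feature, cl$records$feature)
mean(cl$records$group[m] == d$truth$group, na.rm = TRUE)
# [1] 0.943        # fraction of classified features in their true group
```

The shift calls: 601 of the 600 truly shifted features plus a handful of
false positives land in `m_to_p`; group-4 features average X ≈ 3.9, the
odds ratio implied by moving polysome allocation from 0.5 to 0.8. Running
the same pipeline from files is what `analysis/01_simulate.R` …
`analysis/06_uorf_scan.R` do, stage by stage, writing tables under
`results/`; stage 5 recovers the planted 20-mer
`GGAGGAGGAGGAGGAGGAGG` as the best-width consensus and finds it in the
CDS of ~89% of group-4 transcripts versus ~1.5% elsewhere.

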