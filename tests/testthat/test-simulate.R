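test_that("identical configs give bit-identical datasets", {
  cfg <- sim_config(features_per_group = c("4" = 15, "22" = 10), seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$tables$protein$values, d2$tables$protein$values)
  expect_identical(d1$tables$polysome$values, d2$tables$polysome$values)
  expect_identical(d1$transcripts$seq, d2$transcripts$seq)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(sim_config(features_per_group = c("4" = 15,
                                                           "22" = 10),
                                    seed = 8))
  expect_false(identical(d1$tables$protein$values,
                         d3$tables$protein$values))
})

test_that("invalid configuration fields are named in the error", {
  expect_error(sim_config(effect_up = 0.9), "effect_up")
  expect_error(sim_config(effect_down = 1.5), "effect_down")
  expect_error(sim_config(polysome_fraction_base = 1.2),
               "polysome_fraction_base")
  expect_error(sim_config(features_per_group = c("30" = 5)),
               "features_per_group")
  expect_error(sim_config(cds_length = 100), "cds_length")
})

test_that("null-template features have unit effects on every layer", {
  cfg <- sim_config(features_per_group = c("14" = 100), seed = 71)
  d <- generate_dataset(cfg)
  for (layer in c("protein", "total", "free", "monosome", "polysome")) {
    tab <- d$tables[[layer]]
    ctrl <- tab$metadata$condition == "control"
    ratio <- rowMeans(tab$values[, !ctrl]) / rowMeans(tab$values[, ctrl])
    # replicate_cv 0.1 over 4+4 columns: mean ratio near 1, tight spread
    expect_equal(mean(ratio), 1, tolerance = 0.05)
    expect_lt(sd(ratio), 0.15)
  }
})

test_that("group-4 features raise their polysome/monosome ratio under treatment", {
  cfg <- sim_config(features_per_group = c("4" = 200, "14" = 200), seed = 1)
  d <- generate_dataset(cfg)
  mono <- d$tables$monosome$values; poly <- d$tables$polysome$values
  ctrl <- d$tables$monosome$metadata$condition == "control"
  pm <- poly / mono
  up <- rowMeans(pm[, !ctrl]) > rowMeans(pm[, ctrl])
  g4 <- d$truth$group == 4
  expect_gt(mean(up[g4]), 0.95)
  expect_lt(mean(up[!g4]), 0.7)
})

test_that("monosome plus polysome equals total times the fractionation efficiency", {
  cfg <- sim_config(features_per_group = c("1" = 50, "14" = 50, "27" = 50),
                    replicate_cv = 1e-4, unit_cv = 0, seed = 72)
  d <- generate_dataset(cfg)
  bound <- d$tables$monosome$values + d$tables$polysome$values
  expect_equal(unname(bound / d$tables$total$values),
               matrix(cfg$fractionation_efficiency, nrow(bound),
                      ncol(bound)),
               tolerance = 1e-3)
})

test_that("template effect signs match each group's defining triple", {
  cfg <- sim_config(features_per_group = setNames(rep(5L, 27L),
                                                  as.character(1:27)),
                    seed = 73)
  d <- generate_dataset(cfg)
  tr <- group_triple(d$truth$group)
  expect_equal(sign(d$truth$protein_effect - 1),
               c(up = 1, stable = 0, down = -1)[tr$protein_call],
               ignore_attr = TRUE)
  expect_equal(sign(d$truth$rna_effect - 1),
               c(up = 1, stable = 0, down = -1)[tr$rna_call],
               ignore_attr = TRUE)
  expect_equal(sign(d$truth$theta_treated - d$truth$theta_control),
               c(m_to_p = 1, stable = 0, p_to_m = -1)[tr$shift_call],
               ignore_attr = TRUE)
})

test_that("every feature appears once in the truth and once per layer", {
  cfg <- sim_config(features_per_group = c("4" = 12, "14" = 8), seed = 74)
  d <- generate_dataset(cfg)
  expect_equal(anyDuplicated(d$truth$feature), 0L)
  for (tab in d$tables) {
    expect_identical(rownames(tab$values), d$truth$feature)
    expect_equal(ncol(tab$values), 2L * cfg$n_units)
  }
  expect_identical(d$transcripts$id, d$truth$feature)
})

test_that("planted motifs land verbatim at the recorded in-region positions", {
  cfg <- sim_config(features_per_group = c("4" = 10), seed = 75)
  d <- generate_dataset(cfg)
  set.seed(76)
  tx <- plant_motif(d$transcripts, group4_motif(), d$transcripts$id,
                    region = "cds", rate = 1)
  pl <- attr(tx, "placements")
  expect_equal(nrow(pl), 10L)
  for (i in seq_len(nrow(pl))) {
    r <- tx[tx$id == pl$feature[i], ]
    expect_equal(substr(r$seq, pl$start[i], pl$end[i]), group4_motif())
    expect_gt(pl$start[i], r$utr5_length)
    expect_lte(pl$end[i], r$utr5_length + r$cds_length)
  }
  # rate 0.8 over 50 transcripts plants exactly 40
  cfg50 <- sim_config(features_per_group = c("14" = 50), seed = 77)
  d50 <- generate_dataset(cfg50)
  set.seed(78)
  tx50 <- plant_motif(d50$transcripts, group4_motif(), d50$transcripts$id,
                      rate = 0.8)
  expect_equal(nrow(attr(tx50, "placements")), 40L)
})

test_that("planting into a too-short region names the transcript", {
  tx <- transcript_set("short5", paste0("ACGTACGTAC",
                                        strrep("ATGGGCGGCTAA", 1)), 10, 12, 0)
  expect_error(plant_motif(tx, group4_motif(), "short5", region = "utr5"),
               "short5")
})

test_that("planted uORFs are found by the finder", {
  cfg <- sim_config(features_per_group = c("14" = 20),
                    utr5_start_free = TRUE, seed = 79)
  d <- generate_dataset(cfg)
  base <- find_uorfs(d$transcripts, mode = "atg_plus_alternatives")
  expect_equal(nrow(base), 0L)  # scrubbed UTRs carry no start codons
  set.seed(80)
  tx <- plant_uorf(d$transcripts, d$transcripts$id, rate = 0.5)
  rec <- find_uorfs(tx, mode = "atg_only")
  expect_setequal(unique(rec$transcript), attr(tx, "placements")$feature)
  expect_true(all(rec$classification == "contained"))
})

test_that("negative-binomial mode yields integer RNA counts with the same templates", {
  cfg <- sim_config(features_per_group = c("4" = 80), noise_model = "negbin",
                    baseline_log_mean = log(500), seed = 81)
  d <- generate_dataset(cfg)
  expect_true(all(d$tables$total$values == round(d$tables$total$values)))
  ctrl <- d$tables$total$metadata$condition == "control"
  expect_false(all(d$tables$protein$values ==
                   round(d$tables$protein$values)))
  rec <- shift_layer(d$tables$monosome, d$tables$polysome)
  expect_gte(mean(rec$call == "m_to_p"), 0.8)
})
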