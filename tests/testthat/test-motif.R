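test_that("ZOOPS EM recovers a planted 20-mer and climbs monotonically", {
  seqs <- planted_sequences(20, 100)
  m <- zoops_em(seqs, 20, seed = 1)
  expect_equal(m$consensus, group4_motif())
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_gt(m$gamma, 0.8)
  expect_gt(m$loglik, m$loglik_background)
  # rerun is deterministic under the same seed
  expect_equal(zoops_em(seqs, 20, seed = 1)$pwm, m$pwm)
})

test_that("sequences shorter than the width are rejected by name", {
  expect_error(zoops_em(c(a = strrep("ACGT", 10), b = "ACGTACGTA"), 12),
               "b")
  expect_error(zoops_em(character(0), 12), "empty")
  expect_error(zoops_em(strrep("A", 50), 9), "width")
})

test_that("on pure background data the penalized score stays negative", {
  set.seed(91)
  hits <- 0L
  for (s in 1:5) {
    null_seqs <- vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
            collapse = ""), character(1))
    m <- zoops_em(null_seqs, 10, seed = s, n_candidates = 30)
    llr <- m$loglik - m$loglik_background
    score <- llr - (3 * 10 + 1) / 2 * log(10)
    if (score < 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("width selection over 10-25 picks the planted width", {
  seqs <- planted_sequences(20, 100)
  d <- discover(seqs, 10, 25, seed = 3)
  expect_equal(d$best$width, 20L)
  expect_equal(d$best$consensus, group4_motif())
  expect_equal(nrow(d$by_width), 16L)
})

test_that("two disjointly planted motifs surface at their own widths", {
  w12 <- "TTTTCCCCAAAT"
  seqs <- c(planted_sequences(10, 80, motif = w12, seed = 101),
            planted_sequences(10, 80, seed = 102))
  d <- discover(seqs, W_min = 12, W_max = 12, seed = 4)
  expect_equal(d$by_width$consensus[1], w12)
  d20 <- discover(seqs, W_min = 20, W_max = 20, seed = 4)
  expect_equal(d20$by_width$consensus[1], group4_motif())
})

test_that("exact score p-values match enumeration for small widths", {
  for (W in c(4L, 6L)) {
    m <- random_model(W, seed = W)
    sm <- integer_score_matrix(m)
    qs <- unique(round(quantile(colSums(sm) + 0,
                                c(0, 0.5, 1)))) # spread of thresholds
    qs <- c(sum(apply(sm, 2, min)), 0, sum(apply(sm, 2, max)), qs)
    bf <- enumerated_pvalue(m, qs)
    dp <- vapply(qs, function(q) exact_score_pvalue(m, q / 1000),
                 numeric(1))
    expect_equal(dp, bf, tolerance = 1e-9)
  }
  m1 <- random_model(1, seed = 3, uniform_bg = TRUE)
  expect_equal(exact_score_pvalue(m1, max(integer_score_matrix(m1)) / 1000),
               0.25)
  expect_equal(exact_score_pvalue(m1, -Inf), 1.0)
})

test_that("scanning finds the consensus and respects region annotation", {
  seqs <- planted_sequences(20, 100)
  m <- zoops_em(seqs, 20, seed = 1)
  tx <- transcript_set("c1", m$consensus, 0, 20, 0)
  hit <- log_odds_scan(m, tx, p_threshold = 1e-4)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 20L)
  expect_equal(hit$region, "cds")
  # all-A transcript against this G-rich model: nothing at 1e-4
  txA <- transcript_set("a1", strrep("A", 60), 10, 30, 20)
  expect_equal(nrow(log_odds_scan(m, txA, p_threshold = 1e-4)), 0L)
  # motif crossing the utr5/cds boundary is labeled spanning
  tx2 <- transcript_set("s1", paste0(strrep("A", 10), m$consensus,
                                     strrep("A", 12)), 15, 21, 6)
  hit2 <- log_odds_scan(m, tx2, p_threshold = 1e-4)
  expect_equal(hit2$region, "spanning")
  expect_true(is.na(hit2$local_start))
})

test_that("overlapping windows resolve greedily by ascending p-value", {
  m <- zoops_em(planted_sequences(20, 100), 20, seed = 1)
  # two planted copies 5 apart can only yield one non-overlapping hit
  tandem <- paste0(strrep("A", 5), group4_motif(), strrep("A", 5))
  tx <- transcript_set("t", paste0(tandem, group4_motif()),
                       0, nchar(tandem) + 20, 0)
  hits <- log_odds_scan(m, tx, p_threshold = 1e-3)
  expect_gte(nrow(hits), 2L)
  sep <- diff(sort(hits$start))
  expect_true(all(sep >= 20))
})

test_that("sense-only scanning: the reverse complement carries no hits", {
  motif <- "CCTGAAGCCACTGATGGAAG"  # non-palindromic
  seqs <- planted_sequences(20, 100, motif = motif, seed = 103)
  m <- zoops_em(seqs, 20, seed = 2)
  expect_equal(m$consensus, motif)
  fwd <- transcript_set("f", paste0(strrep("A", 10), motif,
                                    strrep("C", 12)), 0, 42, 0)
  expect_equal(nrow(log_odds_scan(m, fwd, p_threshold = 1e-4)), 1L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(strrep("A", 10), motif,
                                 strrep("C", 12)))))
  rev <- transcript_set("r", rc, 0, 42, 0)
  expect_equal(nrow(log_odds_scan(m, rev, p_threshold = 1e-4)), 0L)
})

test_that("hit coordinates round-trip between global and region-local", {
  tx <- transcript_set("x", strrep("ACGT", 30), 25, 60, 35)
  for (g in c(1, 25, 26, 40, 85, 86, 120)) {
    loc <- global_to_local(tx, "x", g)
    expect_equal(local_to_global(tx, "x", loc$region, loc$pos), g)
  }
  expect_equal(global_to_local(tx, "x", 26),
               list(region = "cds", pos = 1))
  expect_equal(global_to_local(tx, "x", 40)$pos, 40 - 25)
})

test_that("exact substring search reports CDS-local coordinates", {
  inst <- "CCTGAAGCCACTGATGGAAG"
  cds <- paste0(strrep("GCA", 104), inst, strrep("GCA", 20))
  # instance begins at CDS-local position 313 here by construction
  tx <- transcript_set("n1", paste0(strrep("T", 50), cds), 50, nchar(cds), 0)
  hit <- exact_substring_scan(inst, tx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$region, "cds")
  expect_equal(hit$local_start, 313L)
  expect_equal(hit$start, 50L + 313L)
  expect_equal(hit$local_end, 313L + 19L)
})

test_that("region occurrence tables separate planted from background groups", {
  cfg <- sim_config(features_per_group = c("4" = 30, "14" = 30), seed = 111)
  d <- generate_dataset(cfg)
  g4 <- d$truth$feature[d$truth$group == 4]
  set.seed(112)
  tx <- plant_motif(d$transcripts, group4_motif(), g4, region = "cds",
                    rate = 0.9)
  groups <- data.frame(feature = d$truth$feature, group = d$truth$group)
  tab <- region_occurrence_table(group4_motif(), tx, groups)
  expect_equal(tab$frac_with_hit[tab$group == 4], 0.9, tolerance = 0.01)
  expect_lt(tab$frac_with_hit[tab$group == 14], 0.2)
  expect_gt(tab$frac_cds[tab$group == 4], 0.9)
  # planting in the 3'UTR concentrates the breakdown there
  set.seed(113)
  tx3 <- plant_motif(d$transcripts, group4_motif(), g4, region = "utr3",
                     rate = 1)
  tab3 <- region_occurrence_table(group4_motif(), tx3, groups)
  expect_gt(tab3$frac_utr3[tab3$group == 4], 0.9)
  # empty group: n = 0 row, no division
  tab0 <- region_occurrence_table(group4_motif(), tx,
                                  rbind(groups,
                                        data.frame(feature = "ghost",
                                                   group = 9)))
  expect_equal(tab0$n[tab0$group == 9], 0L)
  expect_true(is.na(tab0$frac_with_hit[tab0$group == 9]))
})

test_that("degenerate backgrounds are rejected", {
  m <- random_model(4, seed = 5)
  m$background["A"] <- 0
  expect_error(integer_score_matrix(m), "degenerate background")
})
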