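test_that("mean_ci matches the closed form and rejects degenerate input", {
  expect_equal(mean_ci(c(10, 10, 10, 10)), c(10, 10))
  # mean 2.5, sd 1.29099, t_{0.975,3} = 3.18245
  expect_equal(round(mean_ci(c(1, 2, 3, 4)), 4), c(0.4457, 4.5543))
  expect_error(mean_ci(5), "insufficient replicates")
  lvl99 <- mean_ci(c(1, 2, 3, 4), level = 0.99)
  expect_true(lvl99[1] < 0.4457 && lvl99[2] > 4.5543)
})

test_that("equivalence containment implements the 70%/130% band", {
  expect_true(equivalence_contained(c(10, 20), c(8, 25)))   # band [7, 26]
  expect_false(equivalence_contained(c(10, 20), c(6, 25)))  # 6 < 7
  # self-containment for any params with lower <= 1 <= upper
  for (ab in list(c(0, 0), c(3, 7), c(2, 2))) {
    expect_true(equivalence_contained(ab, ab))
    expect_true(equivalence_contained(ab, ab,
      equivalence_params(upper_factor = 1.01, lower_factor = 0.99)))
  }
  expect_error(equivalence_contained(c(5, 3), c(1, 2)), "malformed")
  # negative control low is clamped to 0 before the 70% factor
  expect_true(equivalence_contained(c(-5, 20), c(0, 25)))
})

test_that("equivalence containment agrees with a brute-force interval oracle", {
  set.seed(11)
  params <- equivalence_params()
  for (i in 1:10000) {
    c0 <- sort(runif(2, -2, 30))
    t0 <- sort(runif(2, -2, 40))
    band_lo <- 0.70 * max(c0[1], 0)
    band_hi <- 1.30 * c0[2]
    oracle <- t0[1] >= band_lo && t0[2] <= band_hi
    if (oracle != equivalence_contained(c0, t0, params))
      fail(sprintf("mismatch at control (%g,%g) treated (%g,%g)",
                   c0[1], c0[2], t0[1], t0[2]))
  }
  succeed()
})

test_that("widening the treated CI never turns other into stable", {
  set.seed(12)
  for (i in 1:500) {
    c0 <- sort(runif(2, 0, 20))
    t0 <- sort(runif(2, 0, 30))
    wide <- c(t0[1] - runif(1, 0, 5), t0[2] + runif(1, 0, 5))
    if (equivalence_contained(c0, wide))
      expect_true(equivalence_contained(c0, t0))
  }
})

test_that("BH flags reproduce the step-up rule", {
  expect_equal(bh_flags(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_flags(c(0.04, 0.5, 0.9), 0.05), rep(FALSE, 3))
  expect_identical(bh_flags(numeric(0)), logical(0))
  expect_error(bh_flags(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_feature reproduces direction, stability and conventions", {
  expect_equal(call_feature(c(10, 11, 9, 10), c(20, 21, 19, 20))$call, "up")
  expect_equal(call_feature(c(20, 21, 19, 20), c(10, 11, 9, 10))$call, "down")
  same <- call_feature(c(10, 11, 9, 10), c(10, 11, 9, 10))
  expect_equal(same$call, "stable")
  # zero variance in both groups with equal means: stable with p = 1
  const <- call_feature(c(5, 5, 5), c(5, 5, 5))
  expect_equal(const$p_value, 1)
  expect_equal(const$call, "stable")
  expect_error(call_feature(c(0, 0, 0), c(1, 2, 3)), "undefined ratio")
})

test_that("total mRNA read as 26.7 +/- 4.5 vs 24.9 +/- 3.6 is stable under both readings", {
  for (spread in c(1, 2)) {  # 1: +/- is sd; 2: +/- is standard error (n=4)
    ctrl <- values_with(26.7, 4.5 * spread)
    trt <- values_with(24.9, 3.6 * spread)
    res <- call_feature(ctrl, trt)
    expect_false(res$significant)
    expect_equal(res$call, "stable")
  }
})

test_that("calls are invariant under positive rescaling of a feature", {
  set.seed(13)
  for (i in 1:50) {
    ctrl <- rlnorm(4, 3, 0.3)
    trt <- rlnorm(4, 3 + sample(c(-1, 0, 1), 1) * 0.5, 0.3)
    k <- runif(1, 0.01, 100)
    a <- call_feature(ctrl, trt)
    b <- call_feature(k * ctrl, k * trt)
    expect_equal(a$call, b$call)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
    expect_equal(a$ratio, b$ratio, tolerance = 1e-9)
  }
})

test_that("the four verdicts partition every tested feature", {
  set.seed(14)
  cfg <- sim_config(features_per_group = c("1" = 10, "14" = 10, "27" = 10),
                    seed = 21)
  d <- generate_dataset(cfg)
  for (layer in c("protein", "total")) {
    calls <- call_layer(d$tables[[layer]], layer)
    expect_true(all(calls$call %in% c("up", "down", "stable", "other")))
    expect_equal(nrow(calls), 30)
    up <- calls$call == "up"
    expect_true(all(calls$significant[up] & calls$ratio[up] > 1))
    dn <- calls$call == "down"
    expect_true(all(calls$significant[dn] & calls$ratio[dn] < 1))
    expect_true(all(!calls$significant[calls$call == "stable"]))
  }
})

test_that("call_layer recovers the simulated templates", {
  cfg4 <- sim_config(features_per_group = c("4" = 100), seed = 31)
  d4 <- generate_dataset(cfg4)
  prot <- call_layer(d4$tables$protein, "protein")
  expect_gte(mean(prot$call == "up"), 0.90)
  cfg14 <- sim_config(features_per_group = c("14" = 100), seed = 32)
  d14 <- generate_dataset(cfg14)
  tot <- call_layer(d14$tables$total, "total")
  expect_gte(mean(tot$call == "stable"), 0.90)
})

test_that("call_layer flags degenerate features instead of failing", {
  set.seed(15)
  vals <- matrix(rlnorm(5 * 8, 3, 0.2), 5, 8,
                 dimnames = list(paste0("f", 1:5),
                                 paste0("s", 1:8)))
  vals["f1", 1:4] <- 0                 # zero control mean
  vals["f2", c(1, 2, 3, 5, 6)] <- NA  # one usable control replicate
  md <- data.frame(sample = paste0("s", 1:8), layer = "protein",
                   condition = rep(c("control", "treated"), each = 4),
                   unit = rep(paste0("u", 1:4), 2))
  tab <- abundance_table(vals, md)
  calls <- call_layer(tab, "protein")
  expect_equal(calls$call[calls$feature == "f1"], "other")
  expect_equal(calls$reason[calls$feature == "f1"], "zero_control_mean")
  expect_equal(calls$reason[calls$feature == "f2"],
               "insufficient_replicates")
  expect_error(call_layer(tab, "total"), "absent")
})

test_that("the BH gate is at least as conservative as the raw gate", {
  cfg <- sim_config(features_per_group = c("14" = 60), seed = 41)
  d <- generate_dataset(cfg)
  raw <- call_layer(d$tables$total, "total", gate = "raw")
  bh <- call_layer(d$tables$total, "total", gate = "bh")
  expect_lte(sum(bh$significant), sum(raw$significant))
  expect_true(all(bh$significant <= raw$significant))
})
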