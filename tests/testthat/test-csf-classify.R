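test_that("worked examples and boundary conventions classify as documented", {
  got <- classify_point(c(0.2, 0.8, 0.9), c(90, 60, 40))
  expect_equal(got$area, c("A1", "A4", "A6"))
  expect_equal(got$band, c("good_moderate", "weak_cs", "weak_training"))

  # ties: pc exactly 75 -> upper band; pc exactly 50 -> weak CS;
  # contrast exactly at the split -> low-contrast column
  expect_equal(classify_point(0.3, 75)$area, "A1")
  expect_equal(classify_point(0.3, 50)$area, "A3")
  expect_equal(classify_point(0.5, 90)$area, "A1")
  expect_equal(classify_point(0.5 + 1e-9, 90)$area, "A2")
  expect_equal(classify_point(0.3, 49.999)$area, "A5")
})

test_that("the six areas partition the (contrast, pc) rectangle", {
  grid <- expand.grid(contrast = seq(0, 1, length.out = 101),
                      pc = seq(0, 100, length.out = 91))
  rule <- classification_rule()
  got <- classify_point(grid$contrast, grid$pc, rule)
  expect_true(all(got$area %in% paste0("A", 1:6)))
  # disjoint and exhaustive: each point satisfies exactly one region predicate
  preds <- cbind(
    A1 = grid$contrast <= 0.5 & grid$pc >= 75,
    A2 = grid$contrast > 0.5 & grid$pc >= 75,
    A3 = grid$contrast <= 0.5 & grid$pc >= 50 & grid$pc < 75,
    A4 = grid$contrast > 0.5 & grid$pc >= 50 & grid$pc < 75,
    A5 = grid$contrast <= 0.5 & grid$pc < 50,
    A6 = grid$contrast > 0.5 & grid$pc < 50)
  expect_true(all(rowSums(preds) == 1))
  expect_equal(got$area, colnames(preds)[max.col(preds)])
})

test_that("raising accuracy never demotes a point to a worse band", {
  band_rank <- c(weak_training = 1, weak_cs = 2, good_moderate = 3)
  for (ct in c(0.1, 0.5, 0.9)) {
    pcs <- seq(0, 100, by = 5)
    ranks <- band_rank[classify_point(rep(ct, length(pcs)), pcs)$band]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("band summaries count areas and bands consistently", {
  # a 23-point cloud with a known 12 / 7 / 4 split across the bands
  pts <- data.frame(
    contrast = c(seq(0.1, 0.5, length.out = 6), seq(0.6, 1, length.out = 6),
                 c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8, 0.9),
                 c(0.2, 0.4), c(0.7, 0.9)),
    percent_correct = c(rep(90, 12), rep(60, 7), rep(40, 4)))
  bs <- band_summary(pts)
  expect_equal(bs$n, 23)
  expect_equal(unname(bs$band_counts),
               c(12, 7, 4))
  expect_equal(sum(bs$area_counts), 23)
  expect_equal(sum(bs$band_fractions), 1)

  # ceiling data: everything good/moderate
  all_hi <- band_summary(data.frame(contrast = seq(0.1, 1, by = 0.1),
                                    percent_correct = 100))
  expect_equal(unname(all_hi$band_counts[["good_moderate"]]), 10)

  expect_error(band_summary(data.frame(contrast = numeric(0),
                                       percent_correct = numeric(0))),
               class = "swinecs_data_error")
})

test_that("a pure side-presser's points rarely reach the good/moderate band", {
  # at chance the per-contrast percent correct lands at >= 75% only with
  # binomial tail probability ~5% (n = 10), so over seeds the point cloud
  # sits overwhelmingly in the weak-CS / weak-training bands
  frac_outside_good <- vapply(1:20, function(seed) {
    pressy <- observer_params(bias_side = 2, bias_strength = 1, seed = seed)
    pc <- per_contrast_performance(
      run_session(session_config(seed = seed), pressy))
    bs <- band_summary(pc)
    1 - bs$band_fractions[["good_moderate"]]
  }, 0)
  expect_gte(mean(frac_outside_good), 0.8)
})

test_that("rule parameters are validated and configurable", {
  expect_error(classification_rule(contrast_split = 0),
               class = "swinecs_config_error")
  expect_error(classification_rule(upper_band_min_pc = 40),
               class = "swinecs_config_error")
  shifted <- classification_rule(contrast_split = 0.35)
  expect_equal(classify_point(0.4, 90, shifted)$area, "A2")
  expect_error(classify_point(1.2, 50), class = "swinecs_config_error")
  expect_error(classify_point(0.5, 101), class = "swinecs_config_error")
})
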