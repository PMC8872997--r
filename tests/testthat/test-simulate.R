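test_that("score generator plants the requested correlation and sex shift", {
  cfg0 <- sim_config(1e5, score_correlation = 0, score_sex_shift = 0, seed = 1)
  s0 <- withr::with_seed(1, simulate_scores(cfg0))
  expect_lt(abs(cor(s0$score_asd, s0$score_scz)), 0.01)
  expect_equal(mean(s0$score_asd), 0, tolerance = 1e-12)
  expect_equal(sd(s0$score_asd), 1, tolerance = 1e-12)

  cfg <- sim_config(1e5, score_correlation = 0.08, score_sex_shift = 0, seed = 2)
  s <- withr::with_seed(2, simulate_scores(cfg))
  expect_lt(abs(cor(s$score_asd, s$score_scz) - 0.08), 0.01)

  cfgf <- sim_config(1e5, score_sex_shift = 0.04, seed = 3)
  sf <- withr::with_seed(3, simulate_scores(cfgf))
  tt <- t.test(sf$score_asd[sf$sex == 1], sf$score_asd[sf$sex == 0])
  expect_gt(tt$statistic, 0)
  expect_gt(mean(sf$score_asd[sf$sex == 1]), mean(sf$score_asd[sf$sex == 0]))
})

test_that("invalid score parameters are rejected", {
  expect_error(sim_config(100, score_correlation = 1),
               class = "asymlink_parameter_error")
  expect_error(sim_config(100, score_correlation = -1.2),
               class = "asymlink_parameter_error")
  expect_error(sim_config(100, handedness_base_rates = c(0.5, 0.4, 0.2)),
               class = "asymlink_parameter_error")
  expect_error(sim_config(100, outlier_rate = 1),
               class = "asymlink_parameter_error")
})

test_that("left/right construction inverts the asymmetry index exactly", {
  cfg <- sim_config(300, outlier_rate = 0, seed = 5)
  scores <- withr::with_seed(5, simulate_scores(cfg))
  meas <- withr::with_seed(6, simulate_regional_measures(cfg, scores))
  a <- attr(meas, "latent_ai")
  L <- as.matrix(meas[grep("^left_", names(meas))])
  R <- as.matrix(meas[grep("^right_", names(meas))])
  expect_true(all(L > 0) && all(R > 0))
  expect_equal((L - R) / ((L + R) / 2), a, tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("degenerate asymmetry gives symmetric sides and a=0.5 the 2.5/1.5 split", {
  # direct inverse construction: s = 2, a = 0.5
  s <- 2; a <- 0.5
  left <- s * (1 + a / 2); right <- s * (1 - a / 2)
  expect_equal(c(left, right), c(2.5, 1.5))
  expect_equal(asymmetry_index(left, right), 0.5)

  cfg <- sim_config(50, canonical_r_a = 0, canonical_r_b = 0,
                    sex_pattern = rep(0, 42), ai_scale = 1e-12,
                    ai_mean = rep(0, 42),
                    covariate_spec = list(), seed = 7)
  scores <- withr::with_seed(7, simulate_scores(cfg))
  meas <- withr::with_seed(8, simulate_regional_measures(cfg, scores))
  L <- as.matrix(meas[grep("^left_", names(meas))])
  R <- as.matrix(meas[grep("^right_", names(meas))])
  expect_equal(L, R, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("latent asymmetries implying non-positive sides are clipped with a warning", {
  cfg <- sim_config(200, ai_scale = 1.5, ai_mean = rep(1.5, 42), seed = 9)
  scores <- withr::with_seed(9, simulate_scores(cfg))
  expect_warning(
    meas <- withr::with_seed(10, simulate_regional_measures(cfg, scores)),
    "clipped"
  )
  expect_gt(attr(meas, "n_clipped"), 0)
  L <- as.matrix(meas[grep("^left_", names(meas))])
  R <- as.matrix(meas[grep("^right_", names(meas))])
  expect_true(all(L > 0) && all(R > 0))
})

test_that("handedness sampling matches base rates and degenerates cleanly", {
  cfg <- sim_config(1e5,
                    handedness_base_rates = c(0.89, 0.095, 0.015),
                    handedness_betas = matrix(0, 2, 2), seed = 11)
  scores <- withr::with_seed(11, simulate_scores(cfg))
  h <- withr::with_seed(12, simulate_handedness(cfg, scores))
  pr <- table(factor(h, c("right", "left", "mixed"))) / length(h)
  expect_lt(abs(pr[["right"]] - 0.89), 0.005)
  expect_lt(abs(pr[["left"]] - 0.095), 0.005)
  expect_lt(abs(pr[["mixed"]] - 0.015), 0.005)

  cfg1 <- sim_config(500, handedness_base_rates = c(1, 0, 0), seed = 13)
  s1 <- withr::with_seed(13, simulate_scores(cfg1))
  expect_true(all(withr::with_seed(14, simulate_handedness(cfg1, s1)) == "right"))
})

test_that("phenotype panel emits all four declared types", {
  co <- fixture_cohort()
  cb <- attr(co, "codebook")
  expect_setequal(unique(cb$type),
                  c("continuous", "binary", "ordered_categorical",
                    "unordered_categorical"))
  expect_true(all(cb$phenotype %in% names(co)))
  expect_true(all(co$overall_health %in% 1:4))
})

test_that("a fixed seed reproduces the cohort byte-identically", {
  cfg <- sim_config(150, outlier_rate = 0.001, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("cohorts round-trip through TSV plus metadata sidecar", {
  co <- simulate_cohort(sim_config(60, seed = 21))
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(co, prefix)
  expect_true(file.exists(paste0(prefix, ".tsv")))
  expect_true(file.exists(paste0(prefix, ".meta.yaml")))
  back <- read_cohort(prefix)
  expect_equal(nrow(back), nrow(co))
  expect_identical(attr(back, "regions"), attr(co, "regions"))
  expect_identical(attr(back, "codebook"), attr(co, "codebook"))
  expect_equal(back$left_area_region01, co$left_area_region01,
               tolerance = 1e-9)
})

test_that("planted calibration is exact in the decoupled case and feasible when coupled", {
  # closed form: alpha = r / sqrt(1 - r^2) when patterns orthogonal, rho = 0
  a <- asymlink:::calibrate_planted_alphas(0.1, 0.2, 0, 0)
  expect_equal(a, c(0.1 / sqrt(1 - 0.01), 0.2 / sqrt(1 - 0.04)),
               tolerance = 1e-6)
  # coupled case still hits the targets (checked internally to 1e-6)
  expect_silent(asymlink:::calibrate_planted_alphas(0.03, 0.04, 0.08, 0.1))
  expect_equal(asymlink:::calibrate_planted_alphas(0, 0, 0.5, 0), c(0, 0))
})
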