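test_that("asymmetry index follows the laterality formula and its symmetries", {
  expect_equal(asymmetry_index(3, 3), 0)
  expect_equal(asymmetry_index(3, 1), 1)
  expect_equal(asymmetry_index(1, 3), -1)
  expect_error(asymmetry_index(-1, 2), class = "asymlink_value_error")
  expect_error(asymmetry_index(1, 0), class = "asymlink_value_error")

  withr::with_seed(1, {
    for (i in 1:20) {
      L <- runif(50, 0.1, 10)
      R <- runif(50, 0.1, 10)
      cc <- runif(1, 0.01, 100)
      expect_equal(asymmetry_index(L, R), -asymmetry_index(R, L))
      expect_equal(asymmetry_index(cc * L, cc * R), asymmetry_index(L, R))
    }
  })
})

test_that("outlier rule removes only points beyond the SD threshold, computed once", {
  x <- c(rep(0, 99), 100)  # z of the 100 is 9.9 on the pre-removal stats
  out <- remove_outliers(x)
  expect_identical(attr(out, "n_removed"), 1L)
  expect_true(is.na(out[100]))
  expect_true(all(!is.na(out[1:99])))

  withr::with_seed(2, z <- rnorm(1e5))
  cleaned <- remove_outliers(z)
  # expected count n * P(|Z| > 6) ~ 0.2
  expect_lte(attr(cleaned, "n_removed"), 3L)

  expect_warning(const <- remove_outliers(rep(1, 10)), "Zero standard deviation")
  expect_identical(attr(const, "n_removed"), 0L)
  expect_equal(as.numeric(const), rep(1, 10))
})

test_that("inverse normal transform matches the Blom formula and handles ties", {
  got <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(got, c(-0.8694237733, 0, 0.8694237733), tolerance = 1e-9)
  expect_identical(got[2], 0)

  tied <- inverse_normal_transform(c(5, 5, 1, 9))
  expect_identical(tied[1], tied[2])

  withr::with_seed(3, x <- rexp(500))
  y <- inverse_normal_transform(x)
  expect_true(all(order(y) == order(x)))
  g1 <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(g1), 0.05)

  withr::with_seed(4, xm <- replace(rnorm(100), c(3, 7), NA))
  ym <- inverse_normal_transform(xm)
  expect_identical(which(is.na(ym)), c(3L, 7L))

  expect_error(inverse_normal_transform(rep(2, 5)),
               class = "asymlink_value_error")
  # van der Waerden offset maps rank r to qnorm(r / (m + 1))
  expect_equal(inverse_normal_transform(1:3, offset = "vanderwaerden"),
               qnorm((1:3) / 4))
})

test_that("residualization leaves columns orthogonal to the design and is idempotent", {
  withr::with_seed(5, {
    n <- 400
    age <- runif(n, 45, 81)
    noise <- rnorm(n)
    col <- 2 * age + noise
    res <- residualize(cbind(col), cbind(age = age))
    expect_lt(abs(cor(res[, 1], age)), 1e-10)
    expect_equal(residualize(res, cbind(age = age)), res, tolerance = 1e-10)

    # intercept-only design just centres
    m <- matrix(rnorm(60), 20)
    expect_equal(residualize(m), scale(m, scale = FALSE), ignore_attr = TRUE)

    expect_error(residualize(m, cbind(a = 1:20, b = 2 * (1:20))),
                 class = "asymlink_value_error", regexp = "collinear")
  })
})

test_that("missing entries are residualized on their complete cases and stay missing", {
  withr::with_seed(6, {
    n <- 200
    x <- rnorm(n)
    m <- cbind(a = 3 * x + rnorm(n), b = rnorm(n))
    m[c(5, 9), "a"] <- NA
    res <- residualize(m, cbind(x = x))
    expect_true(all(is.na(res[c(5, 9), "a"])))
    obs <- !is.na(m[, "a"])
    expect_lt(abs(cor(res[obs, "a"], x[obs])), 1e-10)
  })
})

test_that("full preprocessing yields 42 centred, covariate-orthogonal columns", {
  co <- fixture_cohort()
  ai <- prepare_asymmetry_matrix(co)
  expect_identical(ncol(ai$values), 42L)
  expect_identical(as.integer(table(ai$regions$measure_class)[c("area", "thickness", "volume")]),
                   c(28L, 8L, 6L))
  mu <- colMeans(ai$values, na.rm = TRUE)
  expect_lt(max(abs(mu)), 1e-8)
  design <- build_covariate_matrix(co)
  for (j in c(1, 10, 42)) {
    obs <- !is.na(ai$values[, j])  # residuals live on each column's cases
    expect_lt(max(abs(cor(ai$values[obs, j], design[obs, ]))), 1e-6)
  }
  expect_true(ai$provenance$include_sex)
  expect_identical(ai$provenance$steps[1], "outlier_removal_raw_6sd")
})

test_that("preprocessing is invariant to monotone rescaling of a raw column", {
  co <- fixture_cohort()
  ai1 <- prepare_asymmetry_matrix(co)
  co2 <- co
  # a monotone map of both sides that preserves the AI ranks: scale by a
  # positive constant (AI is scale-invariant, the rank transform does the rest)
  co2$left_area_region01 <- co2$left_area_region01 * 3.7
  co2$right_area_region01 <- co2$right_area_region01 * 3.7
  ai2 <- prepare_asymmetry_matrix(co2)
  expect_equal(ai1$values[, "area_region01"], ai2$values[, "area_region01"],
               tolerance = 1e-10)
})

test_that("injected extreme measures are removed and counted", {
  cfg <- sim_config(800, outlier_rate = 0.002, seed = 31)
  co <- simulate_cohort(cfg)
  cells <- attr(co, "outlier_cells")
  expect_gt(nrow(cells), 0)
  ai <- prepare_asymmetry_matrix(co)
  expect_gte(sum(ai$provenance$outliers_removed), nrow(cells))
  # every injected cell is missing in the AI matrix
  for (i in seq_len(nrow(cells))) {
    region <- sub("^(left|right)_", "", cells$column[i])
    expect_true(is.na(ai$values[cells$row[i], region]))
  }
})

test_that("the AI-level outlier option and extra covariates are honoured", {
  co <- fixture_cohort()
  ai <- prepare_asymmetry_matrix(co, outliers_on = "ai",
                                 extra_covariates = "brain_size")
  expect_identical(ai$provenance$steps[1], "outlier_removal_ai_6sd")
  expect_true("brain_size" %in% ai$provenance$covariates)
  obs <- !is.na(ai$values[, 1])
  expect_lt(abs(cor(ai$values[obs, 1], co$brain_size[obs])), 1e-6)
})
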