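test_that("loading correlation matches hand arithmetic and boundary cases", {
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  b <- c(0.5, 0.1, 0.4, 0.2, 0.3)
  # hand Pearson: cross-products of deviations give -0.03 / 0.1
  expect_equal(loading_correlation(a, b), -0.3, tolerance = 1e-12)
  expect_equal(loading_correlation(a, a), 1)
  expect_equal(loading_correlation(a, -a), -1)
  expect_error(loading_correlation(a, rep(1, 5)),
               class = "asymlink_value_error")
  expect_error(loading_correlation(a, b[1:4]), class = "asymlink_value_error")
})

test_that("empirical p-value uses the add-one rule", {
  expect_equal(empirical_pvalue(0.45, c(-0.5, 0.1, 0.4)), 0.5)
  null999 <- seq(-0.4, 0.4, length.out = 999)
  expect_equal(empirical_pvalue(0.9, null999), 1 / 1000)
  expect_gt(empirical_pvalue(0, rnorm(500)), 0.9)
  expect_equal(empirical_pvalue(0.3, c(0.4, -0.5, 0.2), sided = "greater"),
               (1 + 1) / 4)
  expect_error(empirical_pvalue(0.1, numeric(0)),
               class = "asymlink_value_error")
})

test_that("empirical p is monotone non-increasing in |observed|", {
  withr::with_seed(1, null <- rnorm(200))
  obs <- seq(0, 1, by = 0.05)
  ps <- vapply(obs, empirical_pvalue, numeric(1), null_sample = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("concordance classification follows the dual-threshold rule", {
  load_a <- c(pars_opercularis = -0.30, r2 = 0.25, r3 = 0.15, r4 = 0.5)
  load_b <- c(pars_opercularis = -0.28, r2 = -0.25, r3 = 0.9, r4 = 0.6)
  got <- classify_concordance(load_a, load_b)
  expect_identical(got$concordant, c("pars_opercularis", "r4"))
  expect_identical(got$discordant, "r2")
  # exactly at the threshold counts as neither
  none <- classify_concordance(c(a = 0.2, b = -0.2), c(a = 0.2, b = -0.2))
  expect_length(none$concordant, 0)
  expect_length(none$discordant, 0)
})

test_that("the joint shuffle preserves the score-score correlation", {
  withr::with_seed(2, {
    n <- 60
    X <- matrix(rnorm(n * 5), n, 5)
    sa <- rnorm(n)
    sb <- 0.5 * sa + rnorm(n)
  })
  r0 <- cor(sa, sb)
  withr::with_seed(3, {
    for (i in 1:10) {
      idx <- sample.int(n)
      expect_equal(cor(sa[idx], sb[idx]), r0, tolerance = 1e-12)
    }
  })
})

test_that("the permutation null is deterministic given the seed", {
  co <- fixture_cohort()
  ai <- prepare_asymmetry_matrix(co)
  suppressWarnings({
    n1 <- joint_permutation_null(ai, co$score_asd, co$score_scz,
                                 n_perm = 10, seed = 7)
    n2 <- joint_permutation_null(ai, co$score_asd, co$score_scz,
                                 n_perm = 10, seed = 7)
  })
  expect_identical(n1, n2)
  expect_length(n1, 10L)
  expect_warning(joint_permutation_null(ai, co$score_asd, co$score_scz,
                                        n_perm = 10, seed = 1),
                 "unstable")
})

test_that("a shared planted pattern lands far in the null's right tail", {
  cfg <- sim_config(4000, loading_pattern_a = sin(1:42),
                    loading_pattern_b = sin(1:42),
                    canonical_r_a = 0.15, canonical_r_b = 0.15, seed = 51)
  co <- simulate_cohort(cfg)
  ai <- prepare_asymmetry_matrix(co)
  cmp <- compare_loading_patterns(ai, co$score_asd, co$score_scz,
                                  n_perm = 199, seed = 52)
  expect_gt(cmp$observed_r, 0.5)
  expect_equal(cmp$empirical_p, 1 / 200)
})

test_that("permutation re-fits match a from-scratch scalar CCA", {
  # one fixed permutation pushed through the fast path must equal the
  # full estimator applied to the permuted score
  co <- fixture_cohort()
  ai <- prepare_asymmetry_matrix(co)
  X <- ai$values[complete.cases(ai$values), ]
  sa <- co$score_asd[complete.cases(ai$values)]
  idx <- withr::with_seed(9, sample.int(nrow(X)))
  full <- scalar_cca(X, sa[idx])$loadings
  Xc <- scale(X, scale = FALSE)
  fast <- asymlink:::.perm_loadings(Xc, chol(crossprod(Xc) / (nrow(X) - 1)),
                                    apply(X, 2, sd), sa[idx])
  expect_equal(unname(full), unname(fast), tolerance = 1e-10)
})

test_that("comparison object reports loadings, concordance sets and plots", {
  co <- fixture_cohort_strong()
  ai <- prepare_asymmetry_matrix(co)
  cmp <- compare_loading_patterns(ai, co$score_asd, co$score_scz,
                                  n_perm = 100, seed = 3)
  expect_identical(cmp$n_permutations, 100L)
  expect_between(cmp$empirical_p, 1 / 101, 1)
  expect_identical(sort(unique(tidy(cmp)$concordance)),
                   sort(unique(c("concordant", "discordant", "neither")[
                     c(length(cmp$concordant) > 0, length(cmp$discordant) > 0, TRUE)])))
  expect_length(intersect(cmp$concordant, cmp$discordant), 0)
  expect_s3_class(autoplot(cmp), "ggplot")
  gl <- glance(cmp)
  expect_identical(gl$n_regions, 42L)
})
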