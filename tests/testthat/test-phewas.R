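test_that("variable classification follows the declared-type-first cascade", {
  expect_identical(classify_variable(c(0, 1, 0, 1)), "binary")
  expect_identical(classify_variable(rnorm(1000)), "continuous")
  expect_identical(classify_variable(c("A", "B", "C", "A")),
                   "unordered_categorical")
  expect_identical(classify_variable(rep(1:4, 10)), "ordered_categorical")
  expect_identical(classify_variable(rep(1:40, 10)), "continuous")
  expect_identical(classify_variable(rnorm(100), declared_type = "binary"),
                   "binary")
  expect_identical(classify_variable(ordered(rep(c("lo", "mid", "hi"), 5))),
                   "ordered_categorical")
  expect_error(classify_variable(rep(3, 10)), class = "asymlink_value_error")
})

test_that("each model type recovers a planted signal and reports sane nulls", {
  withr::with_seed(81, {
    n <- 3000
    score <- rnorm(n)
    design <- cbind(age = runif(n, 45, 81))
    cont <- score + rnorm(n)
    null_bin <- rbinom(n, 1, 0.5)
    ord <- findInterval(0.4 * score + rnorm(n), qnorm((1:3) / 4)) + 1L
  })
  r_cont <- test_phenotype(score, cont, "continuous", design)
  expect_gt(r_cont$estimate, 0)
  expect_lt(r_cont$p_value, 1e-10)
  r_null <- test_phenotype(score, null_bin, "binary", design)
  expect_gt(r_null$p_value, 1e-4)
  r_ord <- test_phenotype(score, ord, "ordered_categorical", design)
  expect_identical(r_ord$model, "ordered_logistic")
  expect_gt(r_ord$estimate, 0)
  expect_lt(r_ord$p_value, 1e-6)
})

test_that("multinomial phenotypes get a likelihood-ratio p for the score", {
  withr::with_seed(82, {
    n <- 2000
    score <- rnorm(n)
    eta <- cbind(0, 0, 0.5 * score)
    pr <- exp(eta) / rowSums(exp(eta))
    u <- runif(n)
    y <- c("a", "b", "c")[rowSums(u > t(apply(pr, 1, cumsum))) + 1L]
  })
  res <- test_phenotype(score, y, "unordered_categorical", NULL)
  expect_identical(res$model, "multinomial_logistic")
  expect_lt(res$p_value, 1e-6)
  expect_gt(abs(res$estimate), 0.2)
})

test_that("BH adjustment matches hand arithmetic and flags discoveries", {
  adj <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$p_adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(adj$discovery))
  expect_true(all(adj$p_adjusted >= adj$p_value))

  none <- bh_fdr(rep(1, 5))
  expect_false(any(none$discovery))
  single <- bh_fdr(0.04)
  expect_true(single$discovery)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "asymlink_value_error")
  expect_error(bh_fdr(c(0.5, NA)), class = "asymlink_value_error")
})

test_that("BH agrees with a brute-force step-up oracle", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  withr::with_seed(83, {
    for (i in 1:20) {
      p <- runif(sample(3:50, 1))
      expect_equal(bh_fdr(p)$p_adjusted, step_up(p), tolerance = 1e-12)
    }
  })
})

test_that("the scan plants effects where configured and excludes bookkeeping columns", {
  co <- fixture_cohort_strong()
  scan <- run_phewas(co, "score_scz")
  expect_s3_class(scan, "phewas_result")
  expect_false(any(grepl("^(left_|right_|score_|pc\\d)", scan$phenotype)))
  expect_false(any(c("handedness", "sex", "age", "brain_size") %in%
                     scan$phenotype))
  fi <- scan[scan$phenotype == "fluid_intelligence", ]
  expect_lt(fi$estimate, 0)
  expect_lt(fi$p_adjusted, 0.01)
  expect_true(all(scan$p_adjusted >= scan$p_value, na.rm = TRUE))
  expect_s3_class(autoplot(scan), "ggplot")
})

test_that("non-converging phenotypes are excluded from FDR with a reason", {
  co <- fixture_cohort()
  co$weird <- c("x", rep(NA, nrow(co) - 1))  # one distinct non-missing value
  cb <- dplyr::bind_rows(attr(co, "codebook"),
                         tibble::tibble(phenotype = "weird",
                                        type = NA_character_,
                                        levels = NA_integer_))
  scan <- run_phewas(co, "score_asd", phenotypes = c("null_continuous", "weird"))
  expect_identical(nrow(scan), 2L)
  weird <- scan[scan$phenotype == "weird", ]
  expect_false(weird$converged)
  expect_true(is.na(weird$p_adjusted))
  expect_true("weird" %in% attr(scan, "excluded")$phenotype)
  # m reflects only the tested phenotypes
  tested <- scan[scan$converged & !is.na(scan$p_value), ]
  expect_equal(tested$p_adjusted, tested$p_value, tolerance = 1e-12)  # m = 1
})

test_that("declared codebook types override classification", {
  co <- fixture_cohort()
  cb <- tibble::tibble(phenotype = "overall_health", type = "continuous",
                       levels = NA_integer_)
  scan <- run_phewas(co, "score_asd", phenotypes = "overall_health",
                     codebook = cb)
  expect_identical(scan$model, "linear")
})
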