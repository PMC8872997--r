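# vectorized two-sample t statistics of every column against a binary
# grouping; pooled variance by default (equivalent to the OLS slope t)
.col_ttests <- function(X, sex, var_equal = TRUE) {
  n1 <- sum(sex == 1)
  n0 <- sum(sex == 0)
  m1 <- drop(crossprod(sex, X)) / n1
  m0 <- drop(crossprod(1 - sex, X)) / n0
  ss <- colSums(X^2)
  if (var_equal) {
    sp2 <- (ss - n1 * m1^2 - n0 * m0^2) / (n1 + n0 - 2)
    t <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(X))
  } else {
    v1 <- (drop(crossprod(sex, X^2)) - n1 * m1^2) / (n1 - 1)
    v0 <- (drop(crossprod(1 - sex, X^2)) - n0 * m0^2) / (n0 - 1)
    se2 <- v1 / n1 + v0 / n0
    t <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t[!is.finite(t)] <- 0  # zero-variance columns: no difference detectable
  list(t = unname(t), df = unname(df))
}

#' Per-region sex-difference map on asymmetry indexes
#'
#' Two-sample t-test of every asymmetry index against sex, on indexes
#' residualized *without* sex. With the female = 1 coding a positive t
#' means an average leftward shift of asymmetry in females relative to
#' males. The pooled-variance statistic (equivalent to the regression
#' slope t of the index on sex) is the default; Welch's variant is
#' available.
#'
#' @param ai An `asym_matrix` preprocessed with `include_sex = FALSE` (or
#'   a numeric matrix).
#' @param sex Binary vector, female = 1, male = 0.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return An object of class `sex_map`: tibble with `region`, `t`,
#'   `p_value`, `n`.
#' @export
sex_ttests <- function(ai, sex, var_equal = TRUE) {
  X <- ai_matrix(ai)
  regions <- ai_regions(ai)
  if (inherits(ai, "asym_matrix") && isTRUE(ai$provenance$include_sex)) {
    warn("Asymmetry matrix was residualized including sex; the sex map should use include_sex = FALSE.")
  }
  keep <- complete.cases(X) & !is.na(sex)
  X <- X[keep, , drop = FALSE]
  sex <- as.numeric(sex[keep])
  if (sum(sex == 1) < 2 || sum(sex == 0) < 2) {
    abort("Each sex group needs at least 2 members.",
          class = "asymlink_value_error")
  }
  tt <- .col_ttests(X, sex, var_equal = var_equal)
  out <- tibble::tibble(
    region = regions,
    t = tt$t,
    p_value = 2 * stats::pt(-abs(tt$t), tt$df),
    n = nrow(X)
  )
  class(out) <- c("sex_map", class(out))
  out
}

#' Correlate a sex-difference map with a loading pattern
#'
#' Pearson correlation across regions between per-region sex-difference
#' t-values and a polygenic-score loading vector, with an empirical
#' p-value from a sex-shuffle permutation null: per permutation the sex
#' labels are shuffled across individuals, the full t-vector is
#' recomputed on the (fixed) sex-free asymmetry matrix, and its
#' correlation with the loading vector recorded. The loading vector is
#' held at its observed value by default, since the null randomizes sex,
#' not the score; `refit = "full"` additionally re-residualizes the
#' indexes on the permuted sex and re-fits the CCA inside each
#' permutation.
#'
#' @param sex_map A `sex_map` from [sex_ttests()] (the observed map).
#' @param loadings Named loading vector from a CCA in which sex *was* a
#'   covariate; region names and order must match the map.
#' @param ai_nosex `asym_matrix` residualized without sex.
#' @param sex Binary sex vector aligned to `ai_nosex` rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param sided Sidedness of the empirical p (default two-sided).
#' @param refit `"tmap_only"` (default) or `"full"`.
#' @param score Score vector, required for `refit = "full"`.
#' @param var_equal Passed to the t statistic.
#' @return An object of class `sex_comparison` with `observed_r`,
#'   `empirical_p`, `null_sample`, `n_permutations`, `refit`, `seed`.
#' @export
sex_pattern_correlation <- function(sex_map, loadings, ai_nosex, sex,
                                    n_perm = 10000L, seed = 1L,
                                    sided = c("two", "greater"),
                                    refit = c("tmap_only", "full"),
                                    score = NULL, var_equal = TRUE) {
  sided <- match.arg(sided)
  refit <- match.arg(refit)
  n_perm <- check_count(n_perm, "n_perm")
  if (!is.null(names(loadings)) &&
      !identical(names(loadings), sex_map$region)) {
    abort("Region ordering of `loadings` does not match the sex map.",
          class = "asymlink_value_error")
  }
  if (refit == "full" && is.null(score)) {
    abort("`score` is required for refit = \"full\".",
          class = "asymlink_value_error")
  }
  observed_r <- loading_correlation(sex_map$t, unname(loadings))

  X <- ai_matrix(ai_nosex)
  keep <- complete.cases(X) & !is.na(sex)
  X <- X[keep, , drop = FALSE]
  sexv <- as.numeric(sex[keep])
  scorev <- if (!is.null(score)) score[keep]
  null_sample <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sp <- sexv[sample.int(length(sexv))]
      tvec <- .col_ttests(X, sp, var_equal = var_equal)$t
      lvec <- if (refit == "full") {
        scalar_cca(residualize(X, cbind(sex = sp)), scorev)$loadings
      } else {
        unname(loadings)
      }
      cor(tvec, lvec)
    }, numeric(1))
  })
  structure(list(
    observed_r = observed_r,
    null_sample = null_sample,
    n_permutations = n_perm,
    empirical_p = empirical_pvalue(observed_r, null_sample, sided = sided),
    sided = sided, refit = refit, seed = seed,
    n = nrow(X), n_regions = ncol(X)
  ), class = "sex_comparison")
}

#' @export
print.sex_comparison <- function(x, ...) {
  cat(sprintf("<sex-map vs loadings> r = %.3f across %d regions, permuted p = %.3g (%d permutations, %s null)\n",
              x$observed_r, x$n_regions, x$empirical_p, x$n_permutations,
              x$refit))
  invisible(x)
}

#' @export
glance.sex_comparison <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r, empirical_p = x$empirical_p,
                 n_permutations = x$n_permutations, n = x$n,
                 n_regions = x$n_regions, refit = x$refit)
}

#' Sex-difference map plot
#'
#' @param object A `sex_map`.
#' @param ... Unused.
#' @return A ggplot object: per-region sex-difference t-values (positive
#'   = leftward shift in females).
#' @export
autoplot.sex_map <- function(object, ...) {
  d <- dplyr::mutate(object, region = stats::reorder(.data$region, .data$t))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$region,
                                  fill = .data$t > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "steelblue")) +
    ggplot2::labs(x = "sex-difference t (positive = leftward in females)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
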