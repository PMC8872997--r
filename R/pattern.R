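#' Correlation between two loading patterns
#'
#' Pearson correlation of two equal-length loading vectors across
#' regions, the similarity statistic for comparing the multivariate
#' association patterns of two risks.
#'
#' @param load_a,load_b Numeric vectors of equal length >= 3.
#' @return Pearson correlation.
#' @export
loading_correlation <- function(load_a, load_b) {
  if (length(load_a) != length(load_b) || length(load_a) < 3) {
    abort("Loading vectors must have equal length >= 3.",
          class = "asymlink_value_error")
  }
  if (sd(load_a) == 0 || sd(load_b) == 0) {
    abort("Loading vectors must not have zero variance.",
          class = "asymlink_value_error")
  }
  cor(load_a, load_b)
}

#' Empirical p-value from a permutation null sample
#'
#' Add-one (permutation-inclusive) empirical p-value:
#' `p = (1 + #extreme) / (1 + n_perm)`, where "extreme" compares absolute
#' values for the two-sided rule and signed values for `sided =
#' "greater"`. The add-one rule keeps p strictly positive.
#'
#' @param observed Observed statistic.
#' @param null_sample Numeric vector of permutation statistics.
#' @param sided `"two"` (default) or `"greater"`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_sample, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (!length(null_sample)) {
    abort("Empty null sample.", class = "asymlink_value_error")
  }
  extreme <- if (sided == "two") {
    sum(abs(null_sample) >= abs(observed))
  } else {
    sum(null_sample >= observed)
  }
  (1 + extreme) / (1 + length(null_sample))
}

#' Classify regions as loading-concordant or loading-discordant
#'
#' A region is concordant when both loadings exceed `threshold` or both
#' fall below `-threshold`; discordant when one exceeds `threshold` and
#' the other falls below `-threshold`. Regions with either |loading| at
#' or below the threshold belong to neither set.
#'
#' @param load_a,load_b Numeric loading vectors of equal length.
#' @param labels Region labels (defaults to names of `load_a`).
#' @param threshold Loading magnitude threshold (default 0.2).
#' @return List with character vectors `concordant` and `discordant`.
#' @export
classify_concordance <- function(load_a, load_b,
                                 labels = names(load_a), threshold = 0.2) {
  if (length(load_a) != length(load_b)) {
    abort("Loading vectors must have equal length.",
          class = "asymlink_value_error")
  }
  if (is.null(labels)) labels <- paste0("region_", seq_along(load_a))
  conc <- (load_a > threshold & load_b > threshold) |
    (load_a < -threshold & load_b < -threshold)
  disc <- (load_a > threshold & load_b < -threshold) |
    (load_a < -threshold & load_b > threshold)
  list(concordant = labels[conc], discordant = labels[disc])
}

# one full scalar-CCA loading extraction from precomputed pieces; used
# inside the permutation loop, mathematically identical to scalar_cca()
.perm_loadings <- function(Xc, chSxx, sdX, y) {
  Sxy <- crossprod(Xc, y - mean(y)) / (nrow(Xc) - 1)
  w0 <- backsolve(chSxx, forwardsolve(t(chSxx), Sxy))
  v <- drop(Xc %*% w0)
  # orientation cor(y, v) >= 0 holds automatically: cov(y, v) is the
  # quadratic form Sxy' Sxx^{-1} Sxy
  drop(crossprod(Xc, v)) / ((nrow(Xc) - 1) * sdX * sd(v))
}

#' Joint-shuffle permutation null for the loading-pattern correlation
#'
#' Builds the permutation null distribution of the correlation between
#' the two scores' loading vectors: in each permutation one shared row
#' shuffle is applied to the pair of scores jointly (preserving their
#' within-subject relation exactly) while the asymmetry matrix stays
#' fixed; both scalar CCAs are re-fit, both loading vectors re-extracted,
#' and their correlation recorded.
#'
#' @param ai `asym_matrix` or numeric matrix.
#' @param score_a,score_b Score vectors aligned to the rows of `ai`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed (the null sample is deterministic given it).
#' @return Numeric vector of `n_perm` null correlations.
#' @export
joint_permutation_null <- function(ai, score_a, score_b, n_perm = 10000L,
                                   seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100) {
    warn("Fewer than 100 permutations gives an unstable empirical p-value.")
  }
  X <- ai_matrix(ai)
  keep <- complete.cases(X) & !is.na(score_a) & !is.na(score_b)
  X <- X[keep, , drop = FALSE]
  sa <- score_a[keep]
  sb <- score_b[keep]
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sdX <- apply(X, 2, sd)
  chSxx <- chol(crossprod(Xc) / (n - 1))
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      la <- .perm_loadings(Xc, chSxx, sdX, sa[idx])
      lb <- .perm_loadings(Xc, chSxx, sdX, sb[idx])
      cor(la, lb)
    }, numeric(1))
  })
}

#' Compare the loading patterns of two polygenic scores
#'
#' Fits the scalar CCA of each score against the same asymmetry matrix,
#' correlates the two loading vectors across regions, attaches an
#' empirical p-value from the joint-shuffle permutation null, and
#' classifies concordant and discordant regions at the loading
#' threshold.
#'
#' @inheritParams joint_permutation_null
#' @param threshold Concordance loading threshold (default 0.2).
#' @param sided Sidedness of the empirical p-value (default two-sided).
#' @return An object of class `loading_comparison` with `observed_r`,
#'   `null_sample`, `n_permutations`, `empirical_p`, `concordant`,
#'   `discordant`, per-region `loadings` tibble, the two `scca` fits,
#'   and `seed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 400, seed = 2))
#' ai <- prepare_asymmetry_matrix(cohort)
#' cmp <- compare_loading_patterns(ai, cohort$score_asd, cohort$score_scz,
#'                                 n_perm = 200, seed = 9)
#' glance(cmp)
compare_loading_patterns <- function(ai, score_a, score_b,
                                     n_perm = 10000L, seed = 1L,
                                     threshold = 0.2,
                                     sided = c("two", "greater")) {
  sided <- match.arg(sided)
  n_perm <- check_count(n_perm, "n_perm")
  fit_a <- scalar_cca(ai, score_a)
  fit_b <- scalar_cca(ai, score_b)
  observed_r <- loading_correlation(fit_a$loadings, fit_b$loadings)
  null_sample <- joint_permutation_null(ai, score_a, score_b,
                                        n_perm = n_perm, seed = seed)
  conc <- classify_concordance(fit_a$loadings, fit_b$loadings,
                               labels = names(fit_a$loadings),
                               threshold = threshold)
  structure(list(
    observed_r = observed_r,
    null_sample = null_sample,
    n_permutations = n_perm,
    empirical_p = empirical_pvalue(observed_r, null_sample, sided = sided),
    sided = sided,
    threshold = threshold,
    concordant = conc$concordant,
    discordant = conc$discordant,
    loadings = tibble::tibble(
      region = names(fit_a$loadings),
      loading_a = unname(fit_a$loadings),
      loading_b = unname(fit_b$loadings)
    ),
    fit_a = fit_a, fit_b = fit_b,
    seed = seed
  ), class = "loading_comparison")
}

#' @export
print.loading_comparison <- function(x, ...) {
  cat(sprintf("<loading comparison> r = %.3f across %d regions, permuted p = %.3g (%d permutations)\n",
              x$observed_r, nrow(x$loadings), x$empirical_p, x$n_permutations))
  cat(sprintf("  concordant: %s\n  discordant: %s\n",
              if (length(x$concordant)) paste(x$concordant, collapse = ", ") else "none",
              if (length(x$discordant)) paste(x$discordant, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
tidy.loading_comparison <- function(x, ...) {
  x$loadings |>
    dplyr::mutate(
      concordance = dplyr::case_when(
        .data$region %in% x$concordant ~ "concordant",
        .data$region %in% x$discordant ~ "discordant",
        TRUE ~ "neither"
      )
    )
}

#' @export
glance.loading_comparison <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r, empirical_p = x$empirical_p,
                 n_permutations = x$n_permutations,
                 n_regions = nrow(x$loadings),
                 n_concordant = length(x$concordant),
                 n_discordant = length(x$discordant))
}

#' Permutation-null histogram for a loading comparison
#'
#' @param object A `loading_comparison`.
#' @param ... Unused.
#' @return A ggplot object: the null distribution of the loading-vector
#'   correlation with the observed value marked.
#' @export
autoplot.loading_comparison <- function(object, ...) {
  d <- tibble::tibble(null_r = object$null_sample)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_r, colour = "firebrick") +
    ggplot2::labs(x = "null loading-pattern correlation", y = "permutations",
                  title = sprintf("observed r = %.3f, empirical p = %.3g",
                                  object$observed_r, object$empirical_p)) +
    ggplot2::theme_minimal()
}
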