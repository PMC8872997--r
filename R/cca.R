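#' Scalar-target canonical correlation analysis
#'
#' Finds the linear combination of asymmetry indexes (the canonical
#' asymmetry index) maximally correlated with a single standardized
#' polygenic score. With a scalar target there is exactly one canonical
#' pair and the canonical correlation equals the multiple correlation of
#' the score on the index matrix; the implementation solves the
#' covariance system `Sxx w = Sxy` directly. The canonical variate is
#' scaled to unit sample variance and oriented so its correlation with
#' the score is non-negative, which makes a positive loading an
#' asymmetry shift toward the left with increasing risk. Loadings are the
#' correlations between each index and the canonical variate; the
#' parametric p-value comes from the exact F test of the equivalent
#' multiple regression.
#'
#' @param ai An `asym_matrix` (or plain numeric matrix) of asymmetry
#'   indexes.
#' @param score Numeric score vector aligned to the rows of `ai`.
#' @return An object of class `scca` with elements `canonical_r`,
#'   `weights` (unit-variance-variate scale), `weights_std` (per SD of
#'   each index), `loadings`, `p_value`, `f_statistic`, `df1`, `df2`,
#'   `n`, `n_regions`, `sign_anchor`.
#' @seealso [cca_pvalue()], [tidy.scca()], [glance.scca()]
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 400, seed = 5))
#' ai <- prepare_asymmetry_matrix(cohort)
#' fit <- scalar_cca(ai, cohort$score_asd)
#' glance(fit)
scalar_cca <- function(ai, score) {
  X <- ai_matrix(ai)
  regions <- ai_regions(ai)
  if (length(score) != nrow(X)) {
    abort("`score` must align with the rows of `ai`.",
          class = "asymlink_value_error")
  }
  keep <- complete.cases(X) & !is.na(score)
  X <- X[keep, , drop = FALSE]
  y <- score[keep]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) {
    abort(sprintf("Need n > p + 1 complete cases (n = %d, p = %d).", n, p),
          class = "asymlink_value_error")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  if (qr(Xc)$rank < p) {
    abort("Asymmetry matrix is rank-deficient (collinear columns).",
          class = "asymlink_value_error")
  }
  Sxx <- crossprod(Xc) / (n - 1)
  Sxy <- crossprod(Xc, yc) / (n - 1)
  ch <- chol(Sxx)
  w0 <- backsolve(ch, forwardsolve(t(ch), Sxy))
  r2 <- drop(crossprod(Sxy, w0)) / var(y)
  r <- sqrt(max(0, min(1, r2)))
  variate <- drop(Xc %*% w0)
  sv <- sd(variate)
  w <- drop(w0) / sv
  variate <- variate / sv
  # with w ~ Sxx^{-1} Sxy the score-variate covariance is a quadratic form,
  # hence already non-negative; the explicit flip guards degenerate input
  if (stats::cov(y, variate) < 0) {
    w <- -w
    variate <- -variate
  }
  loadings <- as.numeric(cor(Xc, variate))
  pv <- cca_pvalue(r, n, p)
  structure(list(
    canonical_r = r,
    weights = setNames(w, regions),
    weights_std = setNames(w * apply(X, 2, sd), regions),
    loadings = setNames(loadings, regions),
    p_value = pv,
    f_statistic = attr(pv, "statistic"),
    df1 = p, df2 = n - p - 1,
    n = n, n_regions = p,
    sign_anchor = "variate oriented so cor(score, variate) >= 0",
    measure_class = if (inherits(ai, "asym_matrix")) ai$regions$measure_class
  ), class = "scca")
}

#' Parametric p-value for a scalar canonical correlation
#'
#' Because the scalar-target canonical correlation is the multiple
#' correlation of the score on the index matrix, its null distribution is
#' governed by the exact F statistic
#' `F = (r^2 / (1 - r^2)) * ((n - p - 1) / p)` on `(p, n - p - 1)`
#' degrees of freedom. Bartlett's chi-squared approximation
#' `-(n - 1 - (p + 2) / 2) * log(1 - r^2)` on `p` degrees of freedom is
#' available as a cross-check.
#'
#' @param r Canonical correlation in [0, 1].
#' @param n Sample size (`n > p + 1`).
#' @param p Number of index columns.
#' @param method `"f"` (exact, default) or `"bartlett"`.
#' @return Upper-tail p-value, with the test statistic as attribute
#'   `statistic`.
#' @export
cca_pvalue <- function(r, n, p, method = c("f", "bartlett")) {
  method <- match.arg(method)
  check_number(r, "r", 0, 1)
  n <- check_count(n, "n", min = 3L)
  p <- check_count(p, "p", min = 1L)
  if (n <= p + 1) {
    abort("Need n > p + 1.", class = "asymlink_value_error")
  }
  if (r == 1) {
    warn("Canonical correlation is exactly 1; p-value is 0.")
    return(structure(0, statistic = Inf))
  }
  if (method == "f") {
    stat <- (r^2 / (1 - r^2)) * ((n - p - 1) / p)
    structure(pf(stat, p, n - p - 1, lower.tail = FALSE), statistic = stat)
  } else {
    stat <- -(n - 1 - (p + 2) / 2) * log(1 - r^2)
    structure(pchisq(stat, p, lower.tail = FALSE), statistic = stat)
  }
}

#' Post hoc univariate score-measure correlations
#'
#' Pearson correlation of the score with each column (typically the
#' separate residualized left and right unilateral measures), one
#' `(r, p)` pair per column.
#'
#' @param score Numeric score vector.
#' @param measures Numeric matrix or data frame of columns to correlate.
#' @return Tibble with `measure`, `r`, `p_value`, `n`.
#' @export
univariate_associations <- function(score, measures) {
  M <- as.matrix(measures)
  nm <- colnames(M) %||% paste0("m", seq_len(ncol(M)))
  purrr::map_dfr(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    obs <- !is.na(x) & !is.na(score)
    if (sum(obs) < 3 || sd(x[obs]) == 0) {
      warn(sprintf("Column '%s' is constant or too short; result is missing.",
                   nm[j]))
      return(tibble::tibble(measure = nm[j], r = NA_real_,
                            p_value = NA_real_, n = sum(obs)))
    }
    ct <- cor.test(score[obs], x[obs], method = "pearson")
    tibble::tibble(measure = nm[j], r = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(obs))
  })
}

#' @export
print.scca <- function(x, ...) {
  cat(sprintf("<scalar CCA> canonical r = %.4f, p = %.3g (F[%d, %d] = %.3f), n = %d\n",
              x$canonical_r, x$p_value, x$df1, x$df2, x$f_statistic, x$n))
  top <- sort(abs(x$loadings), decreasing = TRUE)[1:min(3, length(x$loadings))]
  cat("  strongest loadings:",
      paste(sprintf("%s (%.2f)", names(top), x$loadings[names(top)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-region output of a scalar CCA
#'
#' @param x An `scca` object.
#' @param ... Unused.
#' @return Tibble with `region`, `measure_class`, `weight`, `weight_std`,
#'   `loading`.
#' @export
tidy.scca <- function(x, ...) {
  tibble::tibble(
    region = names(x$loadings),
    measure_class = x$measure_class %||% NA_character_,
    weight = unname(x$weights),
    weight_std = unname(x$weights_std),
    loading = unname(x$loadings)
  )
}

#' One-row model summary of a scalar CCA
#'
#' @param x An `scca` object.
#' @param ... Unused.
#' @return One-row tibble with `canonical_r`, `p_value`, `f_statistic`,
#'   `df1`, `df2`, `n`, `n_regions`.
#' @export
glance.scca <- function(x, ...) {
  tibble::tibble(canonical_r = x$canonical_r, p_value = x$p_value,
                 f_statistic = x$f_statistic, df1 = x$df1, df2 = x$df2,
                 n = x$n, n_regions = x$n_regions)
}

#' Loading map for a scalar CCA
#'
#' Horizontal bar chart of per-region loadings, coloured by measure
#' class; positive loadings indicate a leftward asymmetry shift with
#' increasing score.
#'
#' @param object An `scca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scca <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(region = stats::reorder(.data$region, .data$loading))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$loading, y = .data$region,
                                  fill = .data$measure_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "loading (cor with canonical variate)", y = NULL,
                  fill = "measure",
                  title = sprintf("canonical r = %.3f (p = %.2g, n = %d)",
                                  object$canonical_r, object$p_value,
                                  object$n)) +
    ggplot2::theme_minimal()
}
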