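#' Logistic-regression contrasts of handedness on polygenic scores
#'
#' Fits, for each score, three logistic regressions with right-handedness
#' as the reference outcome: left vs right, mixed vs right, and non-right
#' (left plus mixed) vs right, each adjusted for the standard covariate
#' design. Six models in the two-score configuration. The reported
#' coefficient is the log-odds change per SD of the score. Values of the
#' handedness column other than `"right"`, `"left"`, `"mixed"` (for
#' example "prefer not to answer") are treated as missing.
#'
#' @param cohort Cohort tibble with a `handedness` column.
#' @param score_cols Character vector of score column names.
#' @param covariates,include_sex,extra_covariates Passed to
#'   [build_covariate_matrix()].
#' @param max_iter,tol Convergence controls of the iteratively reweighted
#'   least squares fit.
#' @return An object of class `handedness_result`: tibble with one row
#'   per contrast x score (`contrast`, `score`, `estimate`, `std_error`,
#'   `p_value`, `n_cases`, `n_controls`, `converged`, `separation`).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 2000, seed = 4))
#' fit_handedness_models(cohort)
fit_handedness_models <- function(cohort,
                                  score_cols = c("score_asd", "score_scz"),
                                  covariates = NULL,
                                  include_sex = TRUE,
                                  extra_covariates = NULL,
                                  max_iter = 100L, tol = 1e-8) {
  if (!"handedness" %in% names(cohort)) {
    abort("Cohort has no `handedness` column.", class = "asymlink_value_error")
  }
  hand <- as.character(cohort$handedness)
  hand[!hand %in% c("right", "left", "mixed")] <- NA
  design <- build_covariate_matrix(cohort,
                                   covariates = covariates,
                                   include_sex = include_sex,
                                   extra_covariates = extra_covariates)
  contrasts <- list(
    left_vs_right = "left",
    mixed_vs_right = "mixed",
    nonright_vs_right = c("left", "mixed")
  )
  rows <- purrr::imap(contrasts, function(cases, cname) {
    purrr::map(score_cols, function(sc) {
      score <- cohort[[sc]]
      if (is.null(score)) {
        abort(sprintf("Score column '%s' not found.", sc),
              class = "asymlink_value_error")
      }
      in_model <- hand %in% c(cases, "right") & !is.na(score)
      y <- as.integer(hand[in_model] %in% cases)
      if (sum(y) == 0 || sum(1 - y) == 0) {
        abort(sprintf("Empty group in contrast '%s'.", cname),
              class = "asymlink_value_error")
      }
      x <- score[in_model]
      if (sd(x) == 0) {
        abort(sprintf("Score '%s' is constant in contrast '%s'; coefficient undefined.",
                      sc, cname),
              class = "asymlink_value_error")
      }
      df <- data.frame(y = y, score = x, design[in_model, , drop = FALSE],
                       check.names = FALSE)
      fit <- suppressWarnings(
        glm(y ~ ., data = df, family = binomial(),
            control = list(maxit = max_iter, epsilon = tol))
      )
      sm <- summary(fit)$coefficients
      mu <- fit$fitted.values
      tibble::tibble(
        contrast = cname, score = sc,
        estimate = sm["score", "Estimate"],
        std_error = sm["score", "Std. Error"],
        p_value = sm["score", "Pr(>|z|)"],
        n_cases = sum(y), n_controls = sum(1 - y),
        converged = fit$converged,
        separation = any(mu < 1e-8 | mu > 1 - 1e-8)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("handedness_result", class(out))
  out
}

#' @export
glance.handedness_result <- function(x, ...) {
  tibble::tibble(n_models = nrow(x),
                 n_converged = sum(x$converged),
                 any_separation = any(x$separation))
}

#' Handedness contrast forest plot
#'
#' @param object A `handedness_result`.
#' @param ... Unused.
#' @return A ggplot object of the score log-odds with 95% Wald intervals.
#' @export
autoplot.handedness_result <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     lo = .data$estimate - 1.96 * .data$std_error,
                     hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$contrast,
                                  colour = .data$score)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15,
                            position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log-odds per SD of score", y = NULL) +
    ggplot2::theme_minimal()
}
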