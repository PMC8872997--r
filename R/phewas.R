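#' Classify a phenotype column into a model type
#'
#' A declared type always wins. Otherwise: two distinct non-missing
#' values are binary; non-numeric codes are unordered categorical
#' (ordered factors stay ordered); integer-coded columns with at most
#' `k_max` distinct levels are treated as ordered categorical; anything
#' else is continuous.
#'
#' @param x Phenotype column.
#' @param declared_type Optional declared type, one of `"continuous"`,
#'   `"binary"`, `"ordered_categorical"`, `"unordered_categorical"`.
#' @param k_max Maximum number of integer levels read as ordered.
#' @return The type string.
#' @export
classify_variable <- function(x, declared_type = NULL, k_max = 10L) {
  types <- c("continuous", "binary", "ordered_categorical",
             "unordered_categorical")
  if (!is.null(declared_type) && !is.na(declared_type)) {
    return(match.arg(declared_type, types))
  }
  vals <- unique(x[!is.na(x)])
  if (length(vals) < 2) {
    abort("Phenotype has a single distinct value; excluded.",
          class = "asymlink_value_error")
  }
  if (length(vals) == 2) return("binary")
  if (is.ordered(x)) return("ordered_categorical")
  if (!is.numeric(x)) return("unordered_categorical")
  if (all(vals == round(vals)) && length(vals) <= k_max) {
    return("ordered_categorical")
  }
  "continuous"
}

#' Test one phenotype against a polygenic score
#'
#' Dispatches on the variable type: continuous phenotypes are
#' inverse-normal transformed and fit with a linear model; binary with
#' logistic regression; ordered categorical with a proportional-odds
#' model; unordered categorical with baseline-category (multinomial)
#' logistic regression and an overall likelihood-ratio p-value for the
#' score. All models include the supplied covariate design. For the
#' multinomial model the reported effect is the largest-magnitude
#' per-level score coefficient.
#'
#' @param score Numeric score vector.
#' @param phenotype Phenotype column.
#' @param type Variable type (see [classify_variable()]).
#' @param design Numeric covariate matrix (may be `NULL`).
#' @param int_offset Inverse-normal offset for continuous phenotypes.
#' @return Tibble row: `type`, `model`, `estimate`, `p_value`, `n`,
#'   `converged`, `reason`.
#' @export
test_phenotype <- function(score, phenotype, type, design = NULL,
                           int_offset = "blom") {
  obs <- !is.na(score) & !is.na(phenotype)
  if (!is.null(design)) obs <- obs & complete.cases(design)
  y <- phenotype[obs]
  s <- score[obs]
  D <- if (!is.null(design)) design[obs, , drop = FALSE]
  n <- sum(obs)
  fail <- function(model, reason) {
    tibble::tibble(type = type, model = model, estimate = NA_real_,
                   p_value = NA_real_, n = n, converged = FALSE,
                   reason = reason)
  }
  ok <- function(model, estimate, p) {
    tibble::tibble(type = type, model = model, estimate = estimate,
                   p_value = p, n = n, converged = TRUE, reason = NA_character_)
  }
  df <- data.frame(score = s, check.names = FALSE)
  if (!is.null(D)) df <- cbind(df, as.data.frame(D))
  tryCatch(switch(type,
    continuous = {
      yt <- inverse_normal_transform(as.numeric(y), offset = int_offset)
      fit <- lm(yt ~ ., data = cbind(data.frame(yt = yt), df))
      sm <- summary(fit)$coefficients
      ok("linear", sm["score", "Estimate"], sm["score", "Pr(>|t|)"])
    },
    binary = {
      yb <- as.integer(factor(y)) - 1L
      fit <- suppressWarnings(glm(yb ~ ., data = cbind(data.frame(yb = yb), df),
                                  family = binomial()))
      if (!fit$converged) return(fail("logistic", "non-convergence"))
      sm <- summary(fit)$coefficients
      ok("logistic", sm["score", "Estimate"], sm["score", "Pr(>|z|)"])
    },
    ordered_categorical = {
      yf <- if (is.ordered(y)) y else factor(y, ordered = TRUE)
      if (nlevels(droplevels(yf)) < 3) {
        # two observed levels degrade to the binary model
        yb <- as.integer(droplevels(yf)) - 1L
        fit <- suppressWarnings(glm(yb ~ ., data = cbind(data.frame(yb = yb), df),
                                    family = binomial()))
        sm <- summary(fit)$coefficients
        return(ok("logistic", sm["score", "Estimate"], sm["score", "Pr(>|z|)"]))
      }
      dat <- cbind(data.frame(yf = droplevels(yf)), df)
      fit <- suppressWarnings(MASS::polr(yf ~ ., data = dat, Hess = TRUE))
      sm <- summary(fit)$coefficients
      z <- sm["score", "t value"]
      ok("ordered_logistic", sm["score", "Value"], 2 * pnorm(-abs(z)))
    },
    unordered_categorical = {
      yf <- droplevels(factor(y))
      dat <- cbind(data.frame(yf = yf), df)
      fit1 <- nnet::multinom(yf ~ ., data = dat, trace = FALSE, maxit = 200)
      fit0 <- nnet::multinom(yf ~ . - score, data = dat, trace = FALSE,
                             maxit = 200)
      lr <- fit0$deviance - fit1$deviance
      dfree <- nlevels(yf) - 1L
      cf <- coef(fit1)
      sc <- if (is.matrix(cf)) cf[, "score"] else cf["score"]
      ok("multinomial_logistic", sc[which.max(abs(sc))],
         pchisq(lr, dfree, lower.tail = FALSE))
    },
    fail(NA_character_, sprintf("unknown type '%s'", type))
  ), error = function(e) fail(type, conditionMessage(e)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity; a phenotype is a
#' discovery when its adjusted p is at or below `q`.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q FDR threshold (default 0.05).
#' @return Tibble with `p_value`, `p_adjusted`, `discovery`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  check_number(q, "q", 0, 1)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.",
          class = "asymlink_value_error")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 discovery = adj <= q)
}

#' Type-driven phenome-wide association scan
#'
#' Screens one polygenic score against many phenotype columns: each
#' column is classified (or takes its declared codebook type), tested
#' with the type-appropriate regression adjusted for the standard
#' covariates, and the converged tests are jointly FDR-adjusted with the
#' Benjamini-Hochberg procedure at threshold `q` (run the function once
#' per score, so adjustment is per score). Columns used to build the
#' asymmetry indexes, covariates, identifiers, sex, the scores and
#' handedness are excluded by default, as are phenotypes that fail to
#' converge (with the reason recorded).
#'
#' @param cohort Cohort tibble.
#' @param score_col Name of the score column to screen.
#' @param phenotypes Character vector of phenotype columns. Defaults to
#'   the cohort's codebook attribute, or to every column not excluded.
#' @param codebook Optional tibble with columns `phenotype` and `type`
#'   declaring types (overrides classification).
#' @param covariates,include_sex Passed to [build_covariate_matrix()].
#' @param q FDR threshold (default 0.05).
#' @param k_max Passed to [classify_variable()].
#' @param exclude Additional column names to exclude.
#' @return An object of class `phewas_result`: tibble with one row per
#'   phenotype (`phenotype`, `type`, `model`, `estimate`, `p_value`,
#'   `p_adjusted`, `discovery`, `n`, `converged`, `reason`), with the
#'   exclusion log as attribute `excluded`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 1500, seed = 11))
#' scan <- run_phewas(cohort, "score_scz")
#' dplyr::arrange(scan, p_value)
run_phewas <- function(cohort, score_col,
                       phenotypes = NULL, codebook = NULL,
                       covariates = NULL, include_sex = TRUE,
                       q = 0.05, k_max = 10L, exclude = NULL) {
  if (!score_col %in% names(cohort)) {
    abort(sprintf("Score column '%s' not found.", score_col),
          class = "asymlink_value_error")
  }
  if (is.null(codebook)) codebook <- attr(cohort, "codebook")
  if (is.null(covariates)) covariates <- default_covariate_names(cohort)
  design <- build_covariate_matrix(cohort, covariates,
                                   include_sex = include_sex)
  auto_exclude <- c("id", "sex", "handedness", "brain_size",
                    grep("^(left_|right_|score_)", names(cohort), value = TRUE),
                    covariates, colnames(design), exclude)
  if (is.null(phenotypes)) {
    phenotypes <- if (!is.null(codebook)) {
      intersect(codebook$phenotype, names(cohort))
    } else {
      setdiff(names(cohort), auto_exclude)
    }
  }
  phenotypes <- setdiff(phenotypes, auto_exclude)
  score <- cohort[[score_col]]

  rows <- purrr::map(phenotypes, function(ph) {
    declared <- if (!is.null(codebook) && ph %in% codebook$phenotype) {
      codebook$type[match(ph, codebook$phenotype)]
    }
    type <- tryCatch(classify_variable(cohort[[ph]], declared, k_max = k_max),
                     error = function(e) NA_character_)
    if (is.na(type)) {
      return(tibble::tibble(phenotype = ph, type = NA_character_,
                            model = NA_character_, estimate = NA_real_,
                            p_value = NA_real_, n = 0L, converged = FALSE,
                            reason = "single distinct value"))
    }
    res <- test_phenotype(score, cohort[[ph]], type, design)
    dplyr::bind_cols(tibble::tibble(phenotype = ph), res)
  })
  out <- dplyr::bind_rows(rows)

  tested <- out$converged & !is.na(out$p_value)
  out$p_adjusted <- NA_real_
  out$discovery <- NA
  if (any(tested)) {
    adj <- bh_fdr(out$p_value[tested], q = q)
    out$p_adjusted[tested] <- adj$p_adjusted
    out$discovery[tested] <- adj$discovery
  }
  attr(out, "excluded") <- tibble::tibble(
    phenotype = out$phenotype[!tested],
    reason = out$reason[!tested]
  )
  attr(out, "q") <- q
  attr(out, "score") <- score_col
  class(out) <- c("phewas_result", class(out))
  out
}

#' @export
glance.phewas_result <- function(x, ...) {
  tibble::tibble(score = attr(x, "score") %||% NA_character_,
                 n_phenotypes = nrow(x),
                 n_tested = sum(x$converged & !is.na(x$p_value)),
                 n_discoveries = sum(x$discovery, na.rm = TRUE),
                 q = attr(x, "q") %||% NA_real_)
}

#' Phenome-wide scan plot
#'
#' @param object A `phewas_result`.
#' @param ... Unused.
#' @return A ggplot object: -log10 p by phenotype, coloured by variable
#'   type, with discoveries marked.
#' @export
autoplot.phewas_result <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotype,
                                  y = -log10(.data$p_value),
                                  colour = .data$type,
                                  shape = .data$discovery)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  colour = "type", shape = "FDR discovery") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
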