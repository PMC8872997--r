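#' Calibrate planted signal coefficients for target canonical correlations
#'
#' With latent asymmetries `x = aA * uA * sA + aB * uB * sB + e`,
#' `e ~ N(0, I)`, the scalar canonical correlation between score `sA` and
#' `x` equals the multiple correlation of `sA` on `x`. This function finds
#' coefficients `(aA, aB)` so that both multiple correlations hit their
#' targets, accounting for the correlation between the scores and for any
#' overlap of the two patterns. For orthogonal patterns and uncorrelated
#' scores the solution is the closed form `a = r / sqrt(1 - r^2)`; the
#' general case is solved numerically from that start.
#'
#' @param r_a,r_b Target canonical correlations in [0, 1).
#' @param rho Correlation between the two scores.
#' @param pattern_dot Inner product of the two unit patterns.
#' @return Numeric length-2 vector of signal coefficients.
#' @keywords internal
calibrate_planted_alphas <- function(r_a, r_b, rho, pattern_dot = 0) {
  if (r_a == 0 && r_b == 0) return(c(0, 0))
  S <- matrix(c(1, rho, rho, 1), 2)
  C <- matrix(c(1, pattern_dot, pattern_dot, 1), 2)
  mult_corr <- function(alpha) {
    D <- diag(alpha, nrow = 2)
    K <- D %*% S %*% D
    # U' (I + U K U')^{-1} U = C - C K (I + C K)^{-1} C
    G <- C - C %*% K %*% solve(diag(2) + C %*% K) %*% C
    M <- S %*% D %*% G %*% D %*% S
    sqrt(pmax(0, diag(M)))
  }
  target <- c(r_a, r_b)
  start <- target / sqrt(1 - target^2)
  obj <- function(alpha) sum((mult_corr(abs(alpha)) - target)^2)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 10000))
  alpha <- abs(fit$par)
  err <- max(abs(mult_corr(alpha) - target))
  if (err > 1e-6) {
    abort(sprintf(paste0("Planted canonical correlations are infeasible for ",
                         "this score correlation / pattern overlap ",
                         "(residual %.2g)."), err),
          class = "asymlink_parameter_error")
  }
  alpha
}

#' Simulate polygenic scores and sex
#'
#' Draws the two scores from a bivariate normal with the configured
#' correlation, shifts both upward in females by `score_sex_shift`
#' standard deviations, and z-scales each within the cohort.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sex` (female = 1, male = 0), `score_asd`,
#'   `score_scz`.
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  rho <- config$score_correlation
  sex <- rbinom(n, 1L, config$p_female)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  shift <- config$score_sex_shift * sex
  tibble::tibble(
    sex = sex,
    score_asd = zscore(z1 + shift),
    score_scz = zscore(z2 + shift)
  )
}

simulate_covariate_columns <- function(config, n) {
  cols <- list()
  for (cv in config$covariate_spec) {
    cols[[cv$name]] <- switch(cv$type,
      continuous = if (cv$name == "age") runif(n, 45, 81) else rnorm(n),
      categorical = {
        lev <- paste0(cv$name, "_", seq_len(cv$levels))
        factor(sample(lev, n, replace = TRUE), levels = lev)
      },
      abort(sprintf("Unknown covariate type '%s'.", cv$type),
            class = "asymlink_parameter_error")
    )
  }
  tibble::as_tibble(cols)
}

# standardized numeric contribution of the covariates to the latent AIs
covariate_effect_matrix <- function(config, covs) {
  n <- nrow(covs)
  p <- config$n_regions
  eff <- matrix(0, n, p)
  for (cv in config$covariate_spec) {
    x <- covs[[cv$name]]
    if (cv$type == "continuous") {
      if (any(cv$effect != 0)) eff <- eff + outer(zscore(x), cv$effect)
    } else {
      em <- cv$effect
      if (any(em != 0)) eff <- eff + em[as.integer(x), , drop = FALSE]
    }
  }
  eff
}

#' Simulate paired left/right regional measures
#'
#' Latent asymmetries are built from the planted score patterns, the sex
#' pattern, covariate effects and unit Gaussian noise, scaled to
#' `ai_scale` and shifted by the per-region baseline means. A log-normal
#' bilateral size `s` is drawn per cell and inverted through
#' `left = s (1 + a/2)`, `right = s (1 - a/2)`, so the asymmetry-index
#' formula recovers the latent `a` exactly. Latent values implying a
#' non-positive side (|a| >= 2) are clipped with a warning and counted.
#' With positive `outlier_rate`, unilateral measures are replaced by
#' extreme values 7--10 SDs from their column mean to exercise outlier
#' removal downstream.
#'
#' @param config A [sim_config()].
#' @param scores Tibble from [simulate_scores()].
#' @param covariates Tibble from the covariate roster (may be `NULL` for
#'   none).
#' @return Tibble of `left_*`/`right_*` columns plus `brain_size`, with
#'   attributes `latent_ai` (matrix), `n_clipped`, and `outlier_cells`
#'   (tibble of injected outlier positions).
#' @export
simulate_regional_measures <- function(config, scores, covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  p <- config$n_regions
  uA <- config$loading_pattern_a
  uB <- config$loading_pattern_b
  alpha <- calibrate_planted_alphas(config$canonical_r_a, config$canonical_r_b,
                                    config$score_correlation,
                                    sum(uA * uB))
  z <- outer(scores$score_asd, alpha[1] * uA) +
    outer(scores$score_scz, alpha[2] * uB) +
    outer(scores$sex, config$sex_pattern) +
    matrix(rnorm(n * p), n, p)
  if (!is.null(covariates)) {
    z <- z + covariate_effect_matrix(config, covariates)
  }
  a <- sweep(config$ai_scale * z, 2, config$ai_mean, "+")

  lim <- 2 - 1e-8
  n_clipped <- sum(abs(a) >= lim)
  if (n_clipped > 0) {
    warn(sprintf("%d latent asymmetry value(s) implied a non-positive side and were clipped to |a| < 2.",
                 n_clipped))
    a <- pmin(pmax(a, -lim), lim)
  }

  meanlog <- c(area = log(2500), thickness = log(2.5), volume = log(4000))
  ml <- meanlog[config$region_classes]
  s <- exp(matrix(rnorm(n * p, mean = rep(ml, each = n), sd = config$size_sdlog),
                  n, p))
  left <- s * (1 + a / 2)
  right <- s * (1 - a / 2)
  colnames(left) <- paste0("left_", config$region_labels)
  colnames(right) <- paste0("right_", config$region_labels)

  meas <- cbind(left, right)
  outlier_cells <- tibble::tibble(column = character(), row = integer())
  if (config$outlier_rate > 0) {
    mu <- colMeans(meas)
    sdev <- apply(meas, 2, sd)
    hits <- which(matrix(runif(length(meas)) < config$outlier_rate,
                         nrow = n))
    if (length(hits)) {
      cidx <- (hits - 1L) %/% n + 1L
      ridx <- (hits - 1L) %% n + 1L
      mag <- runif(length(hits), 7, 10)
      sgn <- sample(c(-1, 1), length(hits), replace = TRUE)
      meas[hits] <- mu[cidx] + sgn * mag * sdev[cidx]
      outlier_cells <- tibble::tibble(column = colnames(meas)[cidx],
                                      row = ridx)
    }
  }
  if (config$missing_rate > 0) {
    meas[matrix(runif(length(meas)) < config$missing_rate, nrow = n)] <- NA
  }

  bs_eta <- log(1.2e6) +
    config$brain_size_betas[1] * scores$score_asd +
    config$brain_size_betas[2] * scores$score_scz +
    0.05 * rnorm(n)
  out <- tibble::as_tibble(as.data.frame(meas))
  out$brain_size <- exp(bs_eta)
  attr(out, "latent_ai") <- a
  attr(out, "n_clipped") <- n_clipped
  attr(out, "outlier_cells") <- outlier_cells
  out
}

#' Simulate handedness categories
#'
#' Samples handedness from a baseline-category logistic model with
#' right-handedness as the reference: intercepts reproduce the configured
#' base rates and each score contributes the configured log-odds to the
#' left-vs-right and mixed-vs-right categories.
#'
#' @param config A [sim_config()].
#' @param scores Tibble from [simulate_scores()].
#' @return Character vector of `"right"`, `"left"`, `"mixed"`.
#' @export
simulate_handedness <- function(config, scores) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$handedness_base_rates
  b <- config$handedness_betas
  n <- config$n_individuals
  eta_left <- log(rates["left"] / rates["right"]) +
    b["asd", "left"] * scores$score_asd + b["scz", "left"] * scores$score_scz
  eta_mixed <- log(rates["mixed"] / rates["right"]) +
    b["asd", "mixed"] * scores$score_asd + b["scz", "mixed"] * scores$score_scz
  w <- cbind(right = 1, left = exp(eta_left), mixed = exp(eta_mixed))
  w[is.na(w)] <- 0  # log(0) intercepts for degenerate base rates
  pr <- w / rowSums(w)
  u <- runif(n)
  idx <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
  c("right", "left", "mixed")[idx]
}

#' Simulate typed phenotypes
#'
#' Emits one column per row of the configured phenotype panel, each with a
#' planted per-SD effect of either score: continuous traits are Gaussian
#' with a linear score effect; binary traits follow a logistic model
#' around the configured prevalence; ordered traits discretize a latent
#' Gaussian at balanced thresholds; unordered traits follow a
#' baseline-category logistic model with the effect on the last level.
#'
#' @param config A [sim_config()].
#' @param scores Tibble from [simulate_scores()].
#' @return Tibble of phenotype columns with a `codebook` attribute
#'   (tibble: `phenotype`, `type`, `levels`).
#' @export
simulate_phenotypes <- function(config, scores) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$phenotype_spec
  n <- config$n_individuals
  eta_score <- function(row) {
    row$effect_asd * scores$score_asd + row$effect_scz * scores$score_scz
  }
  cols <- vector("list", nrow(spec))
  names(cols) <- spec$name
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    eta <- eta_score(row)
    cols[[i]] <- switch(row$type,
      continuous = eta + rnorm(n),
      binary = {
        prev <- if (is.na(row$prevalence)) 0.5 else row$prevalence
        as.integer(runif(n) < stats::plogis(stats::qlogis(prev) + eta))
      },
      ordered_categorical = {
        k <- if (is.na(row$levels)) 4L else row$levels
        latent <- eta + rnorm(n)
        cuts <- qnorm(seq_len(k - 1) / k)
        as.integer(findInterval(latent, cuts) + 1L)
      },
      unordered_categorical = {
        k <- if (is.na(row$levels)) 3L else row$levels
        lp <- matrix(0, n, k)
        lp[, k] <- eta
        pr <- exp(lp) / rowSums(exp(lp))
        cum <- t(apply(pr, 1, cumsum))
        u <- runif(n)
        lev <- paste0("cat_", letters[seq_len(k)])
        lev[rowSums(u > cum) + 1L]
      },
      abort(sprintf("Unknown phenotype type '%s'.", row$type),
            class = "asymlink_parameter_error")
    )
  }
  out <- tibble::as_tibble(cols)
  attr(out, "codebook") <- tibble::tibble(
    phenotype = spec$name, type = spec$type,
    levels = spec$levels
  )
  out
}

#' Simulate a full synthetic cohort
#'
#' Runs every generator stage under the configuration's seed and binds the
#' results into one per-individual table: identifier, sex, covariates,
#' the two z-scaled polygenic scores, paired left/right regional measures,
#' brain size, handedness and phenotypes. The result is byte-identical
#' across repeated calls with the same configuration.
#'
#' @param config A [sim_config()].
#' @return A tibble with attributes `regions` (tibble: `region`,
#'   `measure_class`), `codebook`, `covariate_names`, `n_clipped`,
#'   `outlier_cells`, `latent_ai` and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 200, seed = 1))
#' attr(cohort, "regions")
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    scores <- simulate_scores(config)
    covs <- simulate_covariate_columns(config, config$n_individuals)
    meas <- simulate_regional_measures(config, scores, covs)
    hand <- simulate_handedness(config, scores)
    phen <- simulate_phenotypes(config, scores)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("ind_%06d", seq_len(config$n_individuals))),
    scores["sex"], covs, scores[c("score_asd", "score_scz")],
    meas, tibble::tibble(handedness = hand), phen
  )
  attr(out, "regions") <- tibble::tibble(region = config$region_labels,
                                         measure_class = config$region_classes)
  attr(out, "codebook") <- attr(phen, "codebook")
  attr(out, "covariate_names") <- vapply(config$covariate_spec, `[[`,
                                         character(1), "name")
  attr(out, "n_clipped") <- attr(meas, "n_clipped")
  attr(out, "outlier_cells") <- attr(meas, "outlier_cells")
  attr(out, "latent_ai") <- attr(meas, "latent_ai")
  attr(out, "config") <- config
  out
}

#' Write / read a cohort as TSV with a metadata sidecar
#'
#' The table is written as `<prefix>.tsv` and a YAML sidecar
#' `<prefix>.meta.yaml` records column types, region labels and classes,
#' the phenotype codebook and the full simulation configuration including
#' its seed, so a cohort file is self-describing and reproducible.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param prefix Output path prefix.
#' @return `write_cohort()` returns the prefix invisibly; `read_cohort()`
#'   returns the cohort tibble with `regions`, `codebook` and
#'   `covariate_names` attributes restored.
#' @export
write_cohort <- function(cohort, prefix) {
  readr::write_tsv(cohort, paste0(prefix, ".tsv"))
  regions <- attr(cohort, "regions")
  codebook <- attr(cohort, "codebook")
  config <- attr(cohort, "config")
  meta <- list(
    columns = lapply(cohort, function(x) class(x)[1]),
    regions = as.list(setNames(regions$measure_class, regions$region)),
    codebook = if (!is.null(codebook)) {
      lapply(seq_len(nrow(codebook)), function(i) {
        list(phenotype = codebook$phenotype[i], type = codebook$type[i],
             levels = if (is.na(codebook$levels[i])) NULL else codebook$levels[i])
      })
    },
    covariates = as.list(attr(cohort, "covariate_names")),
    config = if (!is.null(config)) {
      lapply(unclass(config)[setdiff(names(config),
                                     c("covariate_spec", "phenotype_spec"))],
             function(x) if (is.matrix(x)) as.numeric(x) else unname(x))
    },
    size_model = "log-normal bilateral size (distribution assumption of the generator)"
  )
  yaml::write_yaml(meta, paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".meta.yaml"))
  out <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE,
                         progress = FALSE)
  for (nm in names(meta$columns)) {
    if (identical(meta$columns[[nm]], "factor") && nm %in% names(out)) {
      out[[nm]] <- factor(out[[nm]])
    }
  }
  attr(out, "regions") <- tibble::tibble(
    region = names(meta$regions),
    measure_class = unlist(meta$regions, use.names = FALSE)
  )
  if (!is.null(meta$codebook)) {
    attr(out, "codebook") <- tibble::tibble(
      phenotype = vapply(meta$codebook, `[[`, character(1), "phenotype"),
      type = vapply(meta$codebook, `[[`, character(1), "type"),
      levels = vapply(meta$codebook,
                      function(x) if (is.null(x$levels)) NA_integer_ else as.integer(x$levels),
                      integer(1))
    )
  }
  attr(out, "covariate_names") <- unlist(meta$covariates, use.names = FALSE)
  out
}
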