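#' Orthonormal default direction set for planted patterns
#'
#' Builds up to three mutually orthonormal length-`p` vectors from smooth
#' trigonometric sequences. They are deterministic (no RNG), so two
#' configurations with the same `n_regions` share the same planted
#' directions regardless of seed.
#'
#' @param p Number of regions.
#' @param k Number of directions (1--3).
#' @return A `p x k` matrix with orthonormal columns.
#' @keywords internal
default_patterns <- function(p, k = 3L) {
  stopifnot(p >= k)
  raw <- cbind(sin(seq_len(p)), cos(seq_len(p)), sin(2 * seq_len(p) + 0.5))
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

default_region_classes <- function(p) {
  if (p == 42L) {
    counts <- c(area = 28L, thickness = 8L, volume = 6L)
  } else {
    # keep the 28:8:6 shape approximately for other sizes
    counts <- pmax(1L, round(p * c(area = 28, thickness = 8, volume = 6) / 42))
    counts[1] <- p - sum(counts[-1])
  }
  rep(names(counts), counts)
}

default_region_labels <- function(p) {
  cls <- default_region_classes(p)
  lab <- character(p)
  for (cl in unique(cls)) {
    j <- which(cls == cl)
    lab[j] <- sprintf("%s_region%02d", cl, seq_along(j))
  }
  lab
}

#' Default covariate roster for simulated cohorts
#'
#' Mirrors the confound set used in large imaging-genetics cohorts: age,
#' ten genetic principal components, scanner table position (x, y, z), T1
#' signal- and contrast-to-noise ratios, assessment centre and genotyping
#' array. Effects on the asymmetry indexes are zero except for small age
#' and centre effects, which exercise the residualization step.
#'
#' Each entry is a list with `name`, `type` (`"continuous"` or
#' `"categorical"`), `levels` (categorical only), and `effect`: a length-`p`
#' vector (per SD of the covariate, in AI-SD units) for continuous entries,
#' or a `levels x p` matrix of level shifts (first row zero) for
#' categorical ones.
#'
#' @param p Number of regions.
#' @return A list of covariate specifications.
#' @export
default_covariate_spec <- function(p = 42L) {
  cont <- function(name, effect = rep(0, p)) {
    list(name = name, type = "continuous", levels = NULL, effect = effect)
  }
  cat_ <- function(name, k, effect = matrix(0, k, p)) {
    list(name = name, type = "categorical", levels = k, effect = effect)
  }
  centre_eff <- matrix(0, 3, p)
  centre_eff[2, seq_len(min(5L, p))] <- 0.02
  centre_eff[3, seq_len(min(5L, p))] <- -0.02
  c(
    list(cont("age", effect = 0.02 * cos(seq_len(p)))),
    lapply(seq_len(10L), function(i) cont(paste0("pc", i))),
    list(cont("scanner_x"), cont("scanner_y"), cont("scanner_z"),
         cont("t1_snr"), cont("t1_cnr"),
         cat_("assessment_centre", 3L, centre_eff),
         cat_("genotyping_array", 2L))
  )
}

#' Default phenotype panel for simulated cohorts
#'
#' A small panel covering the four variable types the phenome-wide scan
#' dispatches on, with planted per-SD score effects on a cognition-like
#' continuous trait and nulls elsewhere.
#'
#' @return A tibble with columns `name`, `type`, `effect_asd`, `effect_scz`,
#'   `levels`, `prevalence`.
#' @export
default_phenotype_spec <- function() {
  tibble::tribble(
    ~name,                ~type,                   ~effect_asd, ~effect_scz, ~levels, ~prevalence,
    "trail_making",       "continuous",            0,           0.10,        NA_integer_, NA_real_,
    "fluid_intelligence", "continuous",            0,          -0.14,        NA_integer_, NA_real_,
    "mood_swings",        "binary",                0.03,        0,           NA_integer_, 0.45,
    "overall_health",     "ordered_categorical",   0,           0.05,        4L,          NA_real_,
    "smoking_status",     "unordered_categorical", 0,           0,           3L,          NA_real_,
    "null_continuous",    "continuous",            0,           0,           NA_integer_, NA_real_,
    "null_binary",        "binary",                0,           0,           NA_integer_, 0.2
  )
}

#' Simulation configuration for a synthetic imaging-genetics cohort
#'
#' Defines the generative model behind [simulate_cohort()]: two z-scaled
#' polygenic scores with a small positive correlation and a small female
#' shift; per-region latent asymmetries carrying two planted loading
#' patterns (one per score, with target canonical correlations), a planted
#' sex-difference pattern, covariate effects and Gaussian noise; strictly
#' positive left/right measures obtained by inverting the asymmetry-index
#' formula around a log-normal bilateral size; handedness from a
#' baseline-category logistic model; and a typed phenotype panel.
#'
#' Defaults reproduce the structure of the motivating study: 42 regions
#' (28 surface area, 8 thickness, 6 subcortical volume), score correlation
#' 0.08, female score shift 0.04 SD, planted canonical correlations 0.03
#' and 0.04 on an orthonormal pair of patterns, handedness base rates
#' (0.890, 0.095, 0.015) with mixed-vs-right log-odds 0.14 and
#' left-vs-right 0.04 for the first score.
#'
#' @param n_individuals Cohort size.
#' @param n_regions Number of left/right region pairs (default 42).
#' @param score_correlation Target correlation of the two scores, in (-1, 1).
#' @param score_sex_shift Standardized mean difference (female minus male)
#'   added to both scores before z-scaling.
#' @param p_female Probability an individual is female (sex coded female = 1).
#' @param loading_pattern_a,loading_pattern_b Planted association directions,
#'   length `n_regions`; rescaled to unit Euclidean norm.
#' @param canonical_r_a,canonical_r_b Target canonical correlations in [0, 1).
#' @param sex_pattern Per-region standardized sex effect on the latent
#'   asymmetries (female minus male, in noise-SD units).
#' @param covariate_spec Covariate roster; see [default_covariate_spec()].
#' @param handedness_base_rates Length-3 probability vector
#'   (right, left, mixed) summing to 1.
#' @param handedness_betas 2 x 2 numeric matrix of per-SD log-odds:
#'   rows = scores (asd, scz), columns = contrasts (left, mixed), both
#'   against right-handedness.
#' @param phenotype_spec Phenotype panel; see [default_phenotype_spec()].
#' @param outlier_rate Per-cell probability that a unilateral measure is
#'   replaced by an extreme (7--10 SD) value, in [0, 1).
#' @param ai_scale Marginal SD of the latent asymmetry index.
#' @param ai_mean Length-`n_regions` baseline mean asymmetries.
#' @param size_sdlog Log-scale SD of individual bilateral size variation.
#' @param brain_size_betas Length-2 per-SD score effects on log brain size.
#' @param missing_rate Per-cell probability that a unilateral measure is
#'   missing, in [0, 1).
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dplyr::glimpse(cohort[, 1:8])
sim_config <- function(n_individuals,
                       n_regions = 42L,
                       score_correlation = 0.08,
                       score_sex_shift = 0.04,
                       p_female = 16968 / 32256,
                       loading_pattern_a = NULL,
                       loading_pattern_b = NULL,
                       canonical_r_a = 0.03,
                       canonical_r_b = 0.04,
                       sex_pattern = NULL,
                       covariate_spec = default_covariate_spec(n_regions),
                       handedness_base_rates = c(right = 28703, left = 3059,
                                                 mixed = 490) / 32252,
                       handedness_betas = matrix(c(0.04, 0.14, 0, 0), nrow = 2,
                                                 byrow = TRUE,
                                                 dimnames = list(c("asd", "scz"),
                                                                 c("left", "mixed"))),
                       phenotype_spec = default_phenotype_spec(),
                       outlier_rate = 0,
                       ai_scale = 0.15,
                       ai_mean = NULL,
                       size_sdlog = 0.1,
                       brain_size_betas = c(asd = 0, scz = -0.02),
                       missing_rate = 0,
                       seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_regions <- check_count(n_regions, "n_regions", min = 3L)
  check_number(score_correlation, "score_correlation", -1, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(score_sex_shift, "score_sex_shift")
  check_number(p_female, "p_female", 0, 1)
  check_number(canonical_r_a, "canonical_r_a", 0, 1, closed_upper = FALSE)
  check_number(canonical_r_b, "canonical_r_b", 0, 1, closed_upper = FALSE)
  check_number(outlier_rate, "outlier_rate", 0, 1, closed_upper = FALSE)
  check_number(missing_rate, "missing_rate", 0, 1, closed_upper = FALSE)
  check_number(ai_scale, "ai_scale", 0, Inf, closed_lower = FALSE)
  check_number(size_sdlog, "size_sdlog", 0, Inf)
  seed <- check_count(seed, "seed", min = 0L)

  pats <- default_patterns(n_regions, 3L)
  if (is.null(loading_pattern_a)) loading_pattern_a <- pats[, 1]
  if (is.null(loading_pattern_b)) loading_pattern_b <- pats[, 2]
  if (is.null(sex_pattern)) sex_pattern <- 0.03 * sqrt(n_regions) * pats[, 3]
  if (is.null(ai_mean)) ai_mean <- 0.1 * sin(seq_len(n_regions))
  loading_pattern_a <- unit_vector(loading_pattern_a, "loading_pattern_a")
  loading_pattern_b <- unit_vector(loading_pattern_b, "loading_pattern_b")
  stopifnot(length(loading_pattern_a) == n_regions,
            length(loading_pattern_b) == n_regions,
            length(sex_pattern) == n_regions,
            length(ai_mean) == n_regions)

  if (length(handedness_base_rates) != 3L || any(handedness_base_rates < 0) ||
      abs(sum(handedness_base_rates) - 1) > 1e-8) {
    abort("`handedness_base_rates` must be a length-3 simplex (right, left, mixed).",
          class = "asymlink_parameter_error")
  }
  handedness_base_rates <- setNames(as.numeric(handedness_base_rates),
                                    c("right", "left", "mixed"))
  handedness_betas <- matrix(as.numeric(handedness_betas), nrow = 2,
                             dimnames = list(c("asd", "scz"), c("left", "mixed")))

  structure(list(
    n_individuals = n_individuals, n_regions = n_regions,
    score_correlation = score_correlation, score_sex_shift = score_sex_shift,
    p_female = p_female,
    loading_pattern_a = loading_pattern_a, loading_pattern_b = loading_pattern_b,
    canonical_r_a = canonical_r_a, canonical_r_b = canonical_r_b,
    sex_pattern = sex_pattern, covariate_spec = covariate_spec,
    handedness_base_rates = handedness_base_rates,
    handedness_betas = handedness_betas,
    phenotype_spec = phenotype_spec,
    outlier_rate = outlier_rate, ai_scale = ai_scale, ai_mean = ai_mean,
    size_sdlog = size_sdlog, brain_size_betas = brain_size_betas,
    missing_rate = missing_rate,
    region_labels = default_region_labels(n_regions),
    region_classes = default_region_classes(n_regions),
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  individuals: %d, regions: %d (%s)\n", x$n_individuals,
              x$n_regions,
              paste(table(x$region_classes)[unique(x$region_classes)],
                    unique(x$region_classes), collapse = " + ")))
  cat(sprintf("  score correlation %.3f, female shift %.3f SD\n",
              x$score_correlation, x$score_sex_shift))
  cat(sprintf("  planted canonical r: %.3f / %.3f, outlier rate %.3g, seed %d\n",
              x$canonical_r_a, x$canonical_r_b, x$outlier_rate, x$seed))
  invisible(x)
}
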