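#' Configuration for an end-to-end pipeline run
#'
#' Bundles every input and threshold of the full analysis: either a
#' simulation configuration (for a synthetic cohort) or a cohort table,
#' the score columns, the covariate set, permutation counts, the master
#' seed, and stage toggles. Every stochastic stage derives its own seed
#' from the master seed (see [derive_stage_seeds()]).
#'
#' @param sim A [sim_config()] for a simulated cohort, or `NULL` when
#'   `cohort` is supplied.
#' @param cohort A cohort tibble, or `NULL` to simulate.
#' @param score_cols Two score column names (first vs second is the order
#'   used in the loading-pattern comparison).
#' @param covariates Covariate column names (`NULL` = auto-detect).
#' @param n_perm Permutations for both permutation nulls.
#' @param seed Master seed.
#' @param sd_threshold Outlier threshold in SD units.
#' @param loading_threshold Concordance threshold on loadings.
#' @param fdr_q FDR threshold of the phenome-wide scan.
#' @param brain_size_sensitivity Also run the CCAs with brain size as an
#'   extra covariate?
#' @param sex_refit Sex-map permutation variant (`"tmap_only"` or
#'   `"full"`).
#' @param run_phewas_stage,run_handedness_stage,run_sex_stage Stage
#'   toggles.
#' @return An object of class `asymlink_config`.
#' @export
pipeline_config <- function(sim = NULL, cohort = NULL,
                            score_cols = c("score_asd", "score_scz"),
                            covariates = NULL,
                            n_perm = 10000L,
                            seed = 1L,
                            sd_threshold = 6,
                            loading_threshold = 0.2,
                            fdr_q = 0.05,
                            brain_size_sensitivity = FALSE,
                            sex_refit = c("tmap_only", "full"),
                            run_phewas_stage = TRUE,
                            run_handedness_stage = TRUE,
                            run_sex_stage = TRUE) {
  if (is.null(sim) && is.null(cohort)) {
    abort("Provide either `sim` or `cohort`.",
          class = "asymlink_parameter_error")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (length(score_cols) != 2) {
    abort("`score_cols` must name exactly two scores.",
          class = "asymlink_parameter_error")
  }
  structure(list(
    sim = sim, cohort = cohort, score_cols = score_cols,
    covariates = covariates,
    n_perm = check_count(n_perm, "n_perm"),
    seed = check_count(seed, "seed", min = 0L),
    sd_threshold = sd_threshold,
    loading_threshold = loading_threshold,
    fdr_q = fdr_q,
    brain_size_sensitivity = isTRUE(brain_size_sensitivity),
    sex_refit = match.arg(sex_refit),
    run_phewas_stage = isTRUE(run_phewas_stage),
    run_handedness_stage = isTRUE(run_handedness_stage),
    run_sex_stage = isTRUE(run_sex_stage)
  ), class = "asymlink_config")
}

config_hash <- function(config) {
  hashable <- config
  hashable$cohort <- NULL  # the cohort itself may be large; sims are hashed
  rlang::hash(hashable)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (unless a cohort is supplied),
#' asymmetry preprocessing with and without the sex covariate, a scalar
#' CCA per score, the loading-pattern comparison with its joint-shuffle
#' permutation null, the sex-difference map and its permutation-tested
#' correlation with each score's loadings, the six handedness logistic
#' contrasts, and the phenome-wide scan per score. Stage outputs carry
#' explicit sample sizes and filter counts; the summary embeds the
#' configuration hash and all derived seeds, and a rerun with the same
#' configuration reproduces it byte-identically.
#'
#' @param config An [pipeline_config()].
#' @return An object of class `asymlink_report`: a list with elements
#'   `cohort_n`, `ai_withsex`, `ai_nosex`, `cca` (named list of `scca`),
#'   `cca_sensitivity` (when toggled), `comparison`, `sex_map`,
#'   `sex_comparisons`, `handedness`, `phewas`, `seeds`, `config_hash`.
#' @seealso [report_summary()], [write_report()]
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "asymlink_config"))
  seeds <- derive_stage_seeds(config$seed)

  cohort <- config$cohort
  if (is.null(cohort)) {
    sim <- config$sim
    sim$seed <- unname(seeds[["simulate"]])
    cohort <- simulate_cohort(sim)
  }
  sa <- cohort[[config$score_cols[1]]]
  sb <- cohort[[config$score_cols[2]]]

  ai_withsex <- prepare_asymmetry_matrix(cohort, include_sex = TRUE,
                                         covariates = config$covariates,
                                         sd_threshold = config$sd_threshold)
  cca <- list(
    scalar_cca(ai_withsex, sa),
    scalar_cca(ai_withsex, sb)
  )
  names(cca) <- config$score_cols

  cca_sensitivity <- NULL
  if (config$brain_size_sensitivity && "brain_size" %in% names(cohort)) {
    ai_bs <- prepare_asymmetry_matrix(cohort, include_sex = TRUE,
                                      covariates = config$covariates,
                                      extra_covariates = "brain_size",
                                      sd_threshold = config$sd_threshold)
    cca_sensitivity <- list(scalar_cca(ai_bs, sa), scalar_cca(ai_bs, sb))
    names(cca_sensitivity) <- config$score_cols
  }

  comparison <- compare_loading_patterns(ai_withsex, sa, sb,
                                         n_perm = config$n_perm,
                                         seed = unname(seeds[["perm"]]),
                                         threshold = config$loading_threshold)

  sex_map_res <- NULL
  sex_comparisons <- NULL
  ai_nosex <- NULL
  if (config$run_sex_stage && "sex" %in% names(cohort)) {
    ai_nosex <- prepare_asymmetry_matrix(cohort, include_sex = FALSE,
                                         covariates = config$covariates,
                                         sd_threshold = config$sd_threshold)
    sex_map_res <- sex_ttests(ai_nosex, cohort$sex)
    sex_comparisons <- purrr::imap(cca, function(fit, sc) {
      sex_pattern_correlation(sex_map_res, fit$loadings, ai_nosex,
                              cohort$sex,
                              n_perm = config$n_perm,
                              seed = unname(seeds[["sex_perm"]]),
                              refit = config$sex_refit,
                              score = cohort[[sc]])
    })
  }

  handedness <- NULL
  if (config$run_handedness_stage && "handedness" %in% names(cohort)) {
    handedness <- fit_handedness_models(cohort,
                                        score_cols = config$score_cols,
                                        covariates = config$covariates)
  }

  phewas <- NULL
  if (config$run_phewas_stage && !is.null(attr(cohort, "codebook"))) {
    phewas <- purrr::map(setNames(config$score_cols, config$score_cols),
                         function(sc) {
                           run_phewas(cohort, sc,
                                      covariates = config$covariates,
                                      q = config$fdr_q)
                         })
  }

  structure(list(
    cohort_n = nrow(cohort),
    score_cols = config$score_cols,
    ai_withsex = ai_withsex,
    ai_nosex = ai_nosex,
    cca = cca,
    cca_sensitivity = cca_sensitivity,
    comparison = comparison,
    sex_map = sex_map_res,
    sex_comparisons = sex_comparisons,
    handedness = handedness,
    phewas = phewas,
    seeds = seeds,
    config_hash = config_hash(config)
  ), class = "asymlink_report")
}

#' Machine-readable summary of a pipeline run
#'
#' Collapses a report into plain lists/values suitable for JSON: per-score
#' canonical correlations and p-values, the loading-pattern comparison,
#' sex-map comparisons, handedness coefficients, phenome-wide discovery
#' counts, filter bookkeeping, seeds and the configuration hash.
#'
#' @param report An `asymlink_report`.
#' @return A nested list.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "asymlink_report"))
  num <- function(x) unname(as.numeric(x))
  out <- list(
    n = report$cohort_n,
    config_hash = report$config_hash,
    seeds = as.list(report$seeds),
    preprocessing = list(
      outliers_removed = num(sum(report$ai_withsex$provenance$outliers_removed)),
      complete_rows = num(report$ai_withsex$provenance$n_complete),
      n_regions = ncol(report$ai_withsex$values)
    ),
    cca = lapply(report$cca, function(f) {
      list(canonical_r = num(f$canonical_r), p_value = num(f$p_value),
           n = f$n)
    }),
    comparison = list(
      observed_r = num(report$comparison$observed_r),
      empirical_p = num(report$comparison$empirical_p),
      n_permutations = report$comparison$n_permutations,
      concordant = as.list(report$comparison$concordant),
      discordant = as.list(report$comparison$discordant)
    )
  )
  if (!is.null(report$cca_sensitivity)) {
    out$cca_brain_size <- lapply(report$cca_sensitivity, function(f) {
      list(canonical_r = num(f$canonical_r), p_value = num(f$p_value))
    })
  }
  if (!is.null(report$sex_comparisons)) {
    out$sex <- lapply(report$sex_comparisons, function(sx) {
      list(observed_r = num(sx$observed_r), empirical_p = num(sx$empirical_p))
    })
  }
  if (!is.null(report$handedness)) {
    out$handedness <- lapply(seq_len(nrow(report$handedness)), function(i) {
      r <- report$handedness[i, ]
      list(contrast = r$contrast, score = r$score,
           beta = num(r$estimate), se = num(r$std_error),
           p_value = num(r$p_value), n_cases = r$n_cases)
    })
  }
  if (!is.null(report$phewas)) {
    out$phewas <- lapply(report$phewas, function(ph) {
      g <- glance(ph)
      list(n_tested = g$n_tested, n_discoveries = g$n_discoveries)
    })
  }
  out
}

#' Write a pipeline report to disk
#'
#' Writes `summary.json` (the [report_summary()]), and TSV tables of the
#' per-region loadings, the handedness contrasts and the phenome-wide
#' scan when present.
#'
#' @param report An `asymlink_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  loadings <- purrr::imap(report$cca, function(f, sc) {
    dplyr::mutate(tidy(f), score = sc, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(loadings, file.path(dir, "loadings.tsv"))
  if (!is.null(report$handedness)) {
    readr::write_tsv(tibble::as_tibble(report$handedness),
                     file.path(dir, "handedness.tsv"))
  }
  if (!is.null(report$phewas)) {
    ph <- purrr::imap(report$phewas, function(p, sc) {
      dplyr::mutate(tibble::as_tibble(p), score = sc, .before = 1)
    }) |> dplyr::bind_rows()
    readr::write_tsv(ph, file.path(dir, "phewas.tsv"))
  }
  invisible(dir)
}

#' @export
print.asymlink_report <- function(x, ...) {
  cat(sprintf("<asymlink report> n = %d, %d regions, config %s\n",
              x$cohort_n, ncol(x$ai_withsex$values), x$config_hash))
  for (sc in names(x$cca)) {
    f <- x$cca[[sc]]
    cat(sprintf("  %s: canonical r = %.4f (p = %.3g, n = %d)\n",
                sc, f$canonical_r, f$p_value, f$n))
  }
  cat(sprintf("  loading patterns: r = %.3f, permuted p = %.3g\n",
              x$comparison$observed_r, x$comparison$empirical_p))
  if (!is.null(x$sex_comparisons)) {
    for (sc in names(x$sex_comparisons)) {
      s <- x$sex_comparisons[[sc]]
      cat(sprintf("  sex map vs %s loadings: r = %.3f, permuted p = %.3g\n",
                  sc, s$observed_r, s$empirical_p))
    }
  }
  if (!is.null(x$handedness)) {
    cat(sprintf("  handedness: %d logistic contrasts fitted\n",
                nrow(x$handedness)))
  }
  if (!is.null(x$phewas)) {
    for (sc in names(x$phewas)) {
      g <- glance(x$phewas[[sc]])
      cat(sprintf("  phewas (%s): %d tested, %d discoveries at q = %.2f\n",
                  sc, g$n_tested, g$n_discoveries, g$q))
    }
  }
  invisible(x)
}
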