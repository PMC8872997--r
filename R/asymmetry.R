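#' Left-right asymmetry index
#'
#' Computes `(L - R) / ((L + R) / 2)`, the standard normalized laterality
#' index: 0 for symmetric measures, positive for leftward asymmetry, and
#' antisymmetric under swapping sides. Missing values propagate.
#'
#' @param left,right Strictly positive numeric vectors of equal length.
#' @param region Optional region label used in error messages.
#' @return Numeric vector of asymmetry indexes in (-2, 2).
#' @export
#' @examples
#' asymmetry_index(3, 1)   # 1
#' asymmetry_index(1, 3)   # -1
asymmetry_index <- function(left, right, region = NULL) {
  if (length(left) != length(right)) {
    abort("`left` and `right` must have equal length.",
          class = "asymlink_value_error")
  }
  bad <- which((!is.na(left) & left <= 0) | (!is.na(right) & right <= 0))
  if (length(bad)) {
    abort(sprintf("Non-positive measure%s at row(s) %s.",
                  if (is.null(region)) "" else paste0(" for region '", region, "'"),
                  paste(head(bad, 5), collapse = ", ")),
          class = "asymlink_value_error")
  }
  (left - right) / ((left + right) / 2)
}

#' Mark extreme values as missing by an SD rule
#'
#' Entries further than `sd_threshold` standard deviations from the column
#' mean are set to `NA`. Mean and SD are computed once on the column
#' before any removal; the rule is not iterated.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @param sd_threshold Distance threshold in SD units (default 6).
#' @return `x` with outliers set to `NA`; the number removed is attached
#'   as attribute `n_removed`.
#' @export
remove_outliers <- function(x, sd_threshold = 6) {
  check_number(sd_threshold, "sd_threshold", 0, Inf, closed_lower = FALSE)
  obs <- !is.na(x)
  if (sum(obs) < 2) {
    abort("Need at least 2 non-missing values.", class = "asymlink_value_error")
  }
  m <- mean(x[obs])
  s <- sd(x[obs])
  if (s == 0) {
    warn("Zero standard deviation; no outlier removal performed.")
    attr(x, "n_removed") <- 0L
    return(x)
  }
  out <- obs & abs(x - m) > sd_threshold * s
  x[out] <- NA
  attr(x, "n_removed") <- sum(out)
  x
}

int_offset_value <- function(offset) {
  if (is.numeric(offset)) return(check_number(offset, "offset", 0, 0.5))
  switch(match.arg(offset, c("blom", "vanderwaerden", "tukey")),
         blom = 3 / 8, vanderwaerden = 0, tukey = 1 / 3)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (average, for ties) ranks:
#' `qnorm((rank - c) / (m - 2c + 1))` over the `m` non-missing entries,
#' with Blom's offset `c = 3/8` by default (van der Waerden `c = 0` and
#' Tukey `c = 1/3` are available). The transform is monotone and leaves
#' missing values missing.
#'
#' @param x Numeric vector with at least 2 distinct non-missing values.
#' @param offset `"blom"`, `"vanderwaerden"`, `"tukey"`, or a numeric
#'   offset in [0, 0.5].
#' @return Transformed numeric vector.
#' @export
inverse_normal_transform <- function(x, offset = "blom") {
  cc <- int_offset_value(offset)
  obs <- !is.na(x)
  m <- sum(obs)
  if (m < 2 || length(unique(x[obs])) < 2) {
    abort("Need at least 2 distinct non-missing values.",
          class = "asymlink_value_error")
  }
  r <- rank(x[obs], ties.method = "average")
  x[obs] <- qnorm((r - cc) / (m - 2 * cc + 1))
  x
}

expand_design <- function(data, covariates, include_sex = TRUE,
                          sex_col = "sex", nonlinear_age = TRUE,
                          extra_covariates = NULL) {
  covariates <- unique(c(covariates, extra_covariates))
  missing_cols <- setdiff(c(covariates, if (include_sex) sex_col), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Covariate column(s) not found: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "asymlink_value_error")
  }
  cols <- list()
  for (nm in covariates) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      f <- factor(x)
      # reference level = most frequent
      f <- stats::relevel(f, ref = names(which.max(table(f))))
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(f)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  if (nonlinear_age && "age" %in% covariates) {
    age <- as.numeric(data[["age"]])
    cols[["age_nonlinear"]] <- (age - mean(age, na.rm = TRUE))^2
  }
  if (include_sex) cols[[sex_col]] <- as.numeric(data[[sex_col]])
  do.call(cbind, cols)
}

#' Build a covariate design matrix from cohort columns
#'
#' Numeric columns enter as-is; categorical columns are expanded to
#' treatment-coded indicators with the most frequent level as reference.
#' If `age` is among the covariates, a nonlinear age term
#' `(age - mean(age))^2` is appended, with the mean taken on the analysis
#' sample at build time. Sex is appended last when `include_sex = TRUE`.
#'
#' @param data Cohort tibble.
#' @param covariates Character vector of covariate column names. Defaults
#'   to the intersection of the standard imaging-genetics roster (age,
#'   pc1--pc10, scanner position, T1 SNR/CNR, assessment centre,
#'   genotyping array) with the available columns.
#' @param include_sex Include the sex column (female = 1)?
#' @param extra_covariates Extra column names appended to the design (for
#'   example `"brain_size"` for the brain-size sensitivity analysis).
#' @param nonlinear_age Append the quadratic age term?
#' @return Numeric design matrix (without intercept).
#' @export
build_covariate_matrix <- function(data, covariates = NULL,
                                   include_sex = TRUE,
                                   extra_covariates = NULL,
                                   nonlinear_age = TRUE) {
  if (is.null(covariates)) covariates <- default_covariate_names(data)
  expand_design(data, covariates, include_sex = include_sex,
                nonlinear_age = nonlinear_age,
                extra_covariates = extra_covariates)
}

default_covariate_names <- function(data) {
  roster <- c("age", paste0("pc", 1:10), "scanner_x", "scanner_y", "scanner_z",
              "t1_snr", "t1_cnr", "assessment_centre", "genotyping_array")
  from_attr <- attr(data, "covariate_names")
  intersect(from_attr %||% roster, names(data))
}

#' Residualize columns against a covariate design
#'
#' Replaces every column of `mat` by its ordinary-least-squares residual
#' against the design (an intercept is always included), leaving residuals
#' orthogonal to every design column. Columns with missing entries are
#' residualized on their complete cases; missing positions stay missing.
#'
#' @param mat Numeric matrix (or data frame) of columns to residualize.
#' @param design Numeric covariate matrix, `NULL` for intercept-only.
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(mat, design = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  X <- cbind(`(intercept)` = rep(1, n), design)
  if (n <= ncol(X)) {
    abort("Need more rows than design columns.", class = "asymlink_value_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Covariate design is rank-deficient; collinear column(s): %s.",
                  paste(drop_cols, collapse = ", ")),
          class = "asymlink_value_error")
  }
  complete <- !is.na(mat)
  if (all(complete)) {
    return(qr.resid(qrX, mat))
  }
  res <- mat
  for (j in seq_len(ncol(mat))) {
    obs <- complete[, j]
    if (all(obs)) {
      res[, j] <- qr.resid(qrX, mat[, j])
    } else {
      res[obs, j] <- qr.resid(qr(X[obs, , drop = FALSE]), mat[obs, j])
    }
  }
  res
}

#' Construct the preprocessed asymmetry-index matrix
#'
#' Runs the full preprocessing chain on a cohort with paired
#' `left_<region>` / `right_<region>` columns, in this order: per-measure
#' outlier removal on the raw unilateral measures (an asymmetry index is
#' missing if either side is removed), asymmetry-index computation on the
#' surviving pairs, rank-based inverse normal transformation, and
#' residualization against the covariate design (with or without sex).
#' Outlier removal can alternatively be applied to the asymmetry indexes
#' themselves (`outliers_on = "ai"`) as a sensitivity option.
#'
#' @param cohort Cohort tibble (from [simulate_cohort()], [read_cohort()],
#'   or any table with the paired columns).
#' @param include_sex Include sex in the residualization design? The
#'   sex-difference map requires `include_sex = FALSE`.
#' @param covariates,extra_covariates,nonlinear_age Passed to
#'   [build_covariate_matrix()].
#' @param sd_threshold Outlier threshold in SD units (default 6).
#' @param int_offset Inverse-normal offset (default Blom).
#' @param outliers_on `"raw"` (default) removes outliers on each
#'   unilateral measure; `"ai"` removes them on the asymmetry indexes.
#' @return An object of class `asym_matrix`: a list with `values` (n x p
#'   numeric matrix, columns named by region), `regions` (tibble with
#'   `region`, `measure_class`), `row_id`, and `provenance` (ordered list
#'   of applied steps with per-column removal counts).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 300, seed = 3))
#' ai <- prepare_asymmetry_matrix(cohort)
#' ai
prepare_asymmetry_matrix <- function(cohort,
                                     include_sex = TRUE,
                                     covariates = NULL,
                                     extra_covariates = NULL,
                                     nonlinear_age = TRUE,
                                     sd_threshold = 6,
                                     int_offset = "blom",
                                     outliers_on = c("raw", "ai")) {
  outliers_on <- match.arg(outliers_on)
  left_cols <- grep("^left_", names(cohort), value = TRUE)
  regions <- sub("^left_", "", left_cols)
  right_cols <- paste0("right_", regions)
  if (!length(regions) || !all(right_cols %in% names(cohort))) {
    abort("Cohort must contain matching `left_<region>`/`right_<region>` columns.",
          class = "asymlink_value_error")
  }
  region_meta <- attr(cohort, "regions")
  measure_class <- if (!is.null(region_meta)) {
    region_meta$measure_class[match(regions, region_meta$region)]
  } else {
    cls <- sub("_.*$", "", regions)
    ifelse(cls %in% c("area", "thickness", "volume"), cls, NA_character_)
  }

  n <- nrow(cohort)
  p <- length(regions)
  removed <- setNames(integer(p), regions)
  ai <- matrix(NA_real_, n, p, dimnames = list(NULL, regions))
  for (j in seq_len(p)) {
    L <- cohort[[left_cols[j]]]
    R <- cohort[[right_cols[j]]]
    if (outliers_on == "raw") {
      L2 <- remove_outliers(L, sd_threshold)
      R2 <- remove_outliers(R, sd_threshold)
      removed[j] <- attr(L2, "n_removed") + attr(R2, "n_removed")
      keep <- !is.na(L2) & !is.na(R2)
      ai[keep, j] <- asymmetry_index(L2[keep], R2[keep], region = regions[j])
    } else {
      obs <- !is.na(L) & !is.na(R)
      raw <- rep(NA_real_, n)
      raw[obs] <- asymmetry_index(L[obs], R[obs], region = regions[j])
      cleaned <- remove_outliers(raw, sd_threshold)
      removed[j] <- attr(cleaned, "n_removed")
      ai[, j] <- cleaned
    }
    ai[, j] <- inverse_normal_transform(ai[, j], offset = int_offset)
  }

  if (is.null(covariates)) covariates <- default_covariate_names(cohort)
  design <- if (length(covariates) || include_sex || length(extra_covariates)) {
    build_covariate_matrix(cohort, covariates, include_sex = include_sex,
                           extra_covariates = extra_covariates,
                           nonlinear_age = nonlinear_age)
  } else {
    NULL
  }
  values <- residualize(ai, design)

  structure(list(
    values = values,
    regions = tibble::tibble(region = regions, measure_class = measure_class),
    row_id = if ("id" %in% names(cohort)) cohort$id else as.character(seq_len(n)),
    provenance = list(
      steps = c(paste0("outlier_removal_", outliers_on, "_6sd"),
                "asymmetry_index", paste0("inverse_normal_",
                if (is.character(int_offset)) int_offset else "custom"),
                "residualization"),
      sd_threshold = sd_threshold,
      outliers_removed = removed,
      covariates = colnames(design) %||% character(),
      include_sex = include_sex,
      n_rows = n,
      n_complete = sum(stats::complete.cases(values))
    )
  ), class = "asym_matrix")
}

#' @export
print.asym_matrix <- function(x, ...) {
  cat(sprintf("<asym_matrix> %d individuals x %d regions (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(table(x$regions$measure_class)[unique(x$regions$measure_class)],
                    unique(x$regions$measure_class), collapse = " + ")))
  cat(sprintf("  preprocessing: %s\n", paste(x$provenance$steps, collapse = " -> ")))
  cat(sprintf("  covariates: %s\n",
              if (length(x$provenance$covariates))
                paste(head(x$provenance$covariates, 6), collapse = ", ") else "none"))
  cat(sprintf("  outliers removed: %d; complete rows: %d\n",
              sum(x$provenance$outliers_removed), x$provenance$n_complete))
  invisible(x)
}

#' @export
tidy.asym_matrix <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(id = x$row_id, .before = 1) |>
    tidyr::pivot_longer(-"id", names_to = "region", values_to = "ai") |>
    dplyr::left_join(x$regions, by = "region")
}

# internal: matrix + complete-case handling shared by the statistics
ai_matrix <- function(ai) {
  if (inherits(ai, "asym_matrix")) return(ai$values)
  as.matrix(ai)
}

ai_regions <- function(ai) {
  if (inherits(ai, "asym_matrix")) return(ai$regions$region)
  colnames(ai_matrix(ai)) %||% paste0("v", seq_len(ncol(ai_matrix(ai))))
}
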