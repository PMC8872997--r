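#' @importFrom rlang abort warn inform %||%
#' @importFrom stats sd var cor qnorm pnorm pf pchisq rnorm runif rbinom
#'   complete.cases coef lm glm binomial p.adjust cor.test setNames
#' @importFrom utils head
NULL

# shared argument checks ----

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name,
                  if (closed_lower) "[" else "(", format(lower),
                  format(upper), if (closed_upper) "]" else ")"),
          class = "asymlink_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "asymlink_parameter_error")
  }
  invisible(as.integer(x))
}

# unit-normalize a pattern vector; zero vectors are not directions
unit_vector <- function(x, name) {
  nrm <- sqrt(sum(x^2))
  if (!is.numeric(x) || any(!is.finite(x)) || nrm < .Machine$double.eps) {
    abort(sprintf("`%s` must be a finite non-zero numeric vector.", name),
          class = "asymlink_parameter_error")
  }
  x / nrm
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) abort("Cannot z-scale a constant column.",
                    class = "asymlink_parameter_error")
  (x - mean(x)) / s
}

#' Derive per-stage child seeds from a single pipeline seed
#'
#' Stages of the pipeline (simulation, the loading-pattern permutation null,
#' the sex-map permutation null) each consume their own seed so that any
#' stage can be re-run in isolation and still reproduce the full run.
#' Children are derived deterministically as `seed * 11 + stage index`,
#' folded into the 32-bit integer range.
#'
#' @param seed Single integer master seed.
#' @return Named integer vector with elements `simulate`, `perm`, `sex_perm`,
#'   `phewas`.
#' @export
derive_stage_seeds <- function(seed) {
  seed <- check_count(seed, "seed", min = 0L)
  idx <- c(simulate = 1L, perm = 2L, sex_perm = 3L, phewas = 4L)
  vapply(idx, function(i) {
    as.integer((as.double(seed) * 11 + i) %% .Machine$integer.max)
  }, integer(1))
}
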