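#' Parametric proportional hazards model
#'
#' Combines a baseline family with a vector of regression coefficients into a
#' proportional hazards (PH) model
#' \deqn{h(t \mid x) = h_0(t)\, e^{x'\beta},}
#' where \eqn{h_0} is the baseline hazard and no intercept is permitted (the
#' baseline plays that role; the link satisfies \eqn{\psi(0) = 1}).
#'
#' For a GLL baseline the family is closed under this operation: the PH hazard
#' is again a GLL hazard with rate \eqn{k^* = k\, e^{(x'\beta)/\alpha}} and
#' unchanged shapes \eqn{(\alpha, \eta)}.
#'
#' @param baseline A [ph_baseline()].
#' @param beta Numeric vector of regression coefficients (no intercept).
#' @param covariate_names Labels aligned with `beta`; defaults to
#'   `names(beta)` or `x1, x2, ...`.
#' @return An object of class `ph_model`.
#' @examples
#' m <- ph_model(gll_params(0.75, 1.5, 1.25), beta = c(age = 0.75, trt = -0.75))
#' hazard(m, t = 1:3, x = c(0.2, 1))
#' @export
ph_model <- function(baseline, beta = numeric(), covariate_names = NULL) {
  stopifnot(inherits(baseline, "ph_baseline"))
  b <- as.numeric(beta)
  if (is.null(covariate_names)) {
    covariate_names <- if (!is.null(names(beta))) names(beta) else
      if (length(b)) paste0("x", seq_along(b)) else character()
  }
  if (length(covariate_names) != length(b)) {
    stop("`covariate_names` must have the same length as `beta`.", call. = FALSE)
  }
  if (any(!is.finite(b))) stop("`beta` must be finite.", call. = FALSE)
  structure(list(baseline = baseline, beta = stats::setNames(b, covariate_names)),
            class = "ph_model")
}

#' @export
print.ph_model <- function(x, ...) {
  cat("<ph_model> baseline:", x$baseline$family, "\n")
  print(x$baseline)
  cat("beta:\n")
  print(x$beta)
  invisible(x)
}

#' Exponential link of the PH model
#'
#' \eqn{\psi(x'\beta) = e^{x'\beta}}, the relative risk of covariate profile
#' `x` against the baseline. Satisfies `ph_link(beta, 0 * x) == 1`.
#'
#' @param beta Coefficient vector.
#' @param x Covariate vector (same length) or matrix with `length(beta)`
#'   columns (one row per subject).
#' @return Positive scalar (or vector, for a matrix `x`).
#' @export
ph_link <- function(beta, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(beta)) stop("`x` must have length(beta) columns.", call. = FALSE)
    return(exp(drop(x %*% beta)))
  }
  if (length(x) != length(beta)) {
    stop("`x` and `beta` must have the same length.", call. = FALSE)
  }
  exp(sum(x * beta))
}

ph_model_x <- function(object, x) {
  if (is.null(x)) x <- numeric(length(object$beta))
  ph_link(object$beta, x)
}

#' @rdname hazard
#' @param x Covariate profile for `ph_model` methods (defaults to all zero,
#'   i.e. the baseline subject).
#' @export
hazard.ph_model <- function(object, t, x = NULL, ...) {
  hazard(object$baseline, t) * ph_model_x(object, x)
}

#' @rdname hazard
#' @export
cum_hazard.ph_model <- function(object, t, x = NULL, ...) {
  cum_hazard(object$baseline, t) * ph_model_x(object, x)
}

#' @rdname hazard
#' @export
surv.ph_model <- function(object, t, x = NULL, ...) {
  exp(-cum_hazard.ph_model(object, t, x))
}

#' @rdname hazard
#' @export
cdf.ph_model <- function(object, t, x = NULL, ...) {
  -expm1(-cum_hazard.ph_model(object, t, x))
}

#' @rdname hazard
#' @export
dens.ph_model <- function(object, t, x = NULL, ...) {
  s <- surv.ph_model(object, t, x)
  ifelse(s == 0, 0, hazard.ph_model(object, t, x) * s)
}

#' @rdname hazard
#' @export
inv_cum_hazard.ph_model <- function(object, u, x = NULL, ...) {
  chk_nonneg(u, "u")
  inv_cum_hazard(object$baseline, u / ph_model_x(object, x))
}

#' Hazard ratio between two covariate profiles
#'
#' Under proportional hazards the ratio of hazards for profiles `x1` and `x2`
#' is the time-constant \eqn{HR = e^{(x_1 - x_2)'\beta}}.
#'
#' @param beta Coefficient vector.
#' @param x1,x2 Covariate vectors conformable with `beta`.
#' @return Positive scalar.
#' @examples
#' hazard_ratio(c(0.75, -0.75, 0.5), c(1, 0, 0), c(0, 0, 0))
#' @export
hazard_ratio <- function(beta, x1, x2) {
  if (length(x1) != length(beta) || length(x2) != length(beta)) {
    stop("`x1`, `x2` and `beta` must have the same length.", call. = FALSE)
  }
  exp(sum((x1 - x2) * beta))
}

#' Posterior distribution of a hazard ratio
#'
#' Applies [hazard_ratio()] to every retained posterior draw of the
#' regression coefficients and summarizes the induced posterior.
#'
#' @param draws A `gllph_draws` object from [sample_posterior()], or a matrix
#'   of coefficient draws (one column per coefficient).
#' @param x1,x2 Covariate profiles, conformable with the coefficient block.
#' @return One-row tibble: posterior mean, SD, naive SE (SD over the square
#'   root of the retained draw count), time-series SE (SD over the square root
#'   of the effective sample size) and the 2.5/25/50/75/97.5 percentiles.
#' @export
posterior_hazard_ratio <- function(draws, x1, x2) {
  B <- if (inherits(draws, "gllph_draws")) {
    do.call(rbind, lapply(draws$draws, function(m) m[, draws$beta_names, drop = FALSE]))
  } else {
    as.matrix(draws)
  }
  if (nrow(B) == 0) stop("`draws` is empty.", call. = FALSE)
  if (length(x1) != ncol(B) || length(x2) != ncol(B)) {
    stop("`x1`/`x2` must match the number of coefficients (", ncol(B), ").",
         call. = FALSE)
  }
  hr <- exp(drop(B %*% (x1 - x2)))
  qs <- stats::quantile(hr, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  n_eff <- if (stats::sd(hr) == 0) length(hr) else ess(hr)
  tibble::tibble(
    mean = mean(hr), sd = stats::sd(hr),
    naive_se = stats::sd(hr) / sqrt(length(hr)),
    ts_se = stats::sd(hr) / sqrt(n_eff),
    q2.5 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4], q97.5 = qs[5]
  )
}
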