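#' Baseline hazard families
#'
#' Constructs a parametric baseline hazard family for use in a proportional
#' hazards (PH) model. Four families closed under the PH operation are
#' supported:
#'
#' * `"gll"` — generalized log-logistic with rate `k` (1/time) and shape
#'   parameters `alpha` (dimensionless) and `eta` (1/time); hazard
#'   \eqn{h(t) = \alpha k (kt)^{\alpha-1} / (1 + (\eta t)^\alpha)}. The family
#'   nests the Weibull (\eqn{\eta \to 0}) and the standard log-logistic
#'   (\eqn{k = \eta}) and accommodates constant, monotone, V-shaped and
#'   unimodal hazards.
#' * `"exponential"` — constant hazard `k`.
#' * `"weibull"` — \eqn{h(t) = \alpha k (kt)^{\alpha-1}} (rate `k`, shape
#'   `alpha`).
#' * `"gompertz"` — \eqn{h(t) = \alpha k e^{kt}} (rate `k`, scale `alpha`).
#'
#' All parameters must be strictly positive.
#'
#' @param family One of `"gll"`, `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param k Rate parameter (1/time), all families.
#' @param alpha Shape parameter, required for all families except
#'   `"exponential"`.
#' @param eta Second shape/tail parameter (1/time), GLL only.
#'
#' @return An object of class `ph_baseline`.
#' @examples
#' b <- ph_baseline("gll", k = 0.75, alpha = 1.5, eta = 1.25)
#' hazard(b, c(0.5, 1, 2))
#' @seealso [hazard()], [cum_hazard()], [surv()], [dens()], [inv_cum_hazard()],
#'   [ph_model()]
#' @export
ph_baseline <- function(family = c("gll", "exponential", "weibull", "gompertz"),
                        k, alpha = NULL, eta = NULL) {
  family <- match.arg(family)
  chk_pos <- function(x, nm) {
    if (is.null(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single strictly positive number for family '",
           family, "'.", call. = FALSE)
    }
    as.numeric(x)
  }
  k <- chk_pos(k, "k")
  if (family != "exponential") alpha <- chk_pos(alpha, "alpha") else alpha <- NA_real_
  if (family == "gll") eta <- chk_pos(eta, "eta") else eta <- NA_real_
  structure(list(family = family, k = k, alpha = alpha, eta = eta),
            class = "ph_baseline")
}

#' @describeIn ph_baseline shorthand for the generalized log-logistic triple
#'   \eqn{\theta = (k, \alpha, \eta)}.
#' @export
gll_params <- function(k, alpha, eta) ph_baseline("gll", k = k, alpha = alpha, eta = eta)

#' @export
print.ph_baseline <- function(x, ...) {
  pars <- switch(x$family,
    exponential = sprintf("k = %g", x$k),
    gll = sprintf("k = %g, alpha = %g, eta = %g", x$k, x$alpha, x$eta),
    sprintf("k = %g, alpha = %g", x$k, x$alpha)
  )
  cat("<ph_baseline> ", x$family, " (", pars, ")\n", sep = "")
  invisible(x)
}

baseline_par_names <- function(family) {
  switch(family,
    exponential = "k",
    weibull = c("k", "alpha"),
    gompertz = c("k", "alpha"),
    gll = c("k", "alpha", "eta")
  )
}

baseline_pars <- function(b) {
  nm <- baseline_par_names(b$family)
  stats::setNames(unlist(b[nm]), nm)
}

chk_nonneg <- function(t, nm = "t") {
  if (any(!is.finite(t) | t < 0)) {
    stop("`", nm, "` must be finite and nonnegative.", call. = FALSE)
  }
  invisible(t)
}

# log(1 + exp(v)) without overflow; v = alpha * log(eta * t)
log1pexp <- function(v) ifelse(v > 33, v, log1p(exp(pmin(v, 33))))

# (alpha - 1) * log(t) with the 0 * Inf case at alpha = 1, t = 0 resolved to 0
am1_logt <- function(t, alpha) if (alpha == 1) rep(0, length(t)) else (alpha - 1) * log(t)

# -- GLL closed forms (k: rate, alpha/eta: shapes) ---------------------------
# h(t) = alpha * k^alpha * t^(alpha-1) / (1 + (eta t)^alpha)
# H(t) = (k/eta)^alpha * log(1 + (eta t)^alpha)
gll_log_hazard <- function(t, k, alpha, eta) {
  log(alpha) + alpha * log(k) + am1_logt(t, alpha) -
    log1pexp(alpha * log(eta * t))
}

gll_cum_hazard <- function(t, k, alpha, eta) {
  (k / eta)^alpha * log1pexp(alpha * log(eta * t))
}

gll_quantile <- function(q, k, alpha, eta) {
  # from S(t) = (1 + (eta t)^alpha)^(-(k/eta)^alpha): invert F(t) = q
  expm1(-(eta / k)^alpha * log1p(-q))^(1 / alpha) / eta
}

gll_inv_cum_hazard <- function(u, k, alpha, eta) {
  expm1(u * (eta / k)^alpha)^(1 / alpha) / eta
}

# -- family dispatch ---------------------------------------------------------
baseline_log_hazard <- function(b, t) {
  switch(b$family,
    exponential = rep(log(b$k), length(t)),
    weibull = log(b$alpha) + b$alpha * log(b$k) + am1_logt(t, b$alpha),
    gompertz = log(b$alpha) + log(b$k) + b$k * t,
    gll = gll_log_hazard(t, b$k, b$alpha, b$eta)
  )
}

baseline_cum_hazard <- function(b, t) {
  switch(b$family,
    exponential = b$k * t,
    weibull = (b$k * t)^b$alpha,
    gompertz = b$alpha * expm1(b$k * t),
    gll = gll_cum_hazard(t, b$k, b$alpha, b$eta)
  )
}

baseline_inv_cum_hazard <- function(b, u) {
  switch(b$family,
    exponential = u / b$k,
    weibull = u^(1 / b$alpha) / b$k,
    gompertz = log1p(u / b$alpha) / b$k,
    gll = gll_inv_cum_hazard(u, b$k, b$alpha, b$eta)
  )
}

#' Lifetime functions of a baseline family or PH model
#'
#' `hazard()`, `cum_hazard()`, `surv()`, `cdf()` and `dens()` evaluate the
#' hazard rate \eqn{h(t)}, cumulative hazard \eqn{H(t)}, survival
#' \eqn{S(t) = e^{-H(t)}}, distribution function \eqn{F(t) = 1 - S(t)} and
#' density \eqn{f(t) = h(t) S(t)}, vectorized over `t`. `inv_cum_hazard()`
#' evaluates \eqn{H^{-1}(u)}, the inverse cumulative hazard used by
#' inversion-method simulation of event times.
#'
#' For shape `alpha < 1` the GLL and Weibull hazards diverge at the origin;
#' `hazard(b, 0)` then returns `Inf` (the limiting value), not an error.
#'
#' @param object A [ph_baseline()] or [ph_model()].
#' @param t Vector of nonnegative times.
#' @param u Vector of nonnegative cumulative-hazard values.
#' @param ... Passed to methods; for `ph_model` methods, the covariate
#'   profile `x`.
#' @return Numeric vector the length of `t` (or `u`).
#' @examples
#' b <- gll_params(k = 0.75, alpha = 1.5, eta = 1.25)
#' surv(b, 1:3)
#' all.equal(surv(b, 2), exp(-cum_hazard(b, 2)))
#' @export
hazard <- function(object, t, ...) UseMethod("hazard")

#' @rdname hazard
#' @export
hazard.ph_baseline <- function(object, t, ...) {
  chk_nonneg(t)
  exp(baseline_log_hazard(object, t))
}

#' @rdname hazard
#' @export
cum_hazard <- function(object, t, ...) UseMethod("cum_hazard")

#' @rdname hazard
#' @export
cum_hazard.ph_baseline <- function(object, t, ...) {
  chk_nonneg(t)
  baseline_cum_hazard(object, t)
}

#' @rdname hazard
#' @export
surv <- function(object, t, ...) UseMethod("surv")

#' @rdname hazard
#' @export
surv.ph_baseline <- function(object, t, ...) {
  chk_nonneg(t)
  exp(-baseline_cum_hazard(object, t))
}

#' @rdname hazard
#' @export
cdf <- function(object, t, ...) UseMethod("cdf")

#' @rdname hazard
#' @export
cdf.ph_baseline <- function(object, t, ...) {
  chk_nonneg(t)
  -expm1(-baseline_cum_hazard(object, t))
}

#' @rdname hazard
#' @export
dens <- function(object, t, ...) UseMethod("dens")

#' @rdname hazard
#' @export
dens.ph_baseline <- function(object, t, ...) {
  chk_nonneg(t)
  h <- exp(baseline_log_hazard(object, t))
  s <- exp(-baseline_cum_hazard(object, t))
  # at t = 0 with alpha < 1: h = Inf, S = 1 -> density diverges too
  ifelse(s == 0, 0, h * s)
}

#' @rdname hazard
#' @export
inv_cum_hazard <- function(object, u, ...) UseMethod("inv_cum_hazard")

#' @rdname hazard
#' @export
inv_cum_hazard.ph_baseline <- function(object, u, ...) {
  chk_nonneg(u, "u")
  baseline_inv_cum_hazard(object, u)
}

#' Quantile function of a baseline family
#'
#' Inverts the distribution function: returns the time `t` with
#' \eqn{F(t) = q}. For the GLL family the closed form is
#' \eqn{t = ((1-q)^{-(\eta/k)^\alpha} - 1)^{1/\alpha} / \eta}.
#'
#' @param x A [ph_baseline()].
#' @param probs Probabilities in `[0, 1)`.
#' @param ... Unused.
#' @return Numeric vector of times.
#' @examples
#' quantile(gll_params(0.75, 1.5, 1.25), 0.5)
#' @export
quantile.ph_baseline <- function(x, probs = c(0.25, 0.5, 0.75), ...) {
  if (any(!is.finite(probs) | probs < 0 | probs >= 1)) {
    stop("`probs` must lie in [0, 1).", call. = FALSE)
  }
  b <- x
  switch(b$family,
    exponential = -log1p(-probs) / b$k,
    weibull = (-log1p(-probs))^(1 / b$alpha) / b$k,
    gompertz = baseline_inv_cum_hazard(b, -log1p(-probs)),
    gll = gll_quantile(probs, b$k, b$alpha, b$eta)
  )
}

#' The generalized log-logistic distribution
#'
#' Density, distribution function, quantile function, random generation,
#' hazard and cumulative hazard for the three-parameter generalized
#' log-logistic (GLL) distribution with rate `k > 0` and shape parameters
#' `alpha > 0`, `eta > 0`:
#' \deqn{h(t) = \frac{\alpha k (kt)^{\alpha-1}}{1 + (\eta t)^\alpha}, \qquad
#'       H(t) = \left(\frac{k}{\eta}\right)^{\alpha} \log(1 + (\eta t)^\alpha).}
#' With `eta -> 0` the distribution tends to the Weibull(`k`, `alpha`);
#' with `k = eta` it is the standard log-logistic with scale `1/eta`.
#'
#' @param x,t,q Vector of nonnegative times / quantiles.
#' @param p Vector of probabilities in `[0, 1)`.
#' @param n Number of random draws.
#' @param k,alpha,eta Distribution parameters, strictly positive.
#' @param log,log.p Return log values / accept log probabilities.
#' @param lower.tail If `TRUE` (default), probabilities are \eqn{P(T \le t)}.
#' @return `dgll` density, `pgll` distribution function, `qgll` quantiles,
#'   `rgll` random deviates, `hgll` hazard, `Hgll` cumulative hazard.
#' @examples
#' integrate(dgll, 0, Inf, k = 0.75, alpha = 1.5, eta = 1.25)
#' qgll(pgll(2, 0.75, 1.5, 1.25), 0.75, 1.5, 1.25)
#' @name gll
NULL

gll_chk <- function(k, alpha, eta) {
  if (any(c(k, alpha, eta) <= 0) || any(!is.finite(c(k, alpha, eta)))) {
    stop("GLL parameters k, alpha, eta must be strictly positive.", call. = FALSE)
  }
}

#' @rdname gll
#' @export
dgll <- function(x, k, alpha, eta, log = FALSE) {
  gll_chk(k, alpha, eta)
  chk_nonneg(x, "x")
  lf <- gll_log_hazard(x, k, alpha, eta) - gll_cum_hazard(x, k, alpha, eta)
  if (log) lf else exp(lf)
}

#' @rdname gll
#' @export
pgll <- function(q, k, alpha, eta, lower.tail = TRUE, log.p = FALSE) {
  gll_chk(k, alpha, eta)
  chk_nonneg(q, "q")
  lH <- -gll_cum_hazard(q, k, alpha, eta)
  if (lower.tail) {
    p <- -expm1(lH)
    if (log.p) log(p) else p
  } else {
    if (log.p) lH else exp(lH)
  }
}

#' @rdname gll
#' @export
qgll <- function(p, k, alpha, eta) {
  gll_chk(k, alpha, eta)
  if (any(!is.finite(p) | p < 0 | p >= 1)) stop("`p` must lie in [0, 1).", call. = FALSE)
  gll_quantile(p, k, alpha, eta)
}

#' @rdname gll
#' @export
rgll <- function(n, k, alpha, eta) {
  gll_chk(k, alpha, eta)
  gll_quantile(stats::runif(n), k, alpha, eta)
}

#' @rdname gll
#' @export
hgll <- function(t, k, alpha, eta, log = FALSE) {
  gll_chk(k, alpha, eta)
  chk_nonneg(t)
  lh <- gll_log_hazard(t, k, alpha, eta)
  if (log) lh else exp(lh)
}

#' @rdname gll
#' @export
Hgll <- function(t, k, alpha, eta) {
  gll_chk(k, alpha, eta)
  chk_nonneg(t)
  gll_cum_hazard(t, k, alpha, eta)
}
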