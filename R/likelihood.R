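#' Right-censored log-likelihood of a parametric PH model
#'
#' For data \eqn{D = (t_i, \delta_i, x_i)} the censored likelihood factorizes
#' as \eqn{\prod_i h(t_i \mid x_i)^{\delta_i} S(t_i \mid x_i)}, giving
#' \deqn{\ell = \sum_i \delta_i\,[\log h_0(t_i) + x_i'\beta]
#'       - \sum_i H_0(t_i)\, e^{x_i'\beta}.}
#'
#' Non-positive baseline parameters yield `-Inf` (not an error), so that
#' optimizers and samplers can reject such proposals. Subjects with an event
#' at `t = 0` make the hazard term degenerate for `alpha != 1` and are
#' rejected by [fit_ph_mle()] up front.
#'
#' @param data A survival data frame (see [as_surv_data()]).
#' @param model A [ph_model()] whose coefficient length matches the
#'   covariates of `data`.
#' @return Scalar log-likelihood.
#' @examples
#' d <- sim_ph_data(50, gll_params(0.75, 1.5, 1.25),
#'                  beta = c(0.75, -0.75, 0.5), tc = 5, seed = 1)
#' m <- ph_model(gll_params(0.75, 1.5, 1.25), beta = c(0.75, -0.75, 0.5))
#' log_likelihood(d, m)
#' @export
log_likelihood <- function(data, model) {
  stopifnot(inherits(model, "ph_model"))
  data <- as_surv_data(data)
  X <- surv_design_matrix(data)
  if (ncol(X) != length(model$beta)) {
    stop("Model has ", length(model$beta), " coefficients but data has ",
         ncol(X), " covariates.", call. = FALSE)
  }
  par <- c(baseline_pars(model$baseline), model$beta)
  ph_loglik(par, model$baseline$family, data$time, data$status, X)
}

# workhorse: par = c(baseline params in baseline_par_names() order, beta);
# returns -Inf for inadmissible baseline parameters
ph_loglik <- function(par, family, time, status, X) {
  npb <- length(baseline_par_names(family))
  bp <- par[seq_len(npb)]
  if (any(!is.finite(bp)) || any(bp <= 0)) return(-Inf)
  beta <- par[-seq_len(npb)]
  b <- structure(list(family = family, k = bp[[1]],
                      alpha = if (npb >= 2) bp[[2]] else NA_real_,
                      eta = if (npb >= 3) bp[[3]] else NA_real_),
                 class = "ph_baseline")
  xb <- if (ncol(X)) drop(X %*% beta) else numeric(nrow(X))
  ev <- status == 1
  lh0 <- baseline_log_hazard(b, time[ev])
  H0 <- baseline_cum_hazard(b, time)
  ll <- sum(lh0 + xb[ev]) - sum(exp(xb) * H0)
  if (is.nan(ll)) -Inf else ll
}

#' Analytic score of the GLL-PH log-likelihood
#'
#' First derivatives of the right-censored GLL-PH log-likelihood with respect
#' to \eqn{(\alpha, \eta, k, \beta_1, \dots, \beta_p)}. With
#' \eqn{a = \sum_i \delta_i}, \eqn{p_i = e^{x_i'\beta}},
#' \eqn{q_i = (\eta t_i)^\alpha}, \eqn{L_i = \log(1 + q_i)},
#' \eqn{w_i = q_i / (1 + q_i)} and \eqn{r = (k/\eta)^\alpha}:
#' \deqn{\partial\ell/\partial\alpha = a/\alpha + a \log k +
#'   \sum \delta_i \log t_i - \sum \delta_i w_i \log(\eta t_i)
#'   - r\,[\log(k/\eta) \sum p_i L_i + \sum p_i w_i \log(\eta t_i)],}
#' \deqn{\partial\ell/\partial\eta = (\alpha/\eta)\,[-\sum \delta_i w_i +
#'   r \sum p_i (L_i - w_i)],}
#' \deqn{\partial\ell/\partial k = a\alpha/k - (\alpha r / k) \sum p_i L_i,}
#' \deqn{\partial\ell/\partial\beta_j = \sum \delta_i x_{ij} -
#'   r \sum p_i L_i x_{ij}.}
#'
#' @param data Survival data frame.
#' @param model A [ph_model()] with GLL baseline.
#' @return Named gradient vector over `alpha`, `eta`, `k` and the
#'   coefficients.
#' @export
gll_score <- function(data, model) {
  stopifnot(inherits(model, "ph_model"))
  if (model$baseline$family != "gll") {
    stop("`gll_score()` requires a GLL baseline.", call. = FALSE)
  }
  data <- as_surv_data(data)
  X <- surv_design_matrix(data)
  k <- model$baseline$k; alpha <- model$baseline$alpha; eta <- model$baseline$eta
  beta <- model$beta
  time <- data$time; delta <- data$status
  xb <- if (ncol(X)) drop(X %*% beta) else numeric(nrow(X))
  p_i <- exp(xb)
  let <- log(eta * time)                      # -Inf at t = 0
  L <- log1pexp(alpha * let)                  # log(1 + q_i)
  w <- -expm1(-L)                             # q_i / (1 + q_i)
  wlet <- ifelse(w == 0, 0, w * let)          # w_i log(eta t_i), 0 at t = 0
  r <- (k / eta)^alpha
  a <- sum(delta)
  d_alpha <- a / alpha + a * log(k) + sum(delta * ifelse(time == 0, 0, log(time))) -
    sum(delta * wlet) -
    r * (log(k / eta) * sum(p_i * L) + sum(p_i * wlet))
  d_eta <- (alpha / eta) * (-sum(delta * w) + r * sum(p_i * (L - w)))
  d_k <- a * alpha / k - (alpha * r / k) * sum(p_i * L)
  d_beta <- if (ncol(X)) drop(crossprod(X, delta - r * p_i * L)) else numeric()
  out <- c(alpha = d_alpha, eta = d_eta, k = d_k, d_beta)
  if (ncol(X)) names(out)[-(1:3)] <- names(beta)
  out
}

heuristic_init <- function(family, time, status, p) {
  k0 <- sum(status) / max(sum(time), .Machine$double.eps)
  bp <- switch(family,
    exponential = c(k = k0),
    weibull = c(k = k0, alpha = 1),
    gompertz = c(k = k0, alpha = 1),
    gll = c(k = k0, alpha = 1, eta = 1)
  )
  c(bp, rep(0, p))
}

#' Maximum-likelihood fit of a parametric PH model
#'
#' Maximizes the right-censored log-likelihood over strictly positive
#' baseline parameters (optimized on the log scale) and unconstrained
#' regression coefficients by BFGS, using the analytic score for the GLL
#' family. Standard errors come from the inverse of the numerically
#' differentiated observed information at the optimum (natural scale).
#'
#' @param data Survival data frame (see [as_surv_data()]); may also be a raw
#'   data frame with `time`/`status` columns.
#' @param family Baseline family tag.
#' @param time,status,covariates Column mapping passed to [as_surv_data()].
#' @param init Optional named start values on the natural scale
#'   (baseline parameters then coefficients).
#' @param control Passed to [stats::optim()].
#' @return A `gllph_mle` object with `tidy()` and `glance()` methods:
#'   estimates, standard errors, maximized log-likelihood, convergence flag,
#'   iteration count, AIC/BIC.
#' @examples
#' d <- sim_ph_data(200, gll_params(0.75, 1.5, 1.25),
#'                  beta = c(0.75, -0.75, 0.5), tc = 5, seed = 1)
#' fit <- fit_ph_mle(d, family = "gll")
#' tidy(fit)
#' @export
fit_ph_mle <- function(data, family = c("gll", "exponential", "weibull", "gompertz"),
                       time = "time", status = "status", covariates = NULL,
                       init = NULL, control = list()) {
  family <- match.arg(family)
  data <- as_surv_data(data, time = time, status = status, covariates = covariates)
  X <- surv_design_matrix(data)
  n <- nrow(data); p <- ncol(X)
  npb <- length(baseline_par_names(family))
  if (sum(data$status) < 1) stop("No events in `data`; cannot fit.", call. = FALSE)
  if (n < p + npb) stop("Fewer subjects than parameters.", call. = FALSE)
  if (any(data$time == 0 & data$status == 1)) {
    stop("Events at time 0 are not supported (the log-hazard is degenerate ",
         "unless alpha = 1).", call. = FALSE)
  }
  if (is.null(init)) init <- heuristic_init(family, data$time, data$status, p)
  if (length(init) != npb + p || any(init[seq_len(npb)] <= 0)) {
    stop("`init` must supply ", npb, " positive baseline parameters and ",
         p, " coefficients.", call. = FALSE)
  }
  par_names <- c(baseline_par_names(family),
                 if (p) colnames(X) else character())

  # work on phi = (log baseline params, beta)
  to_phi <- function(par) c(log(par[seq_len(npb)]), par[-seq_len(npb)])
  to_par <- function(phi) c(exp(phi[seq_len(npb)]), phi[-seq_len(npb)])
  negll <- function(phi) {
    v <- -ph_loglik(to_par(phi), family, data$time, data$status, X)
    if (!is.finite(v)) 1e10 else v
  }
  grad <- NULL
  if (family == "gll") {
    grad <- function(phi) {
      par <- to_par(phi)
      m <- ph_model(gll_params(par[1], par[2], par[3]), beta = par[-(1:3)],
                    covariate_names = colnames(X))
      g <- gll_score(data, m)                 # d/d(alpha, eta, k, beta)
      g_nat <- c(g[["k"]], g[["alpha"]], g[["eta"]], g[-(1:3)])
      -g_nat * c(par[1:3], rep(1, p))         # chain rule for log scale
    }
  }
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(to_phi(init), negll, gr = grad, method = "BFGS", control = ctl)
  par_hat <- stats::setNames(to_par(opt$par), par_names)

  # observed information on the natural scale
  nll_nat <- function(par) {
    v <- -ph_loglik(par, family, data$time, data$status, X)
    if (!is.finite(v)) 1e10 else v
  }
  hess <- stats::optimHess(par_hat, nll_nat)
  vcov <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, length(par_hat), length(par_hat)))
  se <- suppressWarnings(sqrt(diag(vcov)))
  dimnames(vcov) <- list(par_names, par_names)

  structure(list(
    family = family,
    estimate = par_hat,
    se = stats::setNames(se, par_names),
    vcov = vcov,
    loglik = -opt$value,
    converged = opt$convergence == 0,
    n_iter = unname(opt$counts[1]),
    n = n, n_events = sum(data$status),
    covariates = colnames(X),
    data = data
  ), class = "gllph_mle")
}

#' @export
print.gllph_mle <- function(x, ...) {
  cat("Parametric PH model (", x$family, " baseline), MLE\n", sep = "")
  cat("  n = ", x$n, ", events = ", x$n_events,
      ", logLik = ", format(x$loglik, digits = 6),
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Coefficient of the fitted baseline as a model object
#' @noRd
mle_ph_model <- function(fit) {
  npb <- length(baseline_par_names(fit$family))
  bp <- fit$estimate[seq_len(npb)]
  b <- do.call(ph_baseline, c(list(family = fit$family), as.list(bp)))
  ph_model(b, beta = fit$estimate[-seq_len(npb)],
           covariate_names = fit$covariates)
}

#' @export
#' @method tidy gllph_mle
tidy.gllph_mle <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se),
    conf.low = unname(x$estimate - z * x$se),
    conf.high = unname(x$estimate + z * x$se)
  )
}

#' @export
#' @method glance gllph_mle
glance.gllph_mle <- function(x, ...) {
  npar <- length(x$estimate)
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * npar,
    BIC = -2 * x$loglik + log(x$n) * npar,
    nobs = x$n, n.events = x$n_events,
    converged = x$converged, n.iter = x$n_iter
  )
}

#' @export
logLik.gllph_mle <- function(object, ...) {
  structure(object$loglik, df = length(object$estimate),
            nobs = object$n, class = "logLik")
}
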