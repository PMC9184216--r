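#' Prior specification for a parametric PH model
#'
#' Independent gamma (shape, rate) priors on the positive baseline
#' parameters and an independent normal prior, parameterized by mean and
#' *precision* (1/variance), on every regression coefficient. Defaults are
#' the noninformative choices used throughout the package: gamma(10, 10) on
#' each baseline parameter and N(0, precision 0.001), i.e. variance 1000, on
#' each coefficient. The precision convention is stated explicitly to avoid
#' the usual variance/precision ambiguity.
#'
#' @param alpha_shape,alpha_rate Gamma hyperparameters for the shape `alpha`.
#' @param eta_shape,eta_rate Gamma hyperparameters for the shape `eta`.
#' @param k_shape,k_rate Gamma hyperparameters for the rate `k`.
#' @param beta_mean,beta_precision Normal hyperparameters applied to each
#'   coefficient; `beta_precision` must be > 0.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(alpha_shape = 10, alpha_rate = 10,
                       eta_shape = 10, eta_rate = 10,
                       k_shape = 10, k_rate = 10,
                       beta_mean = 0, beta_precision = 0.001) {
  v <- c(alpha_shape, alpha_rate, eta_shape, eta_rate, k_shape, k_rate,
         beta_precision)
  if (any(!is.finite(v)) || any(v <= 0) || !is.finite(beta_mean)) {
    stop("Gamma shapes/rates and `beta_precision` must be strictly positive.",
         call. = FALSE)
  }
  structure(list(alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 eta_shape = eta_shape, eta_rate = eta_rate,
                 k_shape = k_shape, k_rate = k_rate,
                 beta_mean = beta_mean, beta_precision = beta_precision),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Defaults mirror the reference sampling budget: 3 parallel chains of
#' 40,000 iterations of which the first 3,000 are burn-in, keeping every
#' 10th post-burn-in draw, so each chain retains
#' `floor((n_iter - n_burn) / thin)` draws.
#'
#' @param n_chains Number of chains (>= 1).
#' @param n_iter Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded from the front; adaptation of
#'   the random-walk proposal is confined to this window.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed controlling all sampler randomness.
#' @param target_accept Target acceptance rate of the adaptive joint
#'   random-walk proposal.
#' @param init_jitter SD of the (seeded) normal jitter applied on the
#'   unconstrained scale to overdisperse the per-chain initial values.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 40000, n_burn = 3000, thin = 10,
                        seed = 1, target_accept = 0.3, init_jitter = 0.5) {
  stopifnot(n_chains >= 1, n_iter > n_burn, n_burn >= 0, thin >= 1,
            target_accept > 0, target_accept < 1, init_jitter >= 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept,
                 init_jitter = init_jitter),
            class = "mcmc_config")
}

#' Log prior density
#'
#' Sum of independent gamma log-densities on the baseline parameters present
#' in `family` and normal log-densities on the coefficients. Returns `-Inf`
#' for non-positive baseline parameters.
#'
#' @param par Named numeric vector: baseline parameters (natural scale) then
#'   coefficients, in `c(k, alpha, eta, beta...)` order for the GLL family.
#' @param prior A [prior_spec()].
#' @param family Baseline family tag.
#' @return Scalar log prior density.
#' @export
log_prior <- function(par, prior = prior_spec(), family = "gll") {
  npb <- length(baseline_par_names(family))
  bp <- par[seq_len(npb)]
  if (any(!is.finite(bp)) || any(bp <= 0)) return(-Inf)
  beta <- par[-seq_len(npb)]
  sh <- c(k = prior$k_shape, alpha = prior$alpha_shape, eta = prior$eta_shape)
  ra <- c(k = prior$k_rate, alpha = prior$alpha_rate, eta = prior$eta_rate)
  nm <- baseline_par_names(family)
  lp <- sum(stats::dgamma(bp, shape = sh[nm], rate = ra[nm], log = TRUE))
  if (length(beta)) {
    lp <- lp + sum(stats::dnorm(beta, mean = prior$beta_mean,
                                sd = 1 / sqrt(prior$beta_precision), log = TRUE))
  }
  lp
}

#' Log posterior density (unnormalized)
#'
#' `log_prior + log_likelihood` up to the normalizing constant.
#'
#' @inheritParams log_prior
#' @param data Survival data frame.
#' @return Scalar unnormalized log posterior.
#' @export
log_posterior <- function(par, data, prior = prior_spec(), family = "gll") {
  data <- as_surv_data(data)
  X <- surv_design_matrix(data)
  lp <- log_prior(par, prior, family)
  if (!is.finite(lp)) return(-Inf)
  lp + ph_loglik(par, family, data$time, data$status, X)
}

# one adaptive random-walk Metropolis chain on phi = (log baseline, beta).
# Haario covariance adaptation + Robbins-Monro scale tuning, burn-in only.
run_rwm_chain <- function(lp_fun, init, n_iter, n_burn, thin, target_accept) {
  d <- length(init)
  phi <- init
  lp <- lp_fun(phi)
  if (!is.finite(lp)) stop("Initial value has zero posterior density.", call. = FALSE)
  n_keep <- (n_iter - n_burn) %/% thin
  out <- matrix(NA_real_, n_keep, d)
  log_sc <- log(2.38^2 / d)
  chol_prop <- diag(0.1, d)
  run_mean <- phi
  run_cov <- diag(1e-4, d)
  kept <- 0L
  n_acc <- 0L
  for (i in seq_len(n_iter)) {
    step <- drop(stats::rnorm(d) %*% chol_prop) * exp(log_sc / 2)
    prop <- phi + step
    lp_prop <- lp_fun(prop)
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp)
    if (acc) {
      phi <- prop; lp <- lp_prop; n_acc <- n_acc + 1L
    }
    if (i <= n_burn) {
      w <- 1 / (i + 10)
      delta <- phi - run_mean
      run_mean <- run_mean + w * delta
      run_cov <- run_cov + w * (tcrossprod(delta) - run_cov)
      log_sc <- log_sc + (as.numeric(acc) - target_accept) / max(i, 20)^0.6
      if (i >= 50 && i %% 25 == 0) {
        chol_prop <- tryCatch(chol(run_cov + diag(1e-10, d)),
                              error = function(e) chol_prop)
      }
    } else if ((i - n_burn) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- phi
    }
  }
  list(draws = out[seq_len(kept), , drop = FALSE], accept_rate = n_acc / n_iter)
}

#' Sample the posterior of a parametric PH model by MCMC
#'
#' Adaptive random-walk Metropolis on the unconstrained parameterization
#' (log baseline parameters, coefficients). The proposal is a joint
#' multivariate normal whose covariance is adapted to the running empirical
#' posterior covariance and whose global scale is tuned toward
#' `config$target_accept` during burn-in only, preserving the correct
#' stationary distribution afterwards. Chains start from a moments-based
#' heuristic jittered with chain-indexed, seeded noise (overdispersed
#' starts). Draws are returned on the natural scale.
#'
#' @param data Survival data frame (see [as_surv_data()]).
#' @param family Baseline family tag.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param time,status,covariates Column mapping passed to [as_surv_data()].
#' @param init Optional natural-scale start vector (baseline params, beta)
#'   used as the jitter centre for every chain.
#' @return A `gllph_draws` object: per-chain matrices of retained draws with
#'   parameter names, acceptance rates and the configuration; see
#'   [summarize_posterior()], [diagnose()], [dic()].
#' @examples
#' d <- sim_ph_data(80, gll_params(0.75, 1.5, 1.25),
#'                  beta = c(0.75, -0.75, 0.5), tc = 5, seed = 1)
#' dr <- sample_posterior(d, config = mcmc_config(n_chains = 2, n_iter = 1500,
#'                                                n_burn = 500, thin = 2))
#' summarize_posterior(dr)
#' @export
sample_posterior <- function(data, family = c("gll", "exponential", "weibull", "gompertz"),
                             prior = prior_spec(), config = mcmc_config(),
                             time = "time", status = "status", covariates = NULL,
                             init = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  data <- as_surv_data(data, time = time, status = status, covariates = covariates)
  X <- surv_design_matrix(data)
  p <- ncol(X)
  npb <- length(baseline_par_names(family))
  if (sum(data$status) < 1) stop("No events in `data`; cannot sample.", call. = FALSE)
  if (any(data$time == 0 & data$status == 1)) {
    stop("Events at time 0 are not supported.", call. = FALSE)
  }
  tvec <- data$time; dvec <- data$status
  sh <- c(k = prior$k_shape, alpha = prior$alpha_shape, eta = prior$eta_shape)
  ra <- c(k = prior$k_rate, alpha = prior$alpha_rate, eta = prior$eta_rate)
  nmb <- baseline_par_names(family)
  pr_sh <- sh[nmb]; pr_ra <- ra[nmb]
  b_mean <- prior$beta_mean; b_sd <- 1 / sqrt(prior$beta_precision)
  idxb <- seq_len(npb)

  # log posterior on phi = (log baseline, beta), with log-scale Jacobian
  lp_fun <- function(phi) {
    bp <- exp(phi[idxb])
    if (any(!is.finite(bp))) return(-Inf)
    beta <- phi[-idxb]
    ll <- ph_loglik(c(bp, beta), family, tvec, dvec, X)
    if (!is.finite(ll)) return(-Inf)
    lp <- sum(stats::dgamma(bp, shape = pr_sh, rate = pr_ra, log = TRUE)) +
      sum(phi[idxb])                                    # Jacobian of exp()
    if (p) lp <- lp + sum(stats::dnorm(beta, b_mean, b_sd, log = TRUE))
    lp + ll
  }

  if (is.null(init)) init <- heuristic_init(family, tvec, dvec, p)
  phi0 <- c(log(init[seq_len(npb)]), init[-seq_len(npb)])
  par_names <- c(nmb, if (p) colnames(X) else character())

  chains <- vector("list", config$n_chains)
  accept <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    start <- phi0
    if (config$init_jitter > 0 && config$n_chains > 1) {
      start <- phi0 + stats::rnorm(length(phi0), 0, config$init_jitter)
    }
    # guard: fall back toward the unjittered start if the posterior vanishes
    tries <- 0
    while (!is.finite(lp_fun(start)) && tries < 20) {
      start <- (start + phi0) / 2
      tries <- tries + 1
    }
    res <- run_rwm_chain(lp_fun, start, config$n_iter, config$n_burn,
                         config$thin, config$target_accept)
    nat <- res$draws
    nat[, idxb] <- exp(nat[, idxb])
    colnames(nat) <- par_names
    chains[[ch]] <- nat
    accept[ch] <- res$accept_rate
  }
  flat <- vapply(chains, function(m) any(apply(m, 2, stats::sd) == 0), logical(1))
  if (any(flat)) {
    warning("Zero-variance chain detected (chain ",
            paste(which(flat), collapse = ", "), ").", call. = FALSE)
  }
  structure(list(
    draws = chains,
    par_names = par_names,
    baseline_names = nmb,
    beta_names = if (p) colnames(X) else character(),
    accept_rate = accept,
    family = family,
    prior = prior,
    config = config,
    data = data
  ), class = "gllph_draws")
}

#' @export
print.gllph_draws <- function(x, ...) {
  cat("<gllph_draws> ", x$family, " PH model: ",
      length(x$draws), " chain(s) x ", nrow(x$draws[[1]]), " retained draws, ",
      "acceptance ", paste(sprintf("%.2f", x$accept_rate), collapse = "/"),
      "\n", sep = "")
  print(summarize_posterior(x)[, c("parameter", "mean", "sd", "q2.5", "q97.5")])
  invisible(x)
}

#' @export
#' @method as_tibble gllph_draws
as_tibble.gllph_draws <- function(x, ...) {
  purrr::map2_dfr(x$draws, seq_along(x$draws), function(m, ch) {
    dplyr::bind_cols(tibble::tibble(.chain = ch, .iteration = seq_len(nrow(m))),
                     tibble::as_tibble(m))
  })
}

pooled_draws <- function(draws, parameter = NULL) {
  m <- do.call(rbind, draws$draws)
  if (is.null(parameter)) m else m[, parameter]
}

# matrix iterations x chains for one parameter
chains_matrix <- function(draws, parameter) {
  sapply(draws$draws, function(m) m[, parameter])
}

hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  j <- which.min(widths)
  c(x[j], x[j + m])
}

posterior_mode <- function(x) {
  # midpoint of the maximal-count histogram bin, Freedman-Diaconis widths
  if (stats::sd(x) == 0) return(x[1])
  br <- tryCatch(graphics::hist(x, breaks = "FD", plot = FALSE),
                 error = function(e) graphics::hist(x, plot = FALSE))
  mean(br$breaks[which.max(br$counts) + 0:1])
}

#' Posterior summary table
#'
#' One row per parameter with the posterior characteristics: mean, SD, naive
#' SE (posterior SD over the square root of the retained draw count),
#' time-series SE (SD over the square root of the effective sample size),
#' minimum, 2.5th percentile, quartiles, 97.5th percentile, maximum, mode
#' (midpoint of the tallest Freedman-Diaconis histogram bin), variance,
#' skewness, excess kurtosis, the 95% equal-tail credible interval, the 95%
#' highest-posterior-density interval, and `P(. > 0 | data)`, the fraction of
#' positive draws.
#'
#' @param draws A `gllph_draws` object.
#' @param prob Credible-interval mass (default 0.95).
#' @return A tibble, one row per parameter.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "gllph_draws"))
  a <- (1 - prob) / 2
  purrr::map_dfr(draws$par_names, function(nm) {
    x <- pooled_draws(draws, nm)
    qs <- stats::quantile(x, c(a, 0.25, 0.5, 0.75, 1 - a), names = FALSE)
    hpd <- hpd_interval(x, prob)
    n_eff <- if (stats::sd(x) == 0) length(x) else ess(x)
    tibble::tibble(
      parameter = nm,
      mean = mean(x), sd = stats::sd(x),
      naive_se = stats::sd(x) / sqrt(length(x)),
      ts_se = stats::sd(x) / sqrt(n_eff),
      min = min(x), q2.5 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4],
      q97.5 = qs[5], max = max(x),
      mode = posterior_mode(x),
      variance = stats::var(x),
      skewness = if (stats::sd(x) == 0) 0 else e1071::skewness(x),
      kurtosis = if (stats::sd(x) == 0) 0 else e1071::kurtosis(x),
      cred.low = qs[1], cred.high = qs[5],
      hpd.low = hpd[1], hpd.high = hpd[2],
      p_positive = mean(x > 0)
    )
  })
}

#' @export
#' @method tidy gllph_draws
tidy.gllph_draws <- function(x, conf.level = 0.95, ...) {
  s <- summarize_posterior(x, prob = conf.level)
  tibble::tibble(term = s$parameter, estimate = s$mean, std.error = s$sd,
                 conf.low = s$cred.low, conf.high = s$cred.high)
}

#' @export
#' @method glance gllph_draws
glance.gllph_draws <- function(x, ...) {
  d <- dic(x)
  tibble::tibble(
    n.chains = length(x$draws),
    n.retained = sum(vapply(x$draws, nrow, integer(1))),
    accept.rate = mean(x$accept_rate),
    max.psrf = if (length(x$draws) > 1)
      max(vapply(x$par_names, function(p) psrf(chains_matrix(x, p)), numeric(1)))
      else NA_real_,
    DIC = d$dic, p.D = d$p_d
  )
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - \hat D}, where
#' \eqn{D(\vartheta) = -2 \ell(\vartheta)} is the deviance, \eqn{\bar D} its
#' posterior mean over the retained draws and \eqn{\hat D} the deviance at
#' the posterior mean of each parameter on the natural scale (plug-in
#' convention). Lower is better.
#'
#' @param draws A `gllph_draws` object.
#' @param data Survival data; defaults to the dataset the draws were fit to.
#' @return A one-row tibble with `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
dic <- function(draws, data = NULL) {
  stopifnot(inherits(draws, "gllph_draws"))
  if (is.null(data)) data <- draws$data
  data <- as_surv_data(data)
  X <- surv_design_matrix(data)
  m <- do.call(rbind, draws$draws)
  dev <- apply(m, 1, function(par) {
    -2 * ph_loglik(par, draws$family, data$time, data$status, X)
  })
  d_bar <- mean(dev)
  d_hat <- -2 * ph_loglik(colMeans(m), draws$family, data$time, data$status, X)
  p_d <- d_bar - d_hat
  tibble::tibble(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' Fit several baseline families and rank them by DIC
#'
#' Fits the Bayesian PH model under each requested baseline family on the
#' same data, prior and sampler budget, and returns the DIC ranking table
#' (lowest DIC first).
#'
#' @param data Survival data frame.
#' @param families Character vector of baseline family tags.
#' @inheritParams sample_posterior
#' @return A tibble with one row per family: DIC, effective number of
#'   parameters, mean deviance, and acceptance diagnostics; attribute
#'   `"fits"` carries the `gllph_draws` objects.
#' @export
compare_models <- function(data, families = c("gll", "weibull", "gompertz"),
                           prior = prior_spec(), config = mcmc_config(),
                           time = "time", status = "status", covariates = NULL) {
  fits <- lapply(families, function(f) {
    sample_posterior(data, family = f, prior = prior, config = config,
                     time = time, status = status, covariates = covariates)
  })
  names(fits) <- families
  tab <- purrr::map2_dfr(fits, families, function(fit, f) {
    d <- dic(fit)
    tibble::tibble(family = f, dic = d$dic, p_d = d$p_d, d_bar = d$d_bar,
                   accept_rate = mean(fit$accept_rate))
  })
  tab <- dplyr::arrange(tab, .data$dic)
  attr(tab, "fits") <- fits
  tab
}
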