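# shared fixtures and oracles, built in code at test time

# a reproducible draw of strictly positive baseline parameters per family
random_baseline <- function(family, rng_scale = 1) {
  k <- stats::runif(1, 0.3, 2) * rng_scale
  alpha <- stats::runif(1, 0.5, 2.5)
  eta <- stats::runif(1, 0.3, 2)
  switch(family,
    exponential = ph_baseline("exponential", k = k),
    weibull = ph_baseline("weibull", k = k, alpha = alpha),
    gompertz = ph_baseline("gompertz", k = k, alpha = alpha),
    gll = ph_baseline("gll", k = k, alpha = alpha, eta = eta)
  )
}

all_families <- c("gll", "exponential", "weibull", "gompertz")

# quadrature oracle for the cumulative hazard
cum_hazard_quadrature <- function(b, t) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(function(u) hazard(b, u), 0, ti,
                     rel.tol = 1e-11, abs.tol = 1e-12)$value
  }, numeric(1))
}

# bisection oracle for quantiles, independent of the closed form
quantile_bisect <- function(b, q, upper = 1e6) {
  vapply(q, function(qi) {
    if (qi == 0) return(0)
    stats::uniroot(function(t) cdf(b, t) - qi, c(0, upper),
                   tol = 1e-12)$root
  }, numeric(1))
}

# small standard GLL-PH dataset used across likelihood/bayes tests
make_test_data <- function(n = 120, seed = 42, tc = 5) {
  sim_ph_data(n, gll_params(0.75, 1.5, 1.25), beta = c(0.75, -0.75, 0.5),
              tc = tc, seed = seed)
}

# independent expanded-form GLL-PH log-likelihood (the a*log(alpha) +
# a*alpha*log(k) + ... form), written directly from the sufficient pieces
gll_loglik_expanded <- function(data, k, alpha, eta, beta) {
  X <- as.matrix(data[, c("age", "treatment", "gender")])
  t <- data$time; d <- data$status
  q <- (eta * t)^alpha
  xb <- drop(X %*% beta)
  a <- sum(d)
  a * log(alpha) + a * alpha * log(k) +
    (alpha - 1) * sum(d * log(t)) -
    sum(d * log1p(q)) +
    sum(d * xb) -
    (k / eta)^alpha * sum(exp(xb) * log1p(q))
}
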