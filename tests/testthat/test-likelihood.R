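test_that("log-likelihood agrees with the expanded GLL-PH form", {
  set.seed(21)
  for (i in 1:10) {
    d <- make_test_data(n = 60, seed = 100 + i)
    k <- runif(1, 0.4, 1.2); alpha <- runif(1, 0.8, 2)
    eta <- runif(1, 0.5, 1.8); beta <- rnorm(3, 0, 0.5)
    m <- ph_model(gll_params(k, alpha, eta), beta)
    expect_equal(log_likelihood(d, m),
                 gll_loglik_expanded(d, k, alpha, eta, beta),
                 tolerance = 1e-9)
  }
})

test_that("uncensored data gives sum of log densities, censored gives -sum H", {
  set.seed(22)
  d <- make_test_data(n = 80, seed = 7)
  b <- gll_params(0.7, 1.4, 1.1)
  m0 <- ph_model(b, c(0, 0, 0))
  d_all_events <- d; d_all_events$status <- 1
  expect_equal(log_likelihood(d_all_events, m0),
               sum(dgll(d$time, 0.7, 1.4, 1.1, log = TRUE)),
               tolerance = 1e-10)
  d_all_cens <- d; d_all_cens$status <- 0
  beta <- c(0.2, -0.3, 0.1)
  m <- ph_model(b, beta)
  X <- as.matrix(d[, c("age", "treatment", "gender")])
  expect_equal(log_likelihood(d_all_cens, m),
               -sum(cum_hazard(b, d$time) * exp(drop(X %*% beta))),
               tolerance = 1e-10)
})

test_that("non-positive baseline parameters give -Inf, not an error", {
  d <- make_test_data(n = 30, seed = 8)
  X <- as.matrix(d[, c("age", "treatment", "gender")])
  expect_identical(
    gllph:::ph_loglik(c(-1, 1.5, 1.25, 0, 0, 0), "gll", d$time, d$status, X),
    -Inf
  )
  expect_identical(
    gllph:::ph_loglik(c(0.75, 0, 1.25, 0, 0, 0), "gll", d$time, d$status, X),
    -Inf
  )
})

test_that("analytic score matches the numerical gradient of the likelihood", {
  set.seed(23)
  n_cfg <- 200
  d <- make_test_data(n = 40, seed = 9)
  max_rel <- 0
  for (i in seq_len(n_cfg)) {
    pars <- c(runif(1, 0.4, 1.3), runif(1, 0.7, 2.2), runif(1, 0.4, 1.8),
              rnorm(3, 0, 0.6))
    m <- ph_model(gll_params(pars[1], pars[2], pars[3]), pars[4:6])
    g <- gll_score(d, m)
    g <- g[c("k", "alpha", "eta", names(m$beta))]
    num <- vapply(seq_along(pars), function(j) {
      h <- 1e-6 * max(1, abs(pars[j]))
      pp <- pars; pm <- pars
      pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
      fp <- log_likelihood(d, ph_model(gll_params(pp[1], pp[2], pp[3]), pp[4:6]))
      fm <- log_likelihood(d, ph_model(gll_params(pm[1], pm[2], pm[3]), pm[4:6]))
      (fp - fm) / (2 * h)
    }, numeric(1))
    rel <- max(abs(g - num) / pmax(1, abs(num)))
    max_rel <- max(max_rel, rel)
  }
  expect_lt(max_rel, 1e-5)
})

test_that("score limiting form: all events, negligible (k/eta)^alpha", {
  d <- make_test_data(n = 50, seed = 10)
  d$status <- 1
  X <- as.matrix(d[, c("age", "treatment", "gender")])
  m <- ph_model(gll_params(1e-6, 1.2, 5), c(0.1, -0.1, 0.2),
                c("age", "treatment", "gender"))
  g <- gll_score(d, m)
  expect_equal(unname(g[c("age", "treatment", "gender")]), unname(colSums(X)),
               tolerance = 1e-6)
})

test_that("likelihood is permutation-invariant and factorizes over censoring flips", {
  set.seed(24)
  d <- make_test_data(n = 60, seed = 11)
  m <- ph_model(gll_params(0.8, 1.3, 1.0), c(0.3, -0.4, 0.2))
  perm <- sample(nrow(d))
  expect_equal(log_likelihood(d, m), log_likelihood(d[perm, ], m),
               tolerance = 1e-10)
  i <- which(d$status == 0)[1]
  d2 <- d; d2$status[i] <- 1
  x_i <- as.numeric(d[i, c("age", "treatment", "gender")])
  expect_equal(log_likelihood(d2, m) - log_likelihood(d, m),
               log(hazard(m, d$time[i], x = x_i)),
               tolerance = 1e-10)
})

test_that("exponential MLE without covariates matches the closed form", {
  set.seed(25)
  d <- tibble::tibble(time = rexp(200, 1.7), status = 1)
  fit <- fit_ph_mle(d, family = "exponential", covariates = character())
  expect_equal(unname(fit$estimate["k"]), sum(d$status) / sum(d$time),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("GLL-PH MLE recovers the truth and is stationary at the optimum", {
  d <- sim_ph_data(5000, gll_params(0.75, 1.5, 1.25), c(0.75, -0.75, 0.5),
                   tc = 1e6, seed = 26)  # effectively uncensored
  fit <- fit_ph_mle(d, "gll")
  truth <- c(k = 0.75, alpha = 1.5, eta = 1.25,
             age = 0.75, treatment = -0.75, gender = 0.5)
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_lt(abs(fit$estimate[nm] - truth[nm]), 3 * fit$se[nm] + 1e-8)
  }
  m_hat <- ph_model(gll_params(fit$estimate["k"], fit$estimate["alpha"],
                               fit$estimate["eta"]),
                    fit$estimate[c("age", "treatment", "gender")])
  g <- gll_score(d, m_hat)
  expect_lt(max(abs(g)) / nrow(d), 1e-4)
})

test_that("refits from perturbed starts reach the same optimum", {
  d <- make_test_data(n = 250, seed = 27)
  fit1 <- fit_ph_mle(d, "gll")
  init2 <- c(0.4, 0.8, 0.6, 0.3, 0.1, -0.2)
  fit2 <- fit_ph_mle(d, "gll", init = init2)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- make_test_data(n = 30, seed = 28)
  d0 <- d; d0$status <- 0
  expect_error(fit_ph_mle(d0, "gll"), "No events")
  dz <- d; dz$time[1] <- 0; dz$status[1] <- 1
  expect_error(fit_ph_mle(dz, "gll"), "time 0")
})
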