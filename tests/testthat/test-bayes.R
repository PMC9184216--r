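test_that("log prior matches the gamma/normal closed forms", {
  pr <- prior_spec()
  # gamma(10, 10) log-density at 1, three baseline parameters
  lg <- dgamma(1, shape = 10, rate = 10, log = TRUE)
  expect_equal(log_prior(c(1, 1, 1), pr, "gll"), 3 * lg)
  # coefficient prior N(0, precision 0.001) at 0
  expect_equal(log_prior(c(1, 1, 1, 0), pr, "gll"),
               3 * lg + 0.5 * log(0.001 / (2 * pi)))
  expect_identical(log_prior(c(-0.1, 1, 1), pr, "gll"), -Inf)
  expect_error(prior_spec(k_shape = -1), "strictly positive")
})

test_that("log posterior decomposes as prior plus likelihood", {
  d <- make_test_data(n = 50, seed = 31)
  pr <- prior_spec()
  par1 <- c(0.75, 1.5, 1.25, 0.3, -0.3, 0.1)
  par2 <- c(0.9, 1.2, 1.0, 0.0, 0.2, -0.1)
  lp <- function(par) {
    m <- ph_model(gll_params(par[1], par[2], par[3]), par[4:6])
    log_prior(par, pr, "gll") + log_likelihood(d, m)
  }
  expect_equal(log_posterior(par1, d, pr) - log_posterior(par2, d, pr),
               lp(par1) - lp(par2), tolerance = 1e-10)
  # duplicating the data doubles the likelihood part exactly
  d2 <- dplyr::bind_rows(d, d)
  attr(d2, "covariates") <- attr(d, "covariates")
  m <- ph_model(gll_params(0.75, 1.5, 1.25), c(0.3, -0.3, 0.1))
  expect_equal(log_likelihood(d2, m), 2 * log_likelihood(d, m), tolerance = 1e-9)
})

test_that("sampler kernel reproduces a known gamma target", {
  # prior-only target: Gamma(10, 10) sampled on the log scale
  lp_fun <- function(phi) dgamma(exp(phi), 10, 10, log = TRUE) + phi
  set.seed(32)
  res <- gllph:::run_rwm_chain(lp_fun, init = 0, n_iter = 22000, n_burn = 2000,
                               thin = 2, target_accept = 0.35)
  x <- exp(drop(res$draws))
  mcse <- sd(x) / sqrt(ess(x))
  expect_lt(abs(mean(x) - 1), 3 * mcse + 0.01)
  expect_equal(sd(x), sqrt(10) / 10, tolerance = 0.05)
})

test_that("exponential-baseline posterior matches the conjugate gamma", {
  set.seed(33)
  latent <- rexp(150, 1.2)
  d <- tibble::tibble(time = pmin(latent, 1.5),
                      status = as.numeric(latent <= 1.5))
  a <- 10; bb <- 10
  dr <- sample_posterior(d, family = "exponential",
                         prior = prior_spec(k_shape = a, k_rate = bb),
                         config = mcmc_config(n_chains = 2, n_iter = 12000,
                                              n_burn = 2000, thin = 2, seed = 5),
                         covariates = character())
  x <- as_tibble(dr)$k
  post_shape <- a + sum(d$status)
  post_rate <- bb + sum(d$time)
  mcse <- sd(x) / sqrt(ess(dr, "k"))
  expect_lt(abs(mean(x) - post_shape / post_rate), 3 * mcse)
  expect_equal(sd(x), sqrt(post_shape) / post_rate, tolerance = 0.1)
})

test_that("sampling is reproducible and respects the thinning contract", {
  d <- make_test_data(n = 60, seed = 34)
  cfg <- mcmc_config(n_chains = 2, n_iter = 900, n_burn = 301, thin = 7, seed = 99)
  dr1 <- sample_posterior(d, config = cfg)
  dr2 <- sample_posterior(d, config = cfg)
  expect_identical(dr1$draws, dr2$draws)
  expect_equal(nrow(dr1$draws[[1]]), (900 - 301) %/% 7)
  expect_true(all(do.call(rbind, dr1$draws)[, c("k", "alpha", "eta")] > 0))
  # a different seed moves the draws
  cfg$seed <- 100L
  dr3 <- sample_posterior(d, config = cfg)
  expect_false(identical(dr1$draws, dr3$draws))
})

test_that("posterior summaries have the documented properties", {
  d <- make_test_data(n = 80, seed = 35)
  dr <- sample_posterior(d, config = mcmc_config(n_chains = 2, n_iter = 2400,
                                                 n_burn = 400, thin = 2, seed = 3))
  s <- summarize_posterior(dr)
  expect_setequal(s$parameter, c("k", "alpha", "eta", "age", "treatment", "gender"))
  expect_equal(s$naive_se, s$sd / sqrt(2 * 1000), tolerance = 1e-12)
  expect_true(all(s$ts_se >= s$naive_se - 1e-12))
  # strictly positive baseline parameters report P(.>0|data) = 1
  expect_equal(s$p_positive[s$parameter %in% c("k", "alpha", "eta")], rep(1, 3))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_true(all(s$hpd.high - s$hpd.low <= s$q97.5 - s$q2.5 + 1e-8))
  # chains are exchangeable: permuting chain order leaves pooled summaries as-is
  dr_perm <- dr
  dr_perm$draws <- rev(dr_perm$draws)
  s2 <- summarize_posterior(dr_perm)
  expect_equal(s$mean, s2$mean, tolerance = 1e-12)
  expect_equal(s$sd, s2$sd, tolerance = 1e-12)
})

test_that("summary moments match oracles on synthetic draws", {
  set.seed(36)
  dr <- list(draws = list(cbind(x = rnorm(2e4))), par_names = "x",
             baseline_names = character(), beta_names = character())
  class(dr) <- "gllph_draws"
  s <- summarize_posterior(dr)
  expect_equal(s$skewness, 0, tolerance = 0.06)
  expect_equal(s$kurtosis, 0, tolerance = 0.12)  # excess convention
  expect_equal(s$p_positive, 0.5, tolerance = 0.02)
  # degenerate draws
  drc <- list(draws = list(cbind(x = rep(2.5, 100))), par_names = "x",
              baseline_names = character(), beta_names = character())
  class(drc) <- "gllph_draws"
  sc <- summarize_posterior(drc)
  expect_equal(sc$mean, 2.5)
  expect_equal(sc$median, 2.5)
  expect_equal(sc$mode, 2.5)
  expect_equal(sc$sd, 0)
  expect_equal(sc$p_positive, 1)
})

test_that("HPD interval agrees with coda on unimodal draws", {
  skip_if_not_installed("coda")
  set.seed(37)
  x <- rgamma(5e4, 4, 2)
  h <- gllph:::hpd_interval(x, 0.95)
  hc <- coda::HPDinterval(coda::mcmc(x), 0.95)
  expect_equal(unname(h), unname(c(hc[1], hc[2])), tolerance = 1e-6)
})

test_that("DIC identities hold, and degenerate draws give pD = 0", {
  d <- make_test_data(n = 60, seed = 38)
  dr <- sample_posterior(d, config = mcmc_config(n_chains = 2, n_iter = 1500,
                                                 n_burn = 500, thin = 2, seed = 4))
  di <- dic(dr)
  expect_equal(di$dic, di$d_bar + di$p_d, tolerance = 1e-10)
  expect_equal(di$dic, di$d_hat + 2 * di$p_d, tolerance = 1e-10)
  # point-mass draws: DIC collapses to the deviance at that point
  par0 <- c(k = 0.75, alpha = 1.5, eta = 1.25,
            age = 0.3, treatment = -0.3, gender = 0.2)
  drc <- dr
  drc$draws <- list(matrix(rep(par0, each = 50), nrow = 50,
                           dimnames = list(NULL, names(par0))))
  dic0 <- dic(drc, d)
  m0 <- ph_model(gll_params(0.75, 1.5, 1.25), c(0.3, -0.3, 0.2))
  expect_equal(dic0$p_d, 0, tolerance = 1e-9)
  expect_equal(dic0$dic, -2 * log_likelihood(d, m0), tolerance = 1e-9)
})
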