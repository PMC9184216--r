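test_that("constructors reject non-positive or missing parameters", {
  expect_error(gll_params(0, 1.5, 1.25), "strictly positive")
  expect_error(gll_params(0.75, -1, 1.25), "strictly positive")
  expect_error(ph_baseline("weibull", k = 1), "alpha")
  expect_error(ph_baseline("exponential", k = -2), "strictly positive")
  expect_s3_class(ph_baseline("gompertz", k = 0.1, alpha = 2), "ph_baseline")
})

test_that("lifetime-function identities hold for every family", {
  set.seed(101)
  tgrid <- 10^seq(-2, 1, length.out = 40)
  for (fam in all_families) {
    for (rep in 1:5) {
      b <- random_baseline(fam)
      H <- cum_hazard(b, tgrid)
      expect_equal(surv(b, tgrid), exp(-H), tolerance = 1e-12)
      expect_equal(cdf(b, tgrid), 1 - surv(b, tgrid), tolerance = 1e-12)
      expect_equal(dens(b, tgrid), hazard(b, tgrid) * surv(b, tgrid),
                   tolerance = 1e-12)
      expect_equal(cum_hazard(b, 0), 0)
      expect_equal(surv(b, 0), 1)
      expect_true(all(diff(H) > 0))
    }
  }
})

test_that("cumulative hazard matches quadrature of the hazard", {
  set.seed(202)
  for (fam in all_families) {
    b <- random_baseline(fam)
    t <- c(0.25, 1, 2.5)
    expect_equal(cum_hazard(b, t), cum_hazard_quadrature(b, t),
                 tolerance = 1e-7)
  }
  # the worked triple
  b <- gll_params(0.75, 1.5, 1.25)
  expect_equal(cum_hazard(b, 2), cum_hazard_quadrature(b, 2), tolerance = 1e-8)
})

test_that("GLL density integrates to one", {
  b <- gll_params(0.75, 1.5, 1.25)
  expect_equal(stats::integrate(function(t) dens(b, t), 0, Inf,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
})

test_that("quantile and cdf are mutual inverses; inverse chf roundtrips", {
  set.seed(303)
  qs <- seq(0.01, 0.99, by = 0.07)
  for (fam in all_families) {
    b <- random_baseline(fam)
    tq <- quantile(b, qs)
    expect_equal(cdf(b, tq), qs, tolerance = 1e-10)
    expect_equal(quantile(b, 0), 0)
    expect_true(all(diff(tq) > 0))
    u <- c(0, 0.3, 0.7, 2, 5)
    expect_equal(cum_hazard(b, inv_cum_hazard(b, u)), u, tolerance = 1e-10)
  }
  # closed forms against the bisection oracle
  b <- gll_params(0.75, 1.5, 1.25)
  expect_equal(quantile(b, 0.5), quantile_bisect(b, 0.5), tolerance = 1e-8)
  expect_equal(inv_cum_hazard(ph_baseline("exponential", k = 2), 6), 3)
  expect_equal(cum_hazard(ph_baseline("exponential", k = 2), 3), 6)
})

test_that("GLL with alpha = 1 collapses to k/(1 + eta t); hazard at 0", {
  b <- gll_params(0.5, 1, 0.25)
  expect_equal(hazard(b, 0), 0.5)
  t <- c(0.5, 1, 4)
  expect_equal(hazard(b, t), 0.5 / (1 + 0.25 * t), tolerance = 1e-12)
  # alpha < 1: hazard diverges at the origin (limit, not an error)
  expect_identical(hazard(gll_params(1, 0.5, 1), 0), Inf)
  expect_identical(hazard(ph_baseline("weibull", k = 1, alpha = 0.5), 0), Inf)
})

test_that("GLL tends to the Weibull as eta -> 0", {
  k <- 0.75; alpha <- 1.5
  bg <- gll_params(k, alpha, 1e-8)
  bw <- ph_baseline("weibull", k = k, alpha = alpha)
  t <- 10^seq(-2, 1, length.out = 30)
  for (f in list(hazard, cum_hazard, surv, cdf, dens)) {
    expect_equal(f(bg, t), f(bw, t), tolerance = 1e-5)
  }
  expect_equal(hazard(bg, c(0.5, 1, 2)), alpha * k * (k * c(0.5, 1, 2))^(alpha - 1),
               tolerance = 1e-6)
  expect_equal(quantile(bg, c(0.1, 0.5, 0.9)), quantile(bw, c(0.1, 0.5, 0.9)),
               tolerance = 1e-5)
})

test_that("GLL with k = eta is the standard log-logistic", {
  alpha <- 1.7; eta <- 0.8
  b <- gll_params(eta, alpha, eta)
  t <- 10^seq(-2, 1, length.out = 30)
  # log-logistic with shape alpha, scale 1/eta: S = 1/(1 + (eta t)^alpha)
  expect_equal(surv(b, t), 1 / (1 + (eta * t)^alpha), tolerance = 1e-12)
  expect_equal(hazard(b, t),
               alpha * eta * (eta * t)^(alpha - 1) / (1 + (eta * t)^alpha),
               tolerance = 1e-12)
  expect_equal(quantile(b, 0.5), 1 / eta, tolerance = 1e-12)
  skip_if_not_installed("flexsurv")
  expect_equal(surv(b, t),
               flexsurv::pllogis(t, shape = alpha, scale = 1 / eta,
                                 lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Weibull and Gompertz closed forms match flexsurv", {
  skip_if_not_installed("flexsurv")
  t <- c(0.3, 1, 2.7)
  bw <- ph_baseline("weibull", k = 0.6, alpha = 1.8)
  expect_equal(dens(bw, t), stats::dweibull(t, shape = 1.8, scale = 1 / 0.6),
               tolerance = 1e-12)
  bg <- ph_baseline("gompertz", k = 0.4, alpha = 0.7)
  # gompertz here: h = alpha k e^{kt}; flexsurv: h = rate e^{shape t}
  expect_equal(hazard(bg, t),
               flexsurv::hgompertz(t, shape = 0.4, rate = 0.7 * 0.4),
               tolerance = 1e-12)
  expect_equal(surv(bg, t),
               flexsurv::pgompertz(t, shape = 0.4, rate = 0.7 * 0.4,
                                   lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("GLL hazard shapes: unimodal and monotone regimes", {
  t <- seq(0.005, 12, length.out = 3000)
  h_uni <- hazard(gll_params(0.75, 2, 2), t)
  sgn <- sign(diff(h_uni))
  runs <- rle(sgn[sgn != 0])$values
  expect_identical(runs, c(1, -1))  # rises then falls
  h_mono <- hazard(gll_params(0.75, 1.5, 1e-6), t)
  expect_true(all(diff(h_mono) > 0))
})

test_that("domain errors are raised", {
  b <- gll_params(0.75, 1.5, 1.25)
  expect_error(hazard(b, -1), "nonnegative")
  expect_error(cum_hazard(b, c(1, -2)), "nonnegative")
  expect_error(quantile(b, 1), "\\[0, 1\\)")
  expect_error(inv_cum_hazard(b, -0.1), "nonnegative")
  expect_error(qgll(1.2, 0.75, 1.5, 1.25), "\\[0, 1\\)")
})
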