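# accept a matrix (iterations x chains), a list of equal-length vectors, or
# a gllph_draws object + parameter name
as_chain_matrix <- function(x, parameter = NULL) {
  if (inherits(x, "gllph_draws")) {
    if (is.null(parameter)) stop("Supply `parameter` with a draws object.", call. = FALSE)
    return(chains_matrix(x, parameter))
  }
  if (is.list(x) && !is.data.frame(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1) stop("Chains must have equal lengths.", call. = FALSE)
    return(do.call(cbind, x))
  }
  as.matrix(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF from parallel chains: with \eqn{W} the mean
#' within-chain variance and \eqn{B/n} the between-chain variance of the
#' chain means, \eqn{\hat V = \frac{n-1}{n} W + \frac{B}{n}} and
#' \eqn{PSRF = \sqrt{\hat V / W}}. Values below 1.1 are conventionally taken
#' as convergence; identical chains give \eqn{\sqrt{(n-1)/n} < 1}. The
#' split-chain variant (each chain halved first) is available via
#' `split = TRUE`.
#'
#' @param x Matrix of draws (iterations in rows, one column per chain), list
#'   of equal-length chain vectors, or a `gllph_draws` object.
#' @param parameter Parameter name when `x` is a draws object.
#' @param split Use split chains (halves each chain before comparison).
#' @return Scalar PSRF.
#' @export
psrf <- function(x, parameter = NULL, split = FALSE) {
  m <- as_chain_matrix(x, parameter)
  if (ncol(m) < 2) stop("PSRF needs at least 2 chains.", call. = FALSE)
  if (nrow(m) < 10) stop("Chains too short for PSRF.", call. = FALSE)
  if (split) {
    h <- nrow(m) %/% 2
    m <- cbind(m[seq_len(h), , drop = FALSE],
               m[(nrow(m) - h + 1):nrow(m), , drop = FALSE])
  }
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) {
    warning("Zero within-chain variance; PSRF defined as 1.", call. = FALSE)
    return(1)
  }
  B_over_n <- stats::var(colMeans(m))
  v_hat <- (n - 1) / n * W + B_over_n
  sqrt(v_hat / W)
}

#' Multivariate potential scale reduction factor
#'
#' Multivariate analogue of [psrf()] via the largest eigenvalue
#' \eqn{\lambda_1} of \eqn{W^{-1} B / n}:
#' \eqn{MPSRF = \sqrt{(n-1)/n + \frac{m+1}{m} \lambda_1}} for \eqn{m} chains.
#'
#' @param x A `gllph_draws` object, or a list of matrices (one per chain,
#'   iterations x parameters).
#' @param parameters Optional subset of parameter names for a draws object.
#' @return Scalar MPSRF.
#' @export
mpsrf <- function(x, parameters = NULL) {
  chains <- if (inherits(x, "gllph_draws")) {
    if (is.null(parameters)) parameters <- x$par_names
    lapply(x$draws, function(m) m[, parameters, drop = FALSE])
  } else {
    lapply(x, as.matrix)
  }
  m <- length(chains)
  if (m < 2) stop("MPSRF needs at least 2 chains.", call. = FALSE)
  n <- nrow(chains[[1]])
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mu <- do.call(rbind, lapply(chains, colMeans))
  B_over_n <- stats::cov(mu)
  lam <- tryCatch({
    e <- eigen(solve(W, B_over_n), only.values = TRUE)$values
    max(Re(e))
  }, error = function(e) NA_real_)
  sqrt((n - 1) / n + (m + 1) / m * lam)
}

# spectral density at frequency zero from a Daniell-smoothed, tapered
# periodogram (fixed window; the estimator behind the Geweke z SEs)
spectrum0 <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  sp <- stats::spec.pgram(x, spans = c(max(3, floor(sqrt(length(x)))),
                                       max(3, floor(sqrt(length(x))))),
                          taper = 0.1, detrend = TRUE, plot = FALSE)
  sp$spec[1]  # R's spectrum integrates to the variance over (-0.5, 0.5]
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac_first` fraction of a chain with the
#' mean of the last `frac_last` fraction, standardized by
#' spectral-density-at-zero standard errors; under stationarity
#' \eqn{z \sim N(0, 1)} approximately.
#'
#' @param x Numeric chain vector (or a `gllph_draws` object with
#'   `parameter`, in which case the chains are concatenated).
#' @param parameter Parameter name when `x` is a draws object.
#' @param frac_first,frac_last Fractions of the chain to compare (defaults
#'   0.1 and 0.5).
#' @return Scalar z; a zero-variance chain returns 0 with a warning.
#' @export
geweke <- function(x, parameter = NULL, frac_first = 0.1, frac_last = 0.5) {
  if (inherits(x, "gllph_draws")) x <- pooled_draws(x, parameter)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100) stop("Chain too short for the Geweke diagnostic.", call. = FALSE)
  if (frac_first + frac_last > 1) stop("Window fractions overlap.", call. = FALSE)
  x1 <- x[seq_len(floor(frac_first * n))]
  x2 <- x[(n - floor(frac_last * n) + 1):n]
  if (stats::sd(x) == 0) {
    warning("Zero-variance chain; Geweke z defined as 0.", call. = FALSE)
    return(0)
  }
  se2 <- spectrum0(x1) / length(x1) + spectrum0(x2) / length(x2)
  (mean(x1) - mean(x2)) / sqrt(se2)
}

#' Autocorrelation, effective sample size and running mean of a chain
#'
#' `autocorr()` returns the sample autocorrelations \eqn{\rho_1, \dots,
#' \rho_{max\_lag}}. `ess()` is \eqn{N / (1 + 2\sum_k \rho_k)} with the sum
#' truncated by Geyer's initial-positive-sequence rule on consecutive lag
#' pairs, and capped at \eqn{N}; iid draws give ESS close to \eqn{N}.
#' `running_mean()` returns the cumulative (ergodic) mean, whose final
#' element equals the chain mean.
#'
#' @param x Numeric chain (or `gllph_draws` + `parameter`; `ess()` then sums
#'   the per-chain estimates).
#' @param parameter Parameter name when `x` is a draws object.
#' @param max_lag Number of autocorrelation lags.
#' @return `autocorr()` numeric vector of length `max_lag`; `ess()` scalar;
#'   `running_mean()` vector as long as the chain.
#' @export
ess <- function(x, parameter = NULL) {
  if (inherits(x, "gllph_draws")) {
    return(sum(vapply(x$draws, function(m) ess(m[, parameter]), numeric(1))))
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("Chain too short for ESS.", call. = FALSE)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 10 * ceiling(sqrt(n))),
                    plot = FALSE, demean = TRUE)$acf[-1]
  # Geyer initial positive sequence on pairs (rho_{2m-1} + rho_{2m})
  npair <- length(rho) %/% 2
  s <- 0
  for (mpair in seq_len(npair)) {
    g <- rho[2 * mpair - 1] + rho[2 * mpair]
    if (g <= 0) break
    s <- s + g
  }
  min(n, n / (1 + 2 * s))
}

#' @rdname ess
#' @export
autocorr <- function(x, parameter = NULL, max_lag = 20) {
  if (inherits(x, "gllph_draws")) x <- pooled_draws(x, parameter)
  x <- as.numeric(x)
  if (length(x) < 10) stop("Chain too short.", call. = FALSE)
  if (stats::sd(x) == 0) return(rep(0, max_lag))
  drop(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1])
}

#' @rdname ess
#' @export
running_mean <- function(x, parameter = NULL) {
  if (inherits(x, "gllph_draws")) x <- pooled_draws(x, parameter)
  x <- as.numeric(x)
  cumsum(x) / seq_along(x)
}

#' Convergence diagnostics report
#'
#' One row per parameter: PSRF, Geweke z with two-sided p, effective sample
#' size, and lag-1/lag-10 autocorrelations, flagged against the package's
#' acceptance thresholds (PSRF < 1.1 and ESS >= 100). The multivariate PSRF
#' is attached as attribute `"mpsrf"`.
#'
#' @param draws A `gllph_draws` object with at least two chains.
#' @param psrf_limit,ess_limit Pass thresholds.
#' @return A tibble, one row per parameter, with a logical `pass` column.
#' @export
diagnose <- function(draws, psrf_limit = 1.1, ess_limit = 100) {
  stopifnot(inherits(draws, "gllph_draws"))
  multi <- length(draws$draws) > 1
  out <- purrr::map_dfr(draws$par_names, function(nm) {
    r <- if (multi) psrf(chains_matrix(draws, nm)) else NA_real_
    z <- geweke(draws$draws[[1]][, nm])
    ne <- ess(draws, nm)
    ac <- autocorr(draws$draws[[1]][, nm], max_lag = 10)
    tibble::tibble(
      parameter = nm, psrf = r, geweke_z = z,
      geweke_p = 2 * stats::pnorm(-abs(z)),
      ess = ne, acf_lag1 = ac[1], acf_lag10 = ac[10],
      pass = (!multi || r < psrf_limit) && ne >= ess_limit
    )
  })
  attr(out, "mpsrf") <- if (multi) mpsrf(draws) else NA_real_
  out
}

#' Scaled total time on test (TTT) transform
#'
#' For order statistics \eqn{t_{(1)} \le \dots \le t_{(n)}}, the scaled TTT
#' statistic at \eqn{i/n} is
#' \deqn{G(i/n) = \frac{\sum_{j \le i} t_{(j)} + (n-i)\, t_{(i)}}
#'       {\sum_j t_{(j)}},}
#' ending at \eqn{G(1) = 1}. The curve's shape diagnoses the hazard: close
#' to the diagonal for a constant hazard (exponential), concave for an
#' increasing hazard, convex for a decreasing hazard, and convex-then-concave
#' for a unimodal hazard. Computed descriptively on all observed times,
#' censored ones included.
#'
#' @param times Nonnegative times, `n >= 2`, not all zero.
#' @return Tibble with columns `fraction` (`i/n`) and `ttt` (`G(i/n)`),
#'   including the origin (0, 0).
#' @examples
#' ttt_statistic(rexp(100))
#' @export
ttt_statistic <- function(times) {
  chk_nonneg(times, "times")
  n <- length(times)
  if (n < 2) stop("Need at least 2 times.", call. = FALSE)
  if (sum(times) == 0) stop("All times are zero.", call. = FALSE)
  ts <- sort(times)
  g <- (cumsum(ts) + (n - seq_len(n)) * ts) / sum(ts)
  tibble::tibble(fraction = c(0, seq_len(n) / n), ttt = c(0, g))
}
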