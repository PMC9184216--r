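#' Simulate the study covariates
#'
#' Emulates a severe-cancer population study: a continuous `age` drawn from a
#' three-component uniform mixture — probability 0.25 on (30, 65), 0.35 on
#' (65, 75) and 0.40 on (75, 85) years — and two binary covariates
#' `treatment` and `gender`, each Bernoulli(0.5). By default `age` is
#' standardized within sample to mean 0 and SD 1 before entering any linear
#' predictor; raw age in the 30–85 range combined with coefficients near
#' 0.75 would make the relative risks \eqn{e^{x'\beta}} astronomically large.
#'
#' @param n Number of subjects.
#' @param standardize_age Standardize `age` to mean 0, SD 1 (default `TRUE`).
#' @param seed Optional integer seed.
#' @return Tibble with columns `age`, `treatment`, `gender`.
#' @examples
#' sim_covariates(5, seed = 1)
#' @export
sim_covariates <- function(n, standardize_age = TRUE, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.25, 0.35, 0.40))
  lo <- c(30, 65, 75)[comp]
  hi <- c(65, 75, 85)[comp]
  age <- stats::runif(n, lo, hi)
  if (standardize_age) {
    age <- if (n > 1 && stats::sd(age) > 0) as.numeric(scale(age)) else age * 0
  }
  tibble::tibble(
    age = age,
    treatment = stats::rbinom(n, 1, 0.5),
    gender = stats::rbinom(n, 1, 0.5)
  )
}

#' Simulate PH event times by cumulative-hazard inversion
#'
#' Uses the inversion identity between the conditional cumulative hazard and
#' a standard uniform: with \eqn{U_i \sim U(0,1)},
#' \deqn{T_i = H_0^{-1}\!\left(\frac{-\log(1 - U_i)}{e^{x_i'\beta}}\right)}
#' follows the PH model with baseline \eqn{H_0} for covariates \eqn{x_i}.
#' For the GLL baseline the closed form of \eqn{H_0^{-1}} is used.
#'
#' @param baseline A [ph_baseline()].
#' @param beta Coefficient vector (use `numeric()` for no covariates).
#' @param X Covariate matrix or data frame with `length(beta)` columns.
#' @param u Optional uniform draws (for deterministic checks); defaults to
#'   `runif(nrow(X))`.
#' @param seed Optional integer seed.
#' @return Vector of latent (uncensored) event times.
#' @export
sim_ph_times <- function(baseline, beta, X, u = NULL, seed = NULL) {
  stopifnot(inherits(baseline, "ph_baseline"))
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) {
    stop("`X` must have length(beta) columns.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(u)) u <- stats::runif(nrow(X))
  if (any(u < 0 | u >= 1)) stop("`u` must lie in [0, 1).", call. = FALSE)
  xb <- if (ncol(X)) drop(X %*% beta) else numeric(nrow(X))
  baseline_inv_cum_hazard(baseline, -log1p(-u) / exp(xb))
}

#' Administrative right-censoring
#'
#' Censors latent event times at a fixed horizon: `time = min(T, tc)`,
#' `status = 1` if the event occurred by `tc`, else 0.
#'
#' @param latent Vector of latent event times. Infinite values are allowed
#'   (heavy-tailed baselines can overflow the double range) and are always
#'   censored.
#' @param tc Censoring horizon (> 0), in the study's time unit.
#' @return Tibble with columns `time`, `status`.
#' @export
apply_censoring <- function(latent, tc) {
  stopifnot(tc > 0)
  if (any(is.na(latent) | latent < 0)) {
    stop("`latent` must be nonnegative.", call. = FALSE)
  }
  tibble::tibble(time = pmin(latent, tc), status = as.numeric(latent <= tc))
}

#' Simulate a right-censored GLL-PH dataset
#'
#' One call to [sim_covariates()], [sim_ph_times()] and [apply_censoring()]:
#' the default study conditions are 3 covariates (standardized age and two
#' Bernoulli(0.5) binaries) and administrative censoring at `tc` years.
#' Under the set-I truth with standardized age this yields about 32%
#' censoring at `tc = 5` and 40% at `tc = 3`.
#'
#' @param n Sample size.
#' @param baseline A [ph_baseline()].
#' @param beta Coefficients for `(age, treatment, gender)`.
#' @param tc Censoring horizon (years).
#' @param standardize_age See [sim_covariates()].
#' @param seed Optional integer seed.
#' @return Survival tibble with columns `time`, `status`, `age`,
#'   `treatment`, `gender`.
#' @examples
#' d <- sim_ph_data(100, gll_params(0.75, 1.5, 1.25),
#'                  beta = c(0.75, -0.75, 0.5), tc = 5, seed = 1)
#' mean(d$status == 0)  # censoring fraction
#' @export
sim_ph_data <- function(n, baseline, beta = c(0.75, -0.75, 0.5), tc = 5,
                        standardize_age = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- sim_covariates(n, standardize_age = standardize_age)
  latent <- sim_ph_times(baseline, beta, as.matrix(X))
  out <- dplyr::bind_cols(apply_censoring(latent, tc), X)
  as_surv_data(out)
}

#' Simulation-study design
#'
#' Bundles the true parameter configuration and the inference settings of a
#' replicated recovery experiment. The two reference configurations are
#' available as shorthands: `"setI"` = GLL(k = 0.75, alpha = 1.5,
#' eta = 1.25) with beta = (0.75, -0.75, 0.5); `"setII"` = GLL(k = 0.95,
#' alpha = 1.75, eta = 1.5) with beta = (0.5, -0.85, 0.5).
#'
#' @param n Sample size per replicate (>= 10).
#' @param baseline True [ph_baseline()], or `"setI"` / `"setII"`.
#' @param beta True coefficient vector (ignored when a shorthand is used).
#' @param tc Administrative censoring horizon (> 0); smaller horizons censor
#'   more heavily.
#' @param n_replicates Number of replicates (>= 1).
#' @param mcmc An [mcmc_config()] for the per-replicate fits.
#' @param prior A [prior_spec()].
#' @param seed Master seed; replicate r uses `seed + r` for data generation
#'   and `seed + 5e5 + r` for its sampler.
#' @param standardize_age See [sim_covariates()].
#' @return A `sim_design` list.
#' @export
sim_design <- function(n, baseline = "setI", beta = NULL, tc = 5,
                       n_replicates = 200,
                       mcmc = mcmc_config(n_iter = 4000, n_burn = 1000, thin = 2),
                       prior = prior_spec(), seed = 1,
                       standardize_age = TRUE) {
  if (is.character(baseline)) {
    baseline <- match.arg(baseline, c("setI", "setII"))
    if (baseline == "setI") {
      beta <- c(0.75, -0.75, 0.5)
      baseline <- gll_params(k = 0.75, alpha = 1.5, eta = 1.25)
    } else {
      beta <- c(0.5, -0.85, 0.5)
      baseline <- gll_params(k = 0.95, alpha = 1.75, eta = 1.5)
    }
  }
  stopifnot(inherits(baseline, "ph_baseline"), n >= 10, tc > 0,
            n_replicates >= 1, length(beta) == 3)
  structure(list(n = as.integer(n), baseline = baseline, beta = beta,
                 tc = tc, n_replicates = as.integer(n_replicates),
                 mcmc = mcmc, prior = prior, seed = as.integer(seed),
                 standardize_age = standardize_age),
            class = "sim_design")
}

design_truth <- function(design) {
  c(baseline_pars(design$baseline),
    stats::setNames(design$beta, c("age", "treatment", "gender")))
}

#' Run a replicated Bayesian recovery study
#'
#' For each replicate: simulate a censored GLL-PH dataset under the design's
#' truth, sample the posterior, and record the posterior mean, SD, 95%
#' equal-tail interval, PSRF and ESS of every parameter. Replicate-level
#' sampler failures are recorded and skipped, not fatal. Aggregation across
#' replicates yields, per parameter: the averaged posterior mean, bias
#' (mean estimate minus truth), MSE (mean squared deviation from truth),
#' naive SE (averaged posterior SD over the square root of the retained draw
#' count), coverage probability (fraction of replicates whose 95% interval
#' contains the truth), and the median PSRF and ESS.
#'
#' @param design A [sim_design()].
#' @param cp_method `"quantile"` scores coverage with the 2.5–97.5 posterior
#'   percentile interval (default); `"normal"` uses the normal-approximation
#'   interval, posterior mean ∓ 1.96 posterior SD.
#' @param verbose Print one line per replicate.
#' @return A `gllph_sim_study`: list with `performance` (the per-parameter
#'   table), `replicates` (per-replicate records), `design`, and the indices
#'   of failed replicates. `tidy()` returns the performance table.
#' @export
run_sim_study <- function(design, cp_method = c("quantile", "normal"),
                          verbose = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  cp_method <- match.arg(cp_method)
  truth <- design_truth(design)
  reps <- vector("list", design$n_replicates)
  failed <- integer()
  for (r in seq_len(design$n_replicates)) {
    rec <- tryCatch({
      d <- sim_ph_data(design$n, design$baseline, design$beta, design$tc,
                       standardize_age = design$standardize_age,
                       seed = design$seed + r)
      cfg <- design$mcmc
      cfg$seed <- design$seed + 500000L + r
      dr <- sample_posterior(d, family = "gll", prior = design$prior, config = cfg)
      s <- summarize_posterior(dr)
      multi <- length(dr$draws) > 1
      s$psrf <- vapply(s$parameter, function(p) {
        if (multi) psrf(chains_matrix(dr, p)) else NA_real_
      }, numeric(1))
      s$ess <- vapply(s$parameter, function(p) ess(dr, p), numeric(1))
      s$replicate <- r
      s$censoring <- mean(d$status == 0)
      s[, c("replicate", "parameter", "mean", "sd", "naive_se",
            "q2.5", "q97.5", "psrf", "ess", "censoring")]
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) failed <- c(failed, r) else reps[[r]] <- rec
    if (verbose) cat("replicate", r, "done\n")
  }
  rep_tbl <- dplyr::bind_rows(reps)
  if (nrow(rep_tbl) == 0) stop("All replicates failed.", call. = FALSE)
  truth_tbl <- tibble::tibble(parameter = names(truth), true = unname(truth))
  perf <- rep_tbl |>
    dplyr::left_join(truth_tbl, by = "parameter") |>
    dplyr::mutate(covered = dplyr::case_when(
      cp_method == "quantile" ~ .data$q2.5 <= .data$true & .data$true <= .data$q97.5,
      TRUE ~ (.data$mean - 1.96 * .data$sd) <= .data$true &
        .data$true <= (.data$mean + 1.96 * .data$sd)
    )) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      true = .data$true[1],
      estimate = mean(.data$mean),
      bias = mean(.data$mean) - .data$true[1],
      naive_se = mean(.data$naive_se),
      mse = mean((.data$mean - .data$true[1])^2),
      cp = mean(.data$covered),
      psrf = stats::median(.data$psrf),
      ess = stats::median(.data$ess),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, names(truth)))
  structure(list(performance = perf, replicates = rep_tbl, design = design,
                 failed = failed, mean_censoring = mean(rep_tbl$censoring)),
            class = "gllph_sim_study")
}

#' @export
print.gllph_sim_study <- function(x, ...) {
  cat("<gllph_sim_study> n =", x$design$n, ", tc =", x$design$tc,
      ",", x$design$n_replicates, "replicates (",
      length(x$failed), "failed ), mean censoring",
      sprintf("%.1f%%", 100 * x$mean_censoring), "\n")
  print(x$performance)
  invisible(x)
}

#' @export
#' @method tidy gllph_sim_study
tidy.gllph_sim_study <- function(x, ...) x$performance

#' @export
#' @method glance gllph_sim_study
glance.gllph_sim_study <- function(x, ...) {
  tibble::tibble(
    n = x$design$n, tc = x$design$tc,
    n_replicates = x$design$n_replicates,
    n_failed = length(x$failed),
    mean_censoring = x$mean_censoring,
    max_abs_bias = max(abs(x$performance$bias)),
    min_cp = min(x$performance$cp),
    max_psrf = max(x$performance$psrf)
  )
}
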