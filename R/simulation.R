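#' Simulation scenario for the grouped measurement-error design
#'
#' Describes one cell of the bias study: `G` ordered exposure groups with mean
#' exposures `mu_base + (g - 1) * delta`, `n_y` subjects per group of which
#' `n_x` have a measured exposure, classical error variance `sigma_eta2`,
#' between-subject variance `sigma_b2`, and a linear or logistic outcome with
#' coefficients `(beta0, beta1)`. Defaults are the reference study
#' conditions: five overlapping groups of 30 subjects, means
#' `0.2 + 0.3 (g - 1)`, `beta0 = -2`, `beta1 = 0.3` (about 13% mean risk for
#' logistic), moderate variances, 200 replications. The residual outcome
#' variance `sigma_eps2 = 1` is a package default; the slope's relative bias
#' is insensitive to it (it scales outcome noise, not the exposure
#' attenuation).
#'
#' @param G Number of ordered groups.
#' @param n_y Subjects per group (outcomes always observed).
#' @param n_x Measured exposures per group (`n_x <= n_y`; `n_x = n_y` means no
#'   missingness).
#' @param delta Between-group contrast in mean exposure (>= 0 keeps the means
#'   nondecreasing).
#' @param mu_base Mean exposure of the first group.
#' @param sigma_b2,sigma_eta2,sigma_eps2 Between-subject, measurement-error
#'   and residual outcome variances.
#' @param beta0,beta1 Outcome model coefficients.
#' @param family `"linear"` or `"logistic"`.
#' @param n_reps Number of simulation replications.
#' @return A list of class `scenario`.
#' @export
scenario <- function(G = 5L, n_y = 30L, n_x = n_y, delta = 0.3,
                     mu_base = 0.2, sigma_b2 = 0.6, sigma_eta2 = 0.5,
                     sigma_eps2 = 1, beta0 = -2, beta1 = 0.3,
                     family = c("linear", "logistic"), n_reps = 200L) {
  family <- match.arg(family)
  stopifnot(G >= 2L, n_y >= 2L, n_x >= 1L, n_x <= n_y, n_reps >= 1L,
            sigma_b2 > 0, sigma_eta2 > 0, sigma_eps2 > 0)
  structure(list(G = as.integer(G), n_y = as.integer(n_y),
                 n_x = as.integer(n_x), delta = delta, mu_base = mu_base,
                 sigma_b2 = sigma_b2, sigma_eta2 = sigma_eta2,
                 sigma_eps2 = sigma_eps2, beta0 = beta0, beta1 = beta1,
                 family = family, n_reps = as.integer(n_reps)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$family, ": G = ", x$G, ", n_y = ", x$n_y,
      ", n_x = ", x$n_x, ", delta = ", x$delta, "\n",
      "  sigma_b2 = ", x$sigma_b2, ", sigma_eta2 = ", x$sigma_eta2,
      if (x$family == "linear") paste0(", sigma_eps2 = ", x$sigma_eps2),
      "\n  beta = (", x$beta0, ", ", x$beta1, "), n_reps = ", x$n_reps,
      "\n", sep = "")
  invisible(x)
}

scenario_mu <- function(sc) sc$mu_base + (seq_len(sc$G) - 1L) * sc$delta

#' Generate one complete dataset from a scenario
#'
#' For each group `g`, draws true exposures `X ~ N(mu_g, sigma_b2)`, measured
#' exposures `W = X + eta` with `eta ~ N(0, sigma_eta2)` and outcomes
#' `Y = beta0 + beta1 X + eps` (linear) or `Y ~ Bernoulli(plogis(beta0 +
#' beta1 X))`. All exposures are observed; use [apply_missingness()] to mask
#' them down to `n_x` per group. The true exposure is kept in column
#' `x_true` for oracle checks only -- estimators never touch it.
#'
#' @param sc A [scenario()].
#' @param seed Optional integer seed (global RNG state is restored).
#' @return A grouped-data tibble with columns `group`, `y`, `w`, `x_true`.
#' @export
generate_dataset <- function(sc, seed = NULL) {
  if (!inherits(sc, "scenario")) abort("`sc` must be a scenario object.")
  with_seed(seed, {
    mu <- scenario_mu(sc)
    g <- rep(seq_len(sc$G), each = sc$n_y)
    x <- rnorm(length(g), mu[g], sqrt(sc$sigma_b2))
    w <- x + rnorm(length(g), 0, sqrt(sc$sigma_eta2))
    y <- if (sc$family == "linear") {
      sc$beta0 + sc$beta1 * x + rnorm(length(g), 0, sqrt(sc$sigma_eps2))
    } else {
      rbinom(length(g), 1L, plogis(sc$beta0 + sc$beta1 * x))
    }
    tibble(group = g, y = y, w = w, x_true = x)
  })
}

#' Mask exposures down to n_x observed measurements per group
#'
#' Keeps a simple random sample of `n_x` measured exposures in each group and
#' sets the rest to missing; outcomes are untouched. This is missingness
#' completely at random, ignorable in the likelihood.
#'
#' @param data A grouped dataset.
#' @param n_x Number of exposures to keep per group.
#' @param seed Optional integer seed.
#' @return The dataset with `w` masked.
#' @export
apply_missingness <- function(data, n_x, seed = NULL) {
  data <- as_grouped_data(data)
  counts <- group_counts(data)
  if (any(n_x > counts$n_total)) abort("`n_x` exceeds a group's size.")
  with_seed(seed, {
    for (g in counts$group) {
      idx <- which(data$group == g)
      keep <- sample(idx, n_x)
      data$w[setdiff(idx, keep)] <- NA_real_
    }
    data
  })
}

#' Run a bias/MSE experiment across scenarios and methods
#'
#' For every scenario x method combination, generates `n_reps` independent
#' datasets (a fresh dataset and a fresh missingness mask per replication,
#' with per-replication seeds derived deterministically from `seed`), fits
#' the method, and summarizes the slope estimates as mean relative bias in
#' percent of the true slope, `100 * (mean(beta1_hat) - beta1) / beta1`,
#' with the empirical MSE on the raw slope scale and the Monte-Carlo standard
#' error of the bias estimate. Replications where a fit fails (e.g. complete
#' separation, or isotonized scores pooled to a single value) are dropped and
#' counted. The method `"oracle"` regresses the outcome on the true exposure
#' and is available for calibration checks.
#'
#' @param scenarios A [scenario()] or list of scenarios.
#' @param methods Character vector from `"naive"`, `"gbs"`, `"cgbs"`,
#'   `"cem"`, `"oracle"`.
#' @param seed Master integer seed.
#' @param cem_options Options passed to [fit_cem()] (standard errors are
#'   skipped during the sweep).
#' @return A tibble of class `bias_table`: one row per scenario x method with
#'   scenario descriptors, `bias_pct`, `mse`, `mc_se_bias_pct`, `n_used`,
#'   `n_fail`.
#' @export
run_experiment <- function(scenarios, methods = c("naive", "gbs", "cgbs", "cem"),
                           seed = 1L, cem_options = NULL) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  if (!length(scenarios) || !length(methods)) {
    abort("`scenarios` and `methods` must be non-empty.")
  }
  bad <- setdiff(methods, c("naive", "gbs", "cgbs", "cem", "oracle"))
  if (length(bad)) abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  rows <- list()
  for (ci in seq_along(scenarios)) {
    sc <- scenarios[[ci]]
    est <- matrix(NA_real_, sc$n_reps, length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(sc$n_reps)) {
      s_data <- child_seed(seed, ci, r, 1L)
      s_miss <- child_seed(seed, ci, r, 2L)
      d <- generate_dataset(sc, seed = s_data)
      if (sc$n_x < sc$n_y) d <- apply_missingness(d, sc$n_x, seed = s_miss)
      for (m in methods) {
        est[r, m] <- tryCatch(
          suppressWarnings(fit_one_method(d, m, sc, child_seed(seed, ci, r, 3L),
                                          cem_options)),
          error = function(e) NA_real_)
      }
    }
    for (m in methods) {
      b <- est[, m]
      ok <- is.finite(b)
      rows[[length(rows) + 1L]] <- tibble(
        scenario = ci, family = sc$family, delta = sc$delta,
        sigma_b2 = sc$sigma_b2, sigma_eta2 = sc$sigma_eta2,
        n_y = sc$n_y, n_x = sc$n_x, method = m,
        bias_pct = 100 * (mean(b[ok]) - sc$beta1) / sc$beta1,
        mse = mean((b[ok] - sc$beta1)^2),
        mc_se_bias_pct = 100 * sd(b[ok]) / sqrt(sum(ok)) / abs(sc$beta1),
        n_used = sum(ok), n_fail = sum(!ok))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bias_table", class(out))
  out
}

fit_one_method <- function(d, method, sc, cem_seed, cem_opts) {
  if (method == "oracle") {
    d2 <- d
    d2$w <- d$x_true
    return(fit_naive(d2, sc$family)$beta1_hat)
  }
  if (method == "cem") {
    opts <- cem_opts %||% cem_options()
    opts$seed <- cem_seed
    return(fit_cem(d, sc$family, sigma_eta2 = sc$sigma_eta2,
                   options = opts, se = FALSE)$beta1_hat)
  }
  fit_exposure(d, method = method, family = sc$family)$beta1_hat
}

#' Synthetic dataset mimicking an occupational dust-exposure study
#'
#' Generates a synthetic grouped dataset with the published structure of a
#' large European carbon-black manufacturing survey: 8 job-category groups of
#' sizes (245, 240, 129, 224, 157, 192, 174, 53), nondecreasing log-exposure
#' means spaced by 0.36, between-subject variance 0.41 and measurement-error
#' variance 0.92, with a linear outcome. Only the group structure and
#' variance components match the published summary; all individual values are
#' synthetic draws. Intended for integration tests and documentation, not for
#' reproducing the original study's estimates.
#'
#' @param beta0,beta1 Outcome model coefficients for the synthetic outcome.
#' @param mu_base Log-exposure mean of the lowest group.
#' @param sigma_eps2 Residual outcome variance.
#' @param seed Optional integer seed.
#' @return A grouped-data tibble with `group`, `y`, `w`, `x_true`.
#' @export
generate_carbonblack_like <- function(beta0 = -2, beta1 = 0.3, mu_base = 0.2,
                                      sigma_eps2 = 1, seed = NULL) {
  sizes <- c(245L, 240L, 129L, 224L, 157L, 192L, 174L, 53L)
  delta <- 0.36; sigma_b2 <- 0.41; sigma_eta2 <- 0.92
  with_seed(seed, {
    mu <- mu_base + (seq_along(sizes) - 1L) * delta
    g <- rep(seq_along(sizes), times = sizes)
    x <- rnorm(length(g), mu[g], sqrt(sigma_b2))
    w <- x + rnorm(length(g), 0, sqrt(sigma_eta2))
    y <- beta0 + beta1 * x + rnorm(length(g), 0, sqrt(sigma_eps2))
    tibble(group = g, y = y, w = w, x_true = x)
  })
}
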