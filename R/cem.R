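#' Options for the constrained (Monte Carlo) EM estimator
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the maximum relative parameter change
#'   between successive iterations; defaults to `1e-5` for the linear family
#'   (exact E-step) and `1e-4` for logistic, where the common-random-numbers
#'   E-step makes each phase a deterministic fixed-point iteration.
#' @param mc_draws_initial,mc_draws_final Importance-sampling draws per record
#'   in early iterations and after `draw_escalation_iter` (logistic family
#'   only; the linear E-step is closed form).
#' @param draw_escalation_iter Iteration after which the draw count escalates.
#' @param ess_floor Minimum acceptable effective sample size of the
#'   importance weights, as a fraction of the draw count; falling below it
#'   signals proposal failure and triggers draw escalation.
#' @param seed Optional integer seed making the Monte-Carlo E-step
#'   reproducible (global RNG state is restored afterwards).
#' @param constrained Enforce the nondecreasing order on the group means in
#'   every M-step (isotonized update).
#' @param quad_points Gauss-Hermite nodes for the observed-data log-likelihood
#'   trace.
#' @return A list of class `cem_options`.
#' @export
cem_options <- function(max_iter = 500L, tol = NULL,
                        mc_draws_initial = 200L, mc_draws_final = 2000L,
                        draw_escalation_iter = 20L, ess_floor = 0.02,
                        seed = NULL, constrained = TRUE, quad_points = 41L) {
  stopifnot(max_iter >= 1L, mc_draws_initial >= 50L,
            mc_draws_final >= mc_draws_initial,
            draw_escalation_iter >= 1L, ess_floor > 0, ess_floor < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 mc_draws_initial = as.integer(mc_draws_initial),
                 mc_draws_final = as.integer(mc_draws_final),
                 draw_escalation_iter = as.integer(draw_escalation_iter),
                 ess_floor = ess_floor, seed = seed,
                 constrained = isTRUE(constrained),
                 quad_points = as.integer(quad_points)),
            class = "cem_options")
}

#' E-step: posterior moments of the latent exposures
#'
#' Computes, at the current parameter value, the per-record posterior
#' expectations `E[X]` and `E[X^2]` of the latent true exposure given the
#' observables. For the linear family these are the exact closed forms of
#' [posterior_x_moments()] (observed exposure) and [posterior_xw_missing()]
#' (missing exposure). For the logistic family they are computed by
#' self-normalized importance sampling: observed records draw from the
#' Gaussian "prior x measurement" proposal
#' `N((sigma_b2 w + sigma_eta2 mu_g)/(sigma_b2+sigma_eta2),
#' sigma_b2 sigma_eta2/(sigma_b2+sigma_eta2))` with Bernoulli outcome weights;
#' missing records draw from the prior `N(mu_g, sigma_b2)`. The proposal is
#' exact when `beta1 = 0` (uniform weights) and mildly mismatched otherwise;
#' the per-record effective sample size is monitored.
#'
#' @param data A grouped dataset.
#' @param theta Current [theta()] value.
#' @param options A [cem_options()] list.
#' @param n_draws Number of importance draws per record (logistic family);
#'   defaults to `options$mc_draws_initial`.
#' @param base_draws Optional records x draws matrix of standard-normal
#'   variates to transform through the proposal instead of fresh draws.
#'   [fit_cem()] passes a fixed matrix so that successive E-steps share common
#'   random numbers: the EM map is then deterministic given the draws, which
#'   removes the Monte-Carlo random walk around the maximizer and lets an
#'   ordinary parameter-change convergence test apply.
#' @return A list of class `expected_stats`: `ex`, `ex2` (per record), and for
#'   the logistic family `draws` and `weights` matrices (records x draws) plus
#'   `ess` (effective sample size fraction per record).
#' @export
cem_estep <- function(data, theta, options = cem_options(), n_draws = NULL,
                      base_draws = NULL) {
  data <- as_grouped_data(data)
  if (!is_theta(theta)) abort("`theta` must be a semiecol_theta object.")
  obs <- !is.na(data$w)
  n <- nrow(data)
  if (identical(theta$family, "linear")) {
    ex <- numeric(n); ex2 <- numeric(n)
    if (any(obs)) {
      mom <- posterior_x_moments(data$y[obs], data$w[obs], data$group[obs], theta)
      ex[obs] <- mom$mean; ex2[obs] <- mom$var + mom$mean^2
    }
    if (any(!obs)) {
      mom <- posterior_xw_missing(data$y[!obs], data$group[!obs], theta)
      ex[!obs] <- mom$mean; ex2[!obs] <- mom$var_x + mom$mean^2
    }
    return(structure(list(ex = ex, ex2 = ex2, obs = obs, family = "linear"),
                     class = "expected_stats"))
  }
  check_binary_outcome(data$y)
  K <- if (!is.null(base_draws)) ncol(base_draws) else
    as.integer(n_draws %||% options$mc_draws_initial)
  g <- data$group
  prop_mean <- ifelse(obs,
                      (theta$sigma_b2 * ifelse(is.na(data$w), 0, data$w) +
                         theta$sigma_eta2 * theta$mu[g]) /
                        (theta$sigma_b2 + theta$sigma_eta2),
                      theta$mu[g])
  prop_var <- ifelse(obs,
                     theta$sigma_b2 * theta$sigma_eta2 /
                       (theta$sigma_b2 + theta$sigma_eta2),
                     theta$sigma_b2)
  draws <- if (!is.null(base_draws)) {
    prop_mean + sqrt(prop_var) * base_draws
  } else {
    matrix(rnorm(n * K, mean = prop_mean, sd = sqrt(prop_var)), n, K)
  }
  eta <- theta$beta0 + theta$beta1 * draws
  sgn <- 2 * data$y - 1  # Bernoulli loglik = log plogis(sgn * eta), sgn recycles by row
  logw <- plogis(sgn * eta, log.p = TRUE)
  logw <- logw - apply(logw, 1L, max)
  wt <- exp(logw)
  wt <- wt / rowSums(wt)
  ess <- 1 / rowSums(wt^2) / K
  if (min(ess) < options$ess_floor) {
    warn(paste0("importance-sampling effective sample size dropped to ",
                format(min(ess) * K, digits = 3), " of ", K,
                " draws for some record; consider more draws."),
         class = "semiecol_low_ess")
  }
  ex <- rowSums(wt * draws)
  ex2 <- rowSums(wt * draws^2)
  structure(list(ex = ex, ex2 = ex2, obs = obs, family = "logistic",
                 draws = draws, weights = wt, ess = ess),
            class = "expected_stats")
}

#' M-step: constrained update of the parameter vector
#'
#' Maximizes the expected complete-data log-likelihood from [cem_estep()].
#' The objective separates: (1) the group means are updated to the per-group
#' averages of `E[X]` over all records (observed and missing exposure), then
#' projected onto the nondecreasing cone by [pava()] with total group counts
#' as weights when `constrained`; (2) `sigma_b2` is the mean of
#' `E[(X - mu_g)^2]`; (3) for the linear family `(beta0, beta1)` solve the
#' normal equations in `(E[X], E[X^2])` and `sigma_eps2` is the mean expected
#' squared residual; for logistic, `(beta0, beta1)` maximize the
#' importance-weighted expected Bernoulli log-likelihood by Newton iterations.
#' The known `sigma_eta2` is untouched.
#'
#' @param stats An `expected_stats` object computed at `theta`.
#' @param data The grouped dataset.
#' @param theta Current parameter value.
#' @param constrained Apply the isotonic projection to the group means.
#' @return The updated [theta()].
#' @export
cem_mstep <- function(stats, data, theta, constrained = TRUE) {
  data <- as_grouped_data(data)
  if (!inherits(stats, "expected_stats")) abort("`stats` must come from cem_estep().")
  g <- data$group
  G <- length(theta$mu)
  n_total <- tabulate(g, nbins = G)
  mu_raw <- as.numeric(tapply(stats$ex, factor(g, levels = seq_len(G)), mean))
  mu_new <- if (constrained) pava(mu_raw, n_total)$fitted else mu_raw
  sb2_new <- max(mean(stats$ex2 - 2 * mu_new[g] * stats$ex + mu_new[g]^2), 1e-8)
  y <- data$y
  if (identical(theta$family, "linear")) {
    n <- length(y)
    sx <- sum(stats$ex); sy <- sum(y)
    sxx <- sum(stats$ex2); sxy <- sum(y * stats$ex)
    den <- sxx - sx^2 / n
    if (abs(den) < .Machine$double.eps * 100 * max(1, sxx)) {
      abort("singular normal equations in the M-step (no exposure contrast).")
    }
    b1 <- (sxy - sx * sy / n) / den
    b0 <- (sy - b1 * sx) / n
    seps2 <- max(mean(y^2 - 2 * y * (b0 + b1 * stats$ex) + b0^2 +
                        2 * b0 * b1 * stats$ex + b1^2 * stats$ex2), 1e-8)
    return(theta(beta0 = b0, beta1 = b1, mu = mu_new, sigma_b2 = sb2_new,
                 sigma_eta2 = theta$sigma_eta2, sigma_eps2 = seps2,
                 family = "linear"))
  }
  beta <- newton_logistic_q(y, stats$draws, stats$weights,
                            c(theta$beta0, theta$beta1))
  theta(beta0 = beta[1], beta1 = beta[2], mu = mu_new, sigma_b2 = sb2_new,
        sigma_eta2 = theta$sigma_eta2, family = "logistic")
}

# Newton maximization of sum_i sum_k wt[i,k] * Bernoulli loglik(y_i | x[i,k])
newton_logistic_q <- function(y, draws, wt, start, max_iter = 50L,
                              tol = 1e-9) {
  b <- start
  sgn <- 2 * y - 1
  qfun <- function(b) {
    eta <- b[1] + b[2] * draws
    sum(wt * plogis(sgn * eta, log.p = TRUE))
  }
  q_old <- qfun(b)
  for (it in seq_len(max_iter)) {
    eta <- b[1] + b[2] * draws
    p <- plogis(eta)
    r <- wt * (y - p)
    g1 <- sum(r); g2 <- sum(r * draws)
    pq <- wt * p * (1 - p)
    h11 <- sum(pq); h12 <- sum(pq * draws); h22 <- sum(pq * draws^2)
    det_h <- h11 * h22 - h12^2
    if (!is.finite(det_h) || det_h <= .Machine$double.eps * 100) {
      abort("singular Hessian in the logistic M-step Newton iterations.")
    }
    step <- c(h22 * g1 - h12 * g2, h11 * g2 - h12 * g1) / det_h
    # damped update: halve until the expected log-likelihood does not drop
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      q_new <- qfun(b_new)
      if (is.finite(q_new) && q_new >= q_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) {
        abort(paste0("Newton iterations failed to increase the expected ",
                     "log-likelihood (iteration ", it, ")."),
              class = "semiecol_newton_error")
      }
    }
    conv <- max(abs(b_new - b)) < tol * (1 + max(abs(b)))
    b <- b_new; q_old <- q_new
    if (conv) return(b)
  }
  warn("logistic M-step Newton iterations hit max_iter without full convergence.",
       class = "semiecol_newton_warning")
  b
}

#' Constrained (Monte Carlo) EM estimator
#'
#' Maximum-likelihood estimation of the outcome model and exposure
#' distribution under classical measurement error with known error variance
#' and (optionally) missing exposures, with the group means constrained to be
#' nondecreasing. The algorithm alternates the E-step of [cem_estep()] with
#' the order-constrained M-step of [cem_mstep()], starting from the naive
#' estimates, and reports Meilijson empirical-information standard errors for
#' the slope. For the linear family the E-step is exact and every iteration
#' increases the observed-data log-likelihood; the logistic family uses a
#' Monte-Carlo E-step over a fixed (common-random-numbers) draw matrix whose
#' size escalates after `options$draw_escalation_iter` iterations (or earlier
#' on importance-weight degeneracy), making each phase a deterministic
#' fixed-point iteration so that convergence can be declared on the parameter
#' change between successive iterations.
#'
#' Groups in which no subject has a measured exposure are supported: their
#' records inform the fit through the missing-exposure posterior only.
#'
#' @param data A grouped dataset.
#' @param family `"linear"` or `"logistic"`.
#' @param sigma_eta2 Known measurement-error variance (> 0).
#' @param options A [cem_options()] list (`options$constrained` switches the
#'   isotonic projection on or off; `options$seed` fixes the Monte-Carlo
#'   draws).
#' @param se Compute the Meilijson standard error of the slope (disable for
#'   large simulation sweeps).
#' @return A `semiecol_fit` with estimates, standard error, convergence trace
#'   (`$trace`: iteration, observed-data log-likelihood, parameters) and
#'   iteration count.
#' @examples
#' d <- generate_dataset(scenario(n_y = 30), seed = 3)
#' fit_cem(d, "linear", sigma_eta2 = 0.5,
#'         options = cem_options(max_iter = 200))
#' @export
fit_cem <- function(data, family = c("linear", "logistic"), sigma_eta2,
                    options = cem_options(), se = TRUE) {
  family <- match.arg(family)
  data <- as_grouped_data(data)
  if (!is.numeric(sigma_eta2) || length(sigma_eta2) != 1L ||
      !is.finite(sigma_eta2) || sigma_eta2 <= 0) {
    abort("`sigma_eta2` must be a positive scalar (known error variance).")
  }
  if (family == "logistic") check_binary_outcome(data$y)
  tol <- options$tol %||% if (family == "linear") 1e-5 else 1e-4
  counts <- group_counts(data)
  G <- max(data$group)
  if (sum(counts$n_obs) < 2L) {
    abort("need at least two observed exposure measurements overall.")
  }

  cur <- init_theta(data, counts, family, sigma_eta2, options$constrained)

  with_seed(options$seed, {
    n <- nrow(data)
    # common random numbers: the importance draws are fixed once per draw
    # level, so each MCEM phase is a deterministic fixed-point iteration
    z_init <- z_final <- NULL
    if (family == "logistic") {
      z_init <- matrix(rnorm(n * options$mc_draws_initial), n)
      z_final <- matrix(rnorm(n * options$mc_draws_final), n)
    }
    trace <- vector("list", options$max_iter)
    converged <- FALSE
    it <- 0L
    escalated <- FALSE
    while (it < options$max_iter) {
      it <- it + 1L
      final_phase <- family == "linear" || escalated ||
        it > options$draw_escalation_iter
      low_ess <- FALSE
      stats <- withCallingHandlers(
        cem_estep(data, cur, options,
                  base_draws = if (family == "logistic") {
                    if (final_phase) z_final else z_init
                  }),
        semiecol_low_ess = function(w) {
          low_ess <<- TRUE
          invokeRestart("muffleWarning")
        }
      )
      if (low_ess && !final_phase) escalated <- TRUE
      new <- cem_mstep(stats, data, cur, constrained = options$constrained)
      trace[[it]] <- tibble(
        iter = it,
        loglik = observed_data_loglik(data, new, options$quad_points),
        beta0 = new$beta0, beta1 = new$beta1,
        sigma_b2 = new$sigma_b2,
        sigma_eps2 = if (family == "linear") new$sigma_eps2 else NA_real_)
      relchg <- max(abs(theta_to_vector(new) - theta_to_vector(cur)) /
                      (abs(theta_to_vector(cur)) + 1e-8))
      cur <- new
      if (final_phase && relchg < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      warn(paste0("EM did not meet the convergence tolerance within ",
                  options$max_iter, " iterations."),
           class = "semiecol_em_nonconvergence")
    }
    se_b1 <- NA_real_
    if (se) {
      se_b1 <- tryCatch(se_meilijson(data, cur, options),
                        error = function(e) {
                          warn(paste0("standard error unavailable: ",
                                      conditionMessage(e)))
                          NA_real_
                        })
    }
    new_fit_result(
      method = if (options$constrained) "cem" else "cem_unconstrained",
      family = family, beta0_hat = cur$beta0, beta1_hat = cur$beta1,
      se_beta1 = se_b1, se_inflated = FALSE, mu_hat = cur$mu,
      sigma_b2_hat = cur$sigma_b2,
      sigma_eps2_hat = if (family == "linear") cur$sigma_eps2 else NA_real_,
      converged = converged, n_iterations = it,
      trace = dplyr::bind_rows(trace[seq_len(it)]), sigma_eta2 = sigma_eta2)
  })
}

# Naive initialization: complete-case regression for (beta0, beta1,
# sigma_eps2), observed group means for mu (overall observed mean for groups
# with no measurement), method-of-moments sigma_b2 floored at 1e-4.
init_theta <- function(data, counts, family, sigma_eta2, constrained) {
  cc <- data[!is.na(data$w), ]
  nb <- fit_glm(cc$y, cc$w, family)
  mu0 <- rep(mean(cc$w), max(data$group))
  has <- counts$n_obs > 0L
  if (any(has)) {
    w_bar <- tapply(cc$w, factor(cc$group, levels = counts$group), mean)
    mu0[has] <- as.numeric(w_bar[has])
  }
  if (constrained) mu0 <- pava(mu0, counts$n_total)$fitted
  g_fac <- factor(cc$group, levels = counts$group)
  n_eff <- sum(counts$n_obs >= 2L)
  sb2 <- if (n_eff > 0L && sum(counts$n_obs) > n_eff) {
    centered <- cc$w - ave(cc$w, g_fac)
    sum(centered^2) / (sum(counts$n_obs) - sum(counts$n_obs > 0L))
  } else {
    var(cc$w)
  }
  sb2 <- max(sb2 - sigma_eta2, 1e-4)
  seps2 <- if (family == "linear") {
    max(mean((cc$y - nb$beta0 - nb$beta1 * cc$w)^2), 1e-4)
  } else NULL
  theta(beta0 = nb$beta0, beta1 = nb$beta1, mu = mu0, sigma_b2 = sb2,
        sigma_eta2 = sigma_eta2, sigma_eps2 = seps2, family = family)
}
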