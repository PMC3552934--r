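#' Naive complete-case regression on mismeasured exposure
#'
#' Regresses the outcome directly on the error-prone measurement `w`,
#' dropping records with missing `w` and ignoring measurement error. Under
#' classical error the slope is attenuated toward zero by the reliability
#' ratio `var(X) / (var(X) + sigma_eta2)`; this estimator is the baseline the
#' corrected methods are compared against.
#'
#' @param data A grouped dataset (see [as_grouped_data()]).
#' @param family `"linear"` or `"logistic"`.
#' @return A `semiecol_fit` object.
#' @examples
#' d <- generate_dataset(scenario(), seed = 1)
#' fit_naive(d, "linear")
#' @export
fit_naive <- function(data, family = c("linear", "logistic")) {
  family <- match.arg(family)
  data <- as_grouped_data(data)
  cc <- data[!is.na(data$w), ]
  if (!nrow(cc)) abort("all exposure measurements are missing; nothing to regress on.")
  if (var(cc$w) < .Machine$double.eps * 100) {
    abort("observed `w` is constant; the regression design is degenerate.")
  }
  fit <- fit_glm(cc$y, cc$w, family)
  new_fit_result(method = "naive", family = family,
                 beta0_hat = fit$beta0, beta1_hat = fit$beta1,
                 se_beta1 = fit$se_beta1, se_inflated = FALSE)
}

# shared ML regression of y on a single regressor, with a separation guard
fit_glm <- function(y, x, family) {
  if (family == "linear") {
    f <- lm(y ~ x)
    cf <- coef(f)
    return(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                se_beta1 = sqrt(vcov(f)[2, 2])))
  }
  check_binary_outcome(y)
  sep <- FALSE
  f <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (sep || !f$converged || any(abs(coef(f)) > 1e3)) {
    abort("logistic fit failed (complete separation or non-convergence).",
          class = "semiecol_separation_error")
  }
  cf <- coef(f)
  list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
       se_beta1 = sqrt(vcov(f)[2, 2]))
}

#' Group exposure scores, optionally order-constrained
#'
#' Computes each group's mean observed exposure and, when `constrained = TRUE`,
#' replaces the mean vector by its weighted isotonic regression ([pava()])
#' with weights equal to the observed sample sizes, enforcing the hypothesized
#' nondecreasing ordering of group mean exposures. Every subject of a group is
#' assigned the group's score (single imputation).
#'
#' @param data A grouped dataset; every group needs at least one observed
#'   exposure.
#' @param constrained Isotonize the scores (CGBS) or use raw group means (GBS).
#' @return A tibble of class `score_assignment` with one row per group:
#'   `group`, `n_obs`, `w_bar` (raw mean) and `score`.
#' @examples
#' d <- generate_dataset(scenario(), seed = 1)
#' assign_scores(d, constrained = TRUE)
#' @export
assign_scores <- function(data, constrained = TRUE) {
  data <- as_grouped_data(data)
  counts <- group_counts(data)
  if (any(counts$n_obs == 0L)) {
    abort(paste0("group(s) ", paste(counts$group[counts$n_obs == 0L], collapse = ", "),
                 " have no observed exposure; group-based scores are undefined ",
                 "(the EM estimator handles such groups)."))
  }
  obs <- data[!is.na(data$w), ]
  w_bar <- as.numeric(tapply(obs$w, factor(obs$group, levels = counts$group), mean))
  score <- if (constrained) pava(w_bar, counts$n_obs)$fitted else w_bar
  out <- tibble(group = counts$group, n_obs = counts$n_obs,
                w_bar = w_bar, score = score)
  class(out) <- c("score_assignment", class(out))
  attr(out, "constrained") <- constrained
  out
}

#' Group-based (GBS) and constrained group-based (CGBS) estimators
#'
#' Assigns each subject their group's exposure score (raw or isotonized group
#' mean, see [assign_scores()]) and fits a standard regression of all outcomes
#' -- including those of subjects without a measured exposure -- on the score.
#' The model-based standard error is reported with `se_inflated = TRUE`: it
#' understates the uncertainty because within-group exposure variation is
#' collapsed onto a single score.
#'
#' @inheritParams assign_scores
#' @param family `"linear"` or `"logistic"`.
#' @return A `semiecol_fit` object (`method` = `"cgbs"` or `"gbs"`).
#' @examples
#' d <- apply_missingness(generate_dataset(scenario(), seed = 1), n_x = 10,
#'                        seed = 2)
#' fit_group_based(d, "linear", constrained = TRUE)
#' @export
fit_group_based <- function(data, family = c("linear", "logistic"),
                            constrained = TRUE) {
  family <- match.arg(family)
  data <- as_grouped_data(data)
  sc <- assign_scores(data, constrained = constrained)
  s <- sc$score[data$group]
  if (var(s) < .Machine$double.eps * 100) {
    abort("all group scores are equal (no exposure contrast); the fit is undefined.",
          class = "semiecol_no_contrast_error")
  }
  fit <- fit_glm(data$y, s, family)
  new_fit_result(method = if (constrained) "cgbs" else "gbs", family = family,
                 beta0_hat = fit$beta0, beta1_hat = fit$beta1,
                 se_beta1 = fit$se_beta1, se_inflated = TRUE,
                 mu_hat = sc$score, scores = sc)
}

#' Reliability of a group mean as a proxy for individual exposure
#'
#' The regression coefficient `m = cov(X, W_bar) / var(W_bar)` of a subject's
#' true exposure on their group's mean measurement. Both covariance and
#' variance scale as `1/n_g`, so the group size cancels and
#' `m = sigma_b2 / (sigma_b2 + sigma_eta2)`. Values near 1 indicate that
#' assigning the group mean behaves like a (quasi-)Berkson error model with
#' little bias.
#'
#' @param sigma_b2 Between-subject exposure variance (> 0).
#' @param sigma_eta2 Measurement-error variance (> 0).
#' @return The reliability `m` in (0, 1].
#' @examples
#' reliability_m(0.6, 0.5)
#' @export
reliability_m <- function(sigma_b2, sigma_eta2) {
  if (sigma_b2 <= 0 || sigma_eta2 < 0) abort("variances must be positive.")
  if (sigma_eta2 == 0) return(1)
  sigma_b2 / (sigma_b2 + sigma_eta2)
}

#' @describeIn reliability_m Diagnostic calibration of true exposure on the
#'   group mean measurement: `E[X | W_bar] = W_bar + (m - 1) (W_bar - mu_g)`.
#' @param w_bar Observed group mean measurement(s).
#' @param mu Group mean exposure(s).
#' @export
exposure_calibration <- function(w_bar, mu, sigma_b2, sigma_eta2) {
  m <- reliability_m(sigma_b2, sigma_eta2)
  w_bar + (m - 1) * (w_bar - mu)
}

#' Fit an exposure-disease model by any of the four methods
#'
#' Thin dispatcher over [fit_naive()], [fit_group_based()] and [fit_cem()],
#' convenient for scripted comparisons and the command-line interface.
#'
#' @param data A grouped dataset.
#' @param method One of `"naive"`, `"gbs"`, `"cgbs"`, `"cem"`.
#' @param family `"linear"` or `"logistic"`.
#' @param sigma_eta2 Known measurement-error variance (required for
#'   `method = "cem"`).
#' @param ... Passed on to [fit_cem()] (e.g. `options`).
#' @return A `semiecol_fit` object.
#' @export
fit_exposure <- function(data, method = c("naive", "gbs", "cgbs", "cem"),
                         family = c("linear", "logistic"),
                         sigma_eta2 = NULL, ...) {
  method <- match.arg(method)
  family <- match.arg(family)
  switch(method,
    naive = fit_naive(data, family),
    gbs = fit_group_based(data, family, constrained = FALSE),
    cgbs = fit_group_based(data, family, constrained = TRUE),
    cem = {
      if (is.null(sigma_eta2)) {
        abort("`sigma_eta2` is required for the EM estimator (it is not identifiable from the data).")
      }
      fit_cem(data, family, sigma_eta2 = sigma_eta2, ...)
    }
  )
}

#' Sensitivity analysis over the assumed measurement-error variance
#'
#' Re-fits an estimator for each value of a user-supplied grid of
#' `sigma_eta2` values and collects the slope estimates, supporting the
#' recommended sensitivity analysis when the error variance is only known
#' approximately.
#'
#' @param data A grouped dataset.
#' @param sigma_eta2_grid Positive values of the assumed error variance.
#' @param method Estimation method (only `"cem"` actually uses
#'   `sigma_eta2`; others are provided for side-by-side tables).
#' @param family Outcome family.
#' @param ... Passed to [fit_exposure()].
#' @return A tibble with one row per grid value: `sigma_eta2`, `method`,
#'   `beta0_hat`, `beta1_hat`, `se_beta1`, `converged`.
#' @export
fit_sensitivity <- function(data, sigma_eta2_grid, method = "cem",
                            family = c("linear", "logistic"), ...) {
  family <- match.arg(family)
  if (any(sigma_eta2_grid <= 0)) abort("`sigma_eta2_grid` must be positive.")
  purrr::map_dfr(sigma_eta2_grid, function(s2) {
    f <- fit_exposure(data, method = method, family = family,
                      sigma_eta2 = s2, ...)
    tibble(sigma_eta2 = s2, method = f$method, beta0_hat = f$beta0_hat,
           beta1_hat = f$beta1_hat, se_beta1 = f$se_beta1,
           converged = f$converged)
  })
}
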