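# Shared container for estimation results (all four estimators).

new_fit_result <- function(method, family, beta0_hat, beta1_hat,
                           se_beta1 = NA_real_, se_inflated = FALSE,
                           mu_hat = NULL, sigma_b2_hat = NA_real_,
                           sigma_eps2_hat = NA_real_, converged = TRUE,
                           n_iterations = NA_integer_, trace = NULL,
                           scores = NULL, sigma_eta2 = NA_real_) {
  structure(
    list(method = method, family = family,
         beta0_hat = beta0_hat, beta1_hat = beta1_hat,
         se_beta1 = se_beta1, se_inflated = isTRUE(se_inflated),
         mu_hat = mu_hat, sigma_b2_hat = sigma_b2_hat,
         sigma_eps2_hat = sigma_eps2_hat, converged = isTRUE(converged),
         n_iterations = n_iterations, trace = trace, scores = scores,
         sigma_eta2 = sigma_eta2),
    class = "semiecol_fit"
  )
}

#' @export
print.semiecol_fit <- function(x, ...) {
  cat("<semiecol_fit> method = ", x$method, ", family = ", x$family, "\n",
      sep = "")
  cat("  beta0_hat = ", format(x$beta0_hat, digits = 5),
      ", beta1_hat = ", format(x$beta1_hat, digits = 5), sep = "")
  if (is.finite(x$se_beta1)) {
    cat(" (se ", format(x$se_beta1, digits = 4),
        if (x$se_inflated) ", inflated" else "", ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$mu_hat)) {
    cat("  mu_hat =", paste(format(x$mu_hat, digits = 4), collapse = ", "), "\n")
  }
  if (is.finite(x$sigma_b2_hat)) {
    cat("  sigma_b2_hat =", format(x$sigma_b2_hat, digits = 4))
    if (is.finite(x$sigma_eps2_hat)) {
      cat("  sigma_eps2_hat =", format(x$sigma_eps2_hat, digits = 4))
    }
    cat("\n")
  }
  if (!is.na(x$n_iterations)) {
    cat("  converged = ", x$converged, " after ", x$n_iterations,
        " iteration(s)\n", sep = "")
  }
  invisible(x)
}

#' Tidy an estimation result
#'
#' One row per estimated parameter with columns `term`, `estimate`,
#' `std.error` (NA where the method reports none) and `se_inflated` (TRUE for
#' the group-based methods, whose model-based standard errors understate the
#' uncertainty because all subjects of a group share one imputed score).
#'
#' @param x A `semiecol_fit` (from [fit_naive()], [fit_group_based()],
#'   [fit_cem()] or [fit_exposure()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.semiecol_fit <- function(x, ...) {
  term <- c("beta0", "beta1")
  estimate <- c(x$beta0_hat, x$beta1_hat)
  std.error <- c(NA_real_, x$se_beta1)
  if (!is.null(x$mu_hat)) {
    term <- c(term, paste0("mu", seq_along(x$mu_hat)))
    estimate <- c(estimate, x$mu_hat)
    std.error <- c(std.error, rep(NA_real_, length(x$mu_hat)))
  }
  if (is.finite(x$sigma_b2_hat)) {
    term <- c(term, "sigma_b2"); estimate <- c(estimate, x$sigma_b2_hat)
    std.error <- c(std.error, NA_real_)
  }
  if (is.finite(x$sigma_eps2_hat)) {
    term <- c(term, "sigma_eps2"); estimate <- c(estimate, x$sigma_eps2_hat)
    std.error <- c(std.error, NA_real_)
  }
  tibble(term = term, estimate = estimate, std.error = std.error,
         se_inflated = x$se_inflated)
}

#' Glance at an estimation result
#'
#' @param x A `semiecol_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `family`, `beta1_hat`, `se_beta1`,
#'   `se_inflated`, `converged` and `n_iterations`.
#' @export
glance.semiecol_fit <- function(x, ...) {
  tibble(method = x$method, family = x$family, beta1_hat = x$beta1_hat,
         se_beta1 = x$se_beta1, se_inflated = x$se_inflated,
         converged = x$converged, n_iterations = x$n_iterations)
}
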