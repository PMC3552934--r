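#' Parameter vector for the grouped measurement-error model
#'
#' Bundles the parameters of the outcome model and the exposure model: the
#' regression coefficients, the ordered group mean exposures, the
#' between-subject exposure variance and the (known) measurement-error
#' variance. True exposure for a subject of group g is
#' `X ~ N(mu[g], sigma_b2)`; the observed exposure is `W = X + eta` with
#' `eta ~ N(0, sigma_eta2)` (classical additive error). The outcome follows
#' `Y = beta0 + beta1 * X + eps`, `eps ~ N(0, sigma_eps2)` for the linear
#' family, or `Y ~ Bernoulli(plogis(beta0 + beta1 * X))` for the logistic
#' family.
#'
#' `sigma_eta2` is treated as known throughout: it is not identifiable from
#' single measurements and must be supplied (e.g. from replicate measurement
#' studies), or varied over a grid in a sensitivity analysis (see
#' [fit_sensitivity()]).
#'
#' @param beta0,beta1 Intercept and slope of the outcome model.
#' @param mu Numeric vector of group mean exposures, one per group
#'   (index = group label).
#' @param sigma_b2 Between-subject exposure variance (> 0).
#' @param sigma_eta2 Measurement-error variance (> 0, known).
#' @param sigma_eps2 Residual outcome variance; required for the linear
#'   family, must be `NULL` for logistic.
#' @param family `"linear"` or `"logistic"`.
#'
#' @return An object of class `semiecol_theta` (a named list).
#' @examples
#' theta(beta0 = -2, beta1 = 0.3, mu = c(0.2, 0.5, 0.8, 1.1, 1.4),
#'       sigma_b2 = 0.6, sigma_eta2 = 0.5, sigma_eps2 = 1)
#' @export
theta <- function(beta0, beta1, mu, sigma_b2, sigma_eta2,
                  sigma_eps2 = NULL, family = c("linear", "logistic")) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1),
            is.numeric(mu), length(mu) >= 1L, all(is.finite(mu)))
  if (!is.numeric(sigma_b2) || length(sigma_b2) != 1L || !is.finite(sigma_b2) ||
      sigma_b2 <= 0) {
    abort("`sigma_b2` must be a positive finite scalar.")
  }
  if (!is.numeric(sigma_eta2) || length(sigma_eta2) != 1L ||
      !is.finite(sigma_eta2) || sigma_eta2 <= 0) {
    abort("`sigma_eta2` must be a positive finite scalar.")
  }
  if (family == "linear") {
    if (is.null(sigma_eps2) || !is.numeric(sigma_eps2) ||
        length(sigma_eps2) != 1L || !is.finite(sigma_eps2) || sigma_eps2 <= 0) {
      abort("`sigma_eps2` must be a positive finite scalar for the linear family.")
    }
  } else {
    if (!is.null(sigma_eps2)) {
      abort("`sigma_eps2` must be NULL for the logistic family.")
    }
  }
  structure(
    list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
         mu = as.numeric(mu), sigma_b2 = as.numeric(sigma_b2),
         sigma_eta2 = as.numeric(sigma_eta2),
         sigma_eps2 = if (family == "linear") as.numeric(sigma_eps2) else NULL,
         family = family),
    class = "semiecol_theta"
  )
}

#' @export
print.semiecol_theta <- function(x, ...) {
  cat("<semiecol_theta> family =", x$family, "\n")
  cat("  beta0 =", format(x$beta0), " beta1 =", format(x$beta1), "\n")
  cat("  mu =", paste(format(x$mu, digits = 4), collapse = ", "), "\n")
  cat("  sigma_b2 =", format(x$sigma_b2),
      " sigma_eta2 =", format(x$sigma_eta2))
  if (identical(x$family, "linear")) cat("  sigma_eps2 =", format(x$sigma_eps2))
  cat("\n")
  invisible(x)
}

is_theta <- function(x) inherits(x, "semiecol_theta")

# flatten estimated parameters to a named vector (sigma_eta2 excluded: known)
theta_to_vector <- function(theta) {
  v <- c(beta0 = theta$beta0, beta1 = theta$beta1)
  if (identical(theta$family, "linear")) v <- c(v, sigma_eps2 = theta$sigma_eps2)
  c(v, setNames(theta$mu, paste0("mu", seq_along(theta$mu))),
    sigma_b2 = theta$sigma_b2)
}

vector_to_theta <- function(v, template) {
  G <- length(template$mu)
  theta(beta0 = v[["beta0"]], beta1 = v[["beta1"]],
        mu = unname(v[paste0("mu", seq_len(G))]),
        sigma_b2 = v[["sigma_b2"]], sigma_eta2 = template$sigma_eta2,
        sigma_eps2 = if (identical(template$family, "linear")) v[["sigma_eps2"]] else NULL,
        family = template$family)
}
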