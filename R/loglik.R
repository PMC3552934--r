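#' Complete-data log-likelihood
#'
#' Log-likelihood of the "complete" data in which every subject's true
#' exposure `x` is known: the sum over records of
#' `log f(y | x) + log f(w | x) + log f(x)`, with `f(w | x) = N(x, sigma_eta2)`,
#' `f(x) = N(mu[g], sigma_b2)` and `f(y | x)` either
#' `N(beta0 + beta1 x, sigma_eps2)` or `Bernoulli(plogis(beta0 + beta1 x))`.
#' For records whose `w` is missing, the measurement term uses `w_star` when
#' supplied and is dropped otherwise (it involves no estimated parameter,
#' since the measurement-error variance is known).
#'
#' @param data A grouped dataset.
#' @param x Numeric vector of latent true exposures, one per record.
#' @param theta A [theta()] object.
#' @param w_star Optional numeric vector of latent measurements for
#'   missing-exposure records (`NA` elsewhere), same length as `x`.
#' @return A single number, the complete-data log-likelihood.
#' @export
complete_data_loglik <- function(data, x, theta, w_star = NULL) {
  data <- as_grouped_data(data)
  if (!is_theta(theta)) abort("`theta` must be a semiecol_theta object.")
  if (length(x) != nrow(data)) {
    abort("`x` must supply one latent exposure per record.")
  }
  if (!is.null(w_star) && length(w_star) != nrow(data)) {
    abort("`w_star` must have one entry per record (NA for observed records).")
  }
  g <- data$group
  if (max(g) > length(theta$mu)) abort("more groups in `data` than in `theta$mu`.")
  eta <- theta$beta0 + theta$beta1 * x
  ll_y <- if (identical(theta$family, "linear")) {
    dnorm(data$y, eta, sqrt(theta$sigma_eps2), log = TRUE)
  } else {
    check_binary_outcome(data$y)
    dbinom(data$y, 1L, plogis(eta), log = TRUE)
  }
  w_eff <- data$w
  if (!is.null(w_star)) {
    take <- is.na(w_eff) & !is.na(w_star)
    w_eff[take] <- w_star[take]
  }
  ll_w <- ifelse(is.na(w_eff), 0,
                 dnorm(w_eff, x, sqrt(theta$sigma_eta2), log = TRUE))
  ll_x <- dnorm(x, theta$mu[g], sqrt(theta$sigma_b2), log = TRUE)
  sum(ll_y + ll_w + ll_x)
}

#' Observed-data log-likelihood
#'
#' Marginal log-likelihood of the observables, integrating the latent true
#' exposure out of each record. For the linear family this is closed form:
#' per observed-exposure record, `(Y, W)` is bivariate normal with means
#' `(beta0 + beta1 mu_g, mu_g)`, variances
#' `(beta1^2 sigma_b2 + sigma_eps2, sigma_b2 + sigma_eta2)` and covariance
#' `beta1 sigma_b2`; missing-exposure records contribute the `Y` marginal.
#' For the logistic family the integral is computed by Gauss-Hermite
#' quadrature. Used to verify the ascent of the EM iterations.
#'
#' @param data A grouped dataset.
#' @param theta A [theta()] object.
#' @param quad_points Number of Gauss-Hermite nodes for the logistic family
#'   (>= 21).
#' @return A single number.
#' @export
observed_data_loglik <- function(data, theta, quad_points = 41) {
  data <- as_grouped_data(data)
  if (!is_theta(theta)) abort("`theta` must be a semiecol_theta object.")
  if (quad_points < 21) abort("`quad_points` must be at least 21.")
  g <- data$group
  obs <- !is.na(data$w)
  if (identical(theta$family, "linear")) {
    mu_y <- theta$beta0 + theta$beta1 * theta$mu[g]
    v_y <- theta$beta1^2 * theta$sigma_b2 + theta$sigma_eps2
    v_w <- theta$sigma_b2 + theta$sigma_eta2
    cv <- theta$beta1 * theta$sigma_b2
    ll <- numeric(nrow(data))
    if (any(obs)) {
      dy <- data$y[obs] - mu_y[obs]
      dw <- data$w[obs] - theta$mu[g[obs]]
      det_s <- v_y * v_w - cv^2
      quad <- (v_w * dy^2 - 2 * cv * dy * dw + v_y * dw^2) / det_s
      ll[obs] <- -log(2 * pi) - 0.5 * log(det_s) - 0.5 * quad
    }
    if (any(!obs)) {
      ll[!obs] <- dnorm(data$y[!obs], mu_y[!obs], sqrt(v_y), log = TRUE)
    }
    return(sum(ll))
  }
  check_binary_outcome(data$y)
  rule <- gh_rule(quad_points)
  ll <- numeric(nrow(data))
  if (any(obs)) {
    # N(w; x, se2) N(x; mu, sb2) = N(w; mu, sb2+se2) N(x; m0, v0)
    m0 <- (theta$sigma_b2 * data$w[obs] + theta$sigma_eta2 * theta$mu[g[obs]]) /
      (theta$sigma_b2 + theta$sigma_eta2)
    v0 <- theta$sigma_b2 * theta$sigma_eta2 /
      (theta$sigma_b2 + theta$sigma_eta2)
    xs <- outer(m0, sqrt(2 * v0) * rule$x, `+`)
    p <- plogis(theta$beta0 + theta$beta1 * xs)
    yv <- data$y[obs]
    lik <- yv * p + (1 - yv) * (1 - p)  # yv recycles down rows
    ll[obs] <- log(as.vector(lik %*% rule$w) / sqrt(pi)) +
      dnorm(data$w[obs], theta$mu[g[obs]],
            sqrt(theta$sigma_b2 + theta$sigma_eta2), log = TRUE)
  }
  if (any(!obs)) {
    xs <- outer(theta$mu[g[!obs]], sqrt(2 * theta$sigma_b2) * rule$x, `+`)
    p <- plogis(theta$beta0 + theta$beta1 * xs)
    yv <- data$y[!obs]
    lik <- yv * p + (1 - yv) * (1 - p)
    ll[!obs] <- log(as.vector(lik %*% rule$w) / sqrt(pi))
  }
  sum(ll)
}
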