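#' Meilijson empirical-information standard error of the slope
#'
#' Standard error of the EM slope estimate from the empirical information
#' matrix built out of per-subject observed-data scores. By Fisher's identity
#' the observed-data score of one subject equals the conditional expectation
#' of their complete-data score given the observables, so each subject's score
#' is computable from the same E-step posterior moments the EM uses. The
#' empirical information is the sum of outer products of the per-subject
#' scores, centered at their mean; the slope's standard error is the square
#' root of the corresponding diagonal entry of its inverse. The known
#' `sigma_eta2` is not a free parameter and contributes no score component.
#'
#' @param data A grouped dataset.
#' @param theta_hat Converged parameter estimate ([theta()]).
#' @param options A [cem_options()] list; for the logistic family the scores
#'   use `options$mc_draws_final` importance draws (seeded from
#'   `options$seed` when given).
#' @return The standard error of `beta1` (a positive number). The full
#'   empirical information matrix is attached as attribute `"information"`.
#' @export
se_meilijson <- function(data, theta_hat, options = cem_options()) {
  data <- as_grouped_data(data)
  if (!is_theta(theta_hat)) abort("`theta_hat` must be a semiecol_theta object.")
  S <- with_seed(if (is.null(options$seed)) NULL else child_seed(options$seed, 77L),
                 score_matrix(data, theta_hat, options))
  n <- nrow(S)
  s_bar <- colMeans(S)
  info <- crossprod(S) - n * tcrossprod(s_bar)
  inv <- tryCatch(solve(info), error = function(e) {
    abort("singular empirical information matrix; standard errors unavailable.")
  })
  se <- sqrt(inv["beta1", "beta1"])
  if (!is.finite(se) || se <= 0) {
    abort("empirical information gave a non-positive variance for beta1.")
  }
  structure(se, information = info)
}

# per-subject observed-data scores via Fisher's identity
score_matrix <- function(data, theta, options) {
  g <- data$group
  G <- length(theta$mu)
  y <- data$y
  stats <- cem_estep(data, theta, options,
                     n_draws = if (identical(theta$family, "logistic"))
                       options$mc_draws_final else NULL)
  ex <- stats$ex; ex2 <- stats$ex2
  if (identical(theta$family, "linear")) {
    b0 <- theta$beta0; b1 <- theta$beta1; s2 <- theta$sigma_eps2
    e_res <- y - b0 - b1 * ex
    e_res2 <- y^2 - 2 * y * (b0 + b1 * ex) + b0^2 + 2 * b0 * b1 * ex + b1^2 * ex2
    s_b0 <- e_res / s2
    s_b1 <- (y * ex - b0 * ex - b1 * ex2) / s2
    s_s2 <- -1 / (2 * s2) + e_res2 / (2 * s2^2)
    pre <- cbind(beta0 = s_b0, beta1 = s_b1, sigma_eps2 = s_s2)
  } else {
    p_bar <- rowSums(stats$weights * plogis(theta$beta0 + theta$beta1 * stats$draws))
    px_bar <- rowSums(stats$weights * plogis(theta$beta0 + theta$beta1 * stats$draws) *
                        stats$draws)
    s_b0 <- y - p_bar
    s_b1 <- y * ex - px_bar
    pre <- cbind(beta0 = s_b0, beta1 = s_b1)
  }
  s_mu <- matrix(0, nrow(data), G,
                 dimnames = list(NULL, paste0("mu", seq_len(G))))
  s_mu[cbind(seq_len(nrow(data)), g)] <- (ex - theta$mu[g]) / theta$sigma_b2
  e_dev2 <- ex2 - 2 * theta$mu[g] * ex + theta$mu[g]^2
  s_sb2 <- -1 / (2 * theta$sigma_b2) + e_dev2 / (2 * theta$sigma_b2^2)
  cbind(pre, s_mu, sigma_b2 = s_sb2)
}
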