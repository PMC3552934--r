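#' Posterior moments of true exposure given outcome and measured exposure
#'
#' For the linear family, the latent true exposure `X` of a subject with
#' observed `(y, w)` in group `g` has a normal posterior obtained by
#' precision-weighting three Gaussian sources of information: the group prior
#' `N(mu[g], sigma_b2)`, the measurement `w` (precision `1/sigma_eta2`) and
#' the outcome `y` (precision `beta1^2 / sigma_eps2`):
#' \deqn{1/v = 1/\sigma_b^2 + 1/\sigma_\eta^2 + \beta_1^2/\sigma_\epsilon^2,}
#' \deqn{m = v \left(\mu_g/\sigma_b^2 + w/\sigma_\eta^2 +
#'       \beta_1 (y - \beta_0)/\sigma_\epsilon^2\right).}
#' These are the exact E-step moments of the EM estimator for subjects with a
#' measured exposure. Inputs are vectorized over records.
#'
#' @param y,w,group Outcome, measured exposure and group index per record
#'   (recycled to a common length).
#' @param theta A [theta()] object with `family = "linear"`.
#' @return A tibble with columns `mean` and `var`, one row per record.
#' @examples
#' th <- theta(0, 0, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
#' posterior_x_moments(y = 0, w = 2, group = 1, th)  # mean 1, var 0.5
#' @export
posterior_x_moments <- function(y, w, group, theta) {
  if (!is_theta(theta)) abort("`theta` must be a semiecol_theta object.")
  if (!identical(theta$family, "linear")) {
    abort("posterior_x_moments() requires the linear family; logistic posteriors have no closed form.")
  }
  n <- max(length(y), length(w), length(group))
  y <- rep_len(y, n); w <- rep_len(w, n); group <- rep_len(group, n)
  if (any(!is.finite(y)) || any(!is.finite(w))) {
    abort("`y` and `w` must be finite.")
  }
  if (any(group < 1L) || any(group > length(theta$mu))) {
    abort("`group` out of range for `theta$mu`.")
  }
  prec <- 1 / theta$sigma_b2 + 1 / theta$sigma_eta2 +
    theta$beta1^2 / theta$sigma_eps2
  v <- 1 / prec
  m <- v * (theta$mu[group] / theta$sigma_b2 + w / theta$sigma_eta2 +
              theta$beta1 * (y - theta$beta0) / theta$sigma_eps2)
  tibble(mean = m, var = rep_len(v, n))
}

#' Joint posterior of latent exposure and unmeasured surrogate given outcome
#'
#' For subjects whose exposure measurement is missing, only the outcome `y` is
#' informative. Under the linear family, the pair `(X, W)` of latent true
#' exposure and (unrealized) error-prone measurement is bivariate normal given
#' `y`, with a common mean
#' \deqn{m = \frac{\sigma_\epsilon^2 \mu_g + \beta_1 \sigma_b^2 (y - \beta_0)}
#'                {\sigma_\epsilon^2 + \beta_1^2 \sigma_b^2},}
#' variances `var_x = sigma_eps2 * sigma_b2 / (sigma_eps2 + beta1^2*sigma_b2)`,
#' `var_w = var_x + sigma_eta2`, and correlation `rho = sqrt(var_x / var_w)`.
#' Inputs are vectorized over records.
#'
#' @param y Outcome value(s) of missing-exposure records.
#' @param group Group index per record.
#' @param theta A [theta()] object with `family = "linear"`.
#' @return A tibble with columns `mean`, `var_x`, `var_w`, `rho`.
#' @examples
#' th <- theta(0, 1, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
#' posterior_xw_missing(y = 1, group = 1, th)  # mean 0.5, var_x 0.5, var_w 1.5
#' @export
posterior_xw_missing <- function(y, group, theta) {
  if (!is_theta(theta)) abort("`theta` must be a semiecol_theta object.")
  if (!identical(theta$family, "linear")) {
    abort("posterior_xw_missing() requires the linear family; logistic missing-record posteriors are sampled in the EM.")
  }
  n <- max(length(y), length(group))
  y <- rep_len(y, n); group <- rep_len(group, n)
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (any(group < 1L) || any(group > length(theta$mu))) {
    abort("`group` out of range for `theta$mu`.")
  }
  denom <- theta$sigma_eps2 + theta$beta1^2 * theta$sigma_b2
  m <- (theta$sigma_eps2 * theta$mu[group] +
          theta$beta1 * theta$sigma_b2 * (y - theta$beta0)) / denom
  var_x <- theta$sigma_eps2 * theta$sigma_b2 / denom
  var_w <- var_x + theta$sigma_eta2
  tibble(mean = m, var_x = rep_len(var_x, n), var_w = rep_len(var_w, n),
         rho = rep_len(sqrt(var_x / var_w), n))
}
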