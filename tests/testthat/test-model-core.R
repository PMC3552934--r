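test_that("posterior of X given (y, w) is the precision-weighted combination", {
  th <- theta(0, 0, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
  mom <- posterior_x_moments(y = 5, w = 2, group = 1, th)
  expect_equal(mom$mean, 1.0)   # slope 0: outcome uninformative, prior/measurement average
  expect_equal(mom$var, 0.5)

  th2 <- theta(0, 1, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
  mom2 <- posterior_x_moments(y = 1, w = 1, group = 1, th2)
  expect_equal(mom2$mean, 2 / 3)
  expect_equal(mom2$var, 1 / 3)

  # vanishing measurement error: X pinned at w
  th3 <- theta(0.3, 0.7, mu = 0.4, sigma_b2 = 1, sigma_eta2 = 1e-12,
               sigma_eps2 = 1)
  mom3 <- posterior_x_moments(y = 2, w = 1.7, group = 1, th3)
  expect_equal(mom3$mean, 1.7, tolerance = 1e-9)
  expect_lt(mom3$var, 1e-11)

  expect_error(posterior_x_moments(NA, 1, 1, th2), "finite")
  thl <- theta(0, 1, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, family = "logistic")
  expect_error(posterior_x_moments(1, 1, 1, thl), "linear")
})

test_that("posterior moments match 1-D quadrature across random parameters", {
  set.seed(7)
  for (rep in 1:25) {
    th <- rtheta(G = 3)
    g <- sample(3, 1)
    y <- rnorm(1, th$beta0 + th$beta1 * th$mu[g], 1)
    w <- rnorm(1, th$mu[g], 1)
    mom <- posterior_x_moments(y, w, g, th)
    orc <- quad_x_moments(y, w, g, th)
    expect_equal(mom$mean, orc$mean, tolerance = 1e-6)
    expect_equal(mom$var, orc$var, tolerance = 1e-6)
    # conditioning can only reduce variance below the prior's
    expect_lt(mom$var, th$sigma_b2)
  }
})

test_that("missing-record joint posterior of (X, W) is bivariate normal", {
  th0 <- theta(1, 0, mu = 0.7, sigma_b2 = 0.6, sigma_eta2 = 0.5,
               sigma_eps2 = 1.3)
  mom <- posterior_xw_missing(y = 9, group = 1, th0)
  expect_equal(mom$mean, 0.7)          # slope 0: prior untouched
  expect_equal(mom$var_x, 0.6)
  expect_equal(mom$var_w, 1.1)
  expect_equal(mom$rho, sqrt(0.6 / 1.1))

  th1 <- theta(0, 1, mu = 0, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
  mom1 <- posterior_xw_missing(y = 1, group = 1, th1)
  expect_equal(mom1$mean, 0.5)
  expect_equal(mom1$var_x, 0.5)
  expect_equal(mom1$var_w, 1.5)
  expect_equal(mom1$rho, 0.5773503, tolerance = 1e-6)

  # vanishing measurement error makes W and X coincide
  th2 <- theta(0, 1, mu = 0, sigma_b2 = 1, sigma_eta2 = 1e-12, sigma_eps2 = 1)
  expect_equal(posterior_xw_missing(1, 1, th2)$rho, 1, tolerance = 1e-9)
})

test_that("missing-record posterior matches 2-D quadrature", {
  set.seed(11)
  for (rep in 1:8) {
    th <- rtheta(G = 2)
    g <- sample(2, 1)
    y <- rnorm(1, th$beta0 + th$beta1 * th$mu[g], 0.8)
    mom <- posterior_xw_missing(y, g, th)
    orc <- quad_xw_moments(y, g, th)
    expect_equal(mom$mean, orc$mean_x, tolerance = 1e-5)
    expect_equal(mom$mean, orc$mean_w, tolerance = 1e-5)
    expect_equal(mom$var_x, orc$var_x, tolerance = 1e-5)
    expect_equal(mom$var_w, orc$var_w, tolerance = 1e-5)
    expect_equal(mom$rho, orc$rho, tolerance = 1e-5)
    expect_lte(mom$var_x[1], mom$var_w[1])
  }
})

test_that("complete-data log-likelihood is a sum of the three model kernels", {
  th <- theta(0.5, 2, mu = 1, sigma_b2 = 1, sigma_eta2 = 1, sigma_eps2 = 1)
  d1 <- tibble::tibble(group = 1L, y = 0.5 + 2 * 1, w = 1)
  expect_equal(complete_data_loglik(d1, x = 1, th), -1.5 * log(2 * pi))
  # additivity over records
  d2 <- dplyr::bind_rows(d1, d1)
  expect_equal(complete_data_loglik(d2, c(1, 1), th),
               2 * complete_data_loglik(d1, 1, th))
  expect_error(complete_data_loglik(d2, 1, th), "per record")
})

test_that("complete-data log-likelihood matches a direct density sum", {
  set.seed(21)
  for (family in c("linear", "logistic")) {
    th <- rtheta(G = 2, family = family)
    d <- rdataset(th, n_per_group = 5, missing_frac = 0.3)
    x <- rnorm(nrow(d), d$x_true, 0.3)
    ws <- ifelse(is.na(d$w), rnorm(nrow(d), x, 0.5), NA_real_)
    direct <- sum(
      if (family == "linear") {
        dnorm(d$y, th$beta0 + th$beta1 * x, sqrt(th$sigma_eps2), log = TRUE)
      } else {
        dbinom(d$y, 1, plogis(th$beta0 + th$beta1 * x), log = TRUE)
      },
      dnorm(ifelse(is.na(d$w), ws, d$w), x, sqrt(th$sigma_eta2), log = TRUE),
      dnorm(x, th$mu[d$group], sqrt(th$sigma_b2), log = TRUE))
    expect_equal(complete_data_loglik(d, x, th, w_star = ws), direct)
  }
})

test_that("observed-data log-likelihood: linear closed form equals quadrature", {
  set.seed(31)
  th <- rtheta(G = 3)
  d <- rdataset(th, n_per_group = 4, missing_frac = 0.25)
  # per-record 1-D quadrature oracle
  ll_quad <- sum(vapply(seq_len(nrow(d)), function(i) {
    sd_max <- sqrt(max(th$sigma_b2, th$sigma_eta2, th$sigma_eps2))
    xs <- seq(th$mu[d$group[i]] - 14 * sd_max, th$mu[d$group[i]] + 14 * sd_max,
              length.out = 40001)
    dens <- dnorm(d$y[i], th$beta0 + th$beta1 * xs, sqrt(th$sigma_eps2)) *
      dnorm(xs, th$mu[d$group[i]], sqrt(th$sigma_b2))
    if (!is.na(d$w[i])) dens <- dens * dnorm(d$w[i], xs, sqrt(th$sigma_eta2))
    log(sum(dens) * (xs[2] - xs[1]))
  }, numeric(1)))
  expect_equal(observed_data_loglik(d, th), ll_quad, tolerance = 1e-8)
})

test_that("observed-data log-likelihood: slope zero factorizes; logistic degenerates cleanly", {
  th <- theta(0.4, 0, mu = c(0, 1), sigma_b2 = 0.7, sigma_eta2 = 0.4,
              sigma_eps2 = 1.2)
  d <- tibble::tibble(group = c(1L, 1L, 2L), y = c(0.1, 0.9, 0.4),
                      w = c(0.3, NA, 1.2))
  split_ll <- sum(dnorm(d$y, 0.4, sqrt(1.2), log = TRUE)) +
    sum(dnorm(d$w[!is.na(d$w)], th$mu[d$group[!is.na(d$w)]],
              sqrt(0.7 + 0.4), log = TRUE))
  expect_equal(observed_data_loglik(d, th), split_ll)

  thl <- theta(-1, 0.8, mu = c(0, 1), sigma_b2 = 0.7, sigma_eta2 = 1e-12,
               family = "logistic")
  dl <- tibble::tibble(group = c(1L, 2L, 2L), y = c(1, 0, 1),
                       w = c(0.2, 0.9, 1.4))
  direct <- sum(dbinom(dl$y, 1, plogis(-1 + 0.8 * dl$w), log = TRUE)) +
    sum(dnorm(dl$w, thl$mu[dl$group], sqrt(0.7 + 1e-12), log = TRUE))
  expect_equal(observed_data_loglik(dl, thl), direct, tolerance = 1e-5)

  expect_error(observed_data_loglik(dl, thl, quad_points = 10), "21")
})
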