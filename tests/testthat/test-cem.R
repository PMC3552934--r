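test_that("linear E-step delegates to the closed-form conditionals", {
  set.seed(14)
  th <- rtheta(G = 3)
  d <- rdataset(th, n_per_group = 6, missing_frac = 0.3)
  st <- cem_estep(d, th)
  obs <- !is.na(d$w)
  mo <- posterior_x_moments(d$y[obs], d$w[obs], d$group[obs], th)
  mm <- posterior_xw_missing(d$y[!obs], d$group[!obs], th)
  expect_equal(st$ex[obs], mo$mean)
  expect_equal(st$ex2[obs], mo$var + mo$mean^2)
  expect_equal(st$ex[!obs], mm$mean)
  expect_equal(st$ex2[!obs], mm$var_x + mm$mean^2)
  expect_true(all(st$ex2 >= st$ex^2))
})

test_that("logistic E-step: flat outcome likelihood gives uniform weights", {
  th <- theta(-1, 0, mu = c(0, 0.5), sigma_b2 = 0.6, sigma_eta2 = 0.5,
              family = "logistic")
  d <- tibble::tibble(group = c(1L, 2L, 2L), y = c(1, 0, 1),
                      w = c(0.2, NA, 0.9))
  set.seed(5)
  st <- cem_estep(d, th, cem_options(), n_draws = 400)
  expect_true(all(abs(st$weights - 1 / 400) < 1e-15))
  expect_equal(st$ex, rowMeans(st$draws))
  expect_equal(st$ess, rep(1, 3))
  # weights always normalized per record
  expect_equal(rowSums(st$weights), rep(1, 3))
})

test_that("logistic E-step posterior mean agrees with quadrature", {
  set.seed(23)
  for (rep in 1:5) {
    th <- rtheta(G = 2, family = "logistic")
    y <- rbinom(1, 1, 0.5)
    w <- rnorm(1, th$mu[1], 0.7)
    d <- tibble::tibble(group = 1L, y = as.numeric(y), w = w)
    st <- cem_estep(d, th, cem_options(), n_draws = 8000)
    orc <- gh_posterior_mean_logistic(y, w, 1, th)
    mc_se <- sqrt(sum(st$weights^2 * (st$draws - st$ex)^2))
    expect_lt(abs(st$ex - orc), 3 * mc_se + 1e-6)
  }
})

test_that("M-step updates the group means through the shared isotonic path", {
  # synthetic expected statistics whose group averages equal the worked example
  d <- dataset_with_group_means(table1_values, table1_weights)
  th <- theta(0, 1, mu = rep(1, 5), sigma_b2 = 1, sigma_eta2 = 0.5,
              sigma_eps2 = 1)
  st <- structure(list(ex = d$w, ex2 = d$w^2 + 0.2, obs = !is.na(d$w),
                       family = "linear"), class = "expected_stats")
  up_c <- cem_mstep(st, d, th, constrained = TRUE)
  expect_equal(round(up_c$mu, 4), table1_fitted)
  up_u <- cem_mstep(st, d, th, constrained = FALSE)
  expect_equal(up_u$mu, table1_values, tolerance = 1e-12)

  # already-ordered group averages: constrained update = plain means
  d2 <- dataset_with_group_means(c(0.2, 0.6, 1.1), c(4, 4, 4))
  st2 <- structure(list(ex = d2$w, ex2 = d2$w^2 + 0.1, obs = !is.na(d2$w),
                        family = "linear"), class = "expected_stats")
  th2 <- theta(0, 1, mu = rep(0, 3), sigma_b2 = 1, sigma_eta2 = 0.5,
               sigma_eps2 = 1)
  expect_equal(cem_mstep(st2, d2, th2, TRUE)$mu, c(0.2, 0.6, 1.1),
               tolerance = 1e-12)
})

test_that("linear M-step coefficients minimize the expected quadratic objective", {
  set.seed(9)
  th <- rtheta(G = 2)
  d <- rdataset(th, n_per_group = 10)
  st <- cem_estep(d, th)
  up <- cem_mstep(st, d, th, constrained = FALSE)
  # brute-force minimization of E[(y - b0 - b1 X)^2] summed over records
  obj <- function(b) {
    sum(d$y^2 - 2 * d$y * (b[1] + b[2] * st$ex) + b[1]^2 +
          2 * b[1] * b[2] * st$ex + b[2]^2 * st$ex2)
  }
  opt <- optim(c(0, 0), obj, method = "BFGS")
  expect_equal(c(up$beta0, up$beta1), opt$par, tolerance = 1e-5)
  # sigma_eps2 equals the minimized mean expected squared residual
  expect_equal(up$sigma_eps2, obj(c(up$beta0, up$beta1)) / nrow(d),
               tolerance = 1e-10)
  # sigma_b2 equals the mean expected squared deviation from the new means
  expect_equal(up$sigma_b2,
               mean(st$ex2 - 2 * up$mu[d$group] * st$ex + up$mu[d$group]^2))
})

test_that("EM with vanishing measurement error reduces to the no-error MLE", {
  d <- generate_dataset(scenario(n_y = 30, sigma_eta2 = 1e-12), seed = 6)
  f <- fit_cem(d, "linear", sigma_eta2 = 1e-10,
               options = cem_options(max_iter = 1000))
  ref <- lm(y ~ w, data = d)
  expect_equal(f$beta1_hat, unname(coef(ref)[2]), tolerance = 1e-3)
  expect_equal(f$beta0_hat, unname(coef(ref)[1]), tolerance = 1e-3)
  # group means: isotonized averages of the (error-free) measurements
  counts <- group_counts(d)
  w_bar <- as.numeric(tapply(d$w, d$group, mean))
  expect_equal(f$mu_hat, pava(w_bar, counts$n_total)$fitted, tolerance = 1e-3)
})

test_that("observed-data log-likelihood ascends over linear EM iterations", {
  set.seed(33)
  for (rep in 1:6) {
    th <- rtheta(G = 4)
    d <- rdataset(th, n_per_group = 10, missing_frac = 0.3)
    f <- suppressWarnings(
      fit_cem(d, "linear", sigma_eta2 = th$sigma_eta2,
              options = cem_options(max_iter = 60), se = FALSE))
    # every iteration must increase the observed-data log-likelihood,
    # converged or not (exact E-step)
    expect_true(all(diff(f$trace$loglik) > -1e-8))
  }
})

test_that("constrained fits return ordered means; constraint inactive when unneeded", {
  d <- generate_dataset(scenario(delta = 1.2, n_y = 60), seed = 10)
  fc <- fit_cem(d, "linear", 0.5, options = cem_options(constrained = TRUE))
  fu <- fit_cem(d, "linear", 0.5, options = cem_options(constrained = FALSE))
  expect_false(is.unsorted(fc$mu_hat))
  # wide group separation: the order constraint never binds
  expect_equal(fc$beta1_hat, fu$beta1_hat, tolerance = 1e-6)
  expect_equal(fc$mu_hat, fu$mu_hat, tolerance = 1e-6)
})

test_that("EM handles groups with no measured exposure via the prior-only posterior", {
  d <- generate_dataset(scenario(n_y = 40), seed = 11)
  d$w[d$group == 3] <- NA_real_
  f <- fit_cem(d, "linear", 0.5, se = FALSE)
  expect_true(f$converged)
  expect_false(is.unsorted(f$mu_hat))
  expect_error(assign_scores(d), "no observed exposure")  # contrast with GBS
})

test_that("logistic EM is reproducible and respects the order constraint", {
  d <- generate_dataset(scenario(family = "logistic", n_y = 30), seed = 12)
  op <- cem_options(seed = 4, mc_draws_initial = 100, mc_draws_final = 300,
                    max_iter = 150)
  f1 <- fit_cem(d, "logistic", 0.5, options = op, se = FALSE)
  f2 <- fit_cem(d, "logistic", 0.5, options = op, se = FALSE)
  expect_identical(f1$beta1_hat, f2$beta1_hat)
  expect_false(is.unsorted(f1$mu_hat))
})

test_that("Meilijson standard errors behave like information-based errors", {
  d <- generate_dataset(scenario(n_y = 50, delta = 0.8), seed = 13)
  f <- fit_cem(d, "linear", 0.5, options = cem_options(constrained = FALSE))
  th_hat <- theta(f$beta0_hat, f$beta1_hat, mu = f$mu_hat,
                  sigma_b2 = f$sigma_b2_hat, sigma_eta2 = 0.5,
                  sigma_eps2 = f$sigma_eps2_hat)
  se <- se_meilijson(d, th_hat)
  expect_true(is.finite(se) && se > 0)

  # duplicating the dataset k times shrinks the SE by ~ 1/sqrt(k)
  d4 <- dplyr::bind_rows(d, d, d, d)
  se4 <- se_meilijson(d4, th_hat)
  expect_equal(as.numeric(se4), as.numeric(se) / 2, tolerance = 0.02)

  # numeric-Hessian oracle on the observed-data log-likelihood
  v_hat <- semiecol:::theta_to_vector(th_hat)
  nll <- function(v) {
    names(v) <- names(v_hat)
    -observed_data_loglik(d, semiecol:::vector_to_theta(v, th_hat))
  }
  H <- pracma::hessian(nll, v_hat)
  se_hess <- sqrt(diag(solve(H))[which(names(v_hat) == "beta1")])
  expect_equal(as.numeric(se), as.numeric(se_hess), tolerance = 0.05)
})
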