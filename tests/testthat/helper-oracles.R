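# Independent oracles used across the suite. All are brute force on purpose:
# grid quadrature, exhaustive enumeration, direct density sums.

# 1-D grid quadrature of the unnormalized posterior f(y|x) f(w|x) f(x)
quad_x_moments <- function(y, w, g, th, n_grid = 40001) {
  stopifnot(identical(th$family, "linear"))
  sd_max <- sqrt(max(th$sigma_b2, th$sigma_eta2))
  ctr <- (th$mu[g] + w) / 2
  xs <- seq(ctr - 12 * sd_max, ctr + 12 * sd_max, length.out = n_grid)
  dens <- dnorm(y, th$beta0 + th$beta1 * xs, sqrt(th$sigma_eps2)) *
    dnorm(w, xs, sqrt(th$sigma_eta2)) *
    dnorm(xs, th$mu[g], sqrt(th$sigma_b2))
  z <- sum(dens)
  m <- sum(xs * dens) / z
  v <- sum((xs - m)^2 * dens) / z
  list(mean = m, var = v)
}

# 2-D grid quadrature of f(y|x) f(w|x) f(x) for a missing-exposure record
quad_xw_moments <- function(y, g, th, n_grid = 601) {
  stopifnot(identical(th$family, "linear"))
  sx <- sqrt(th$sigma_b2)
  sw <- sqrt(th$sigma_b2 + th$sigma_eta2)
  xs <- seq(th$mu[g] - 9 * sx, th$mu[g] + 9 * sx, length.out = n_grid)
  ws <- seq(th$mu[g] - 9 * sw, th$mu[g] + 9 * sw, length.out = n_grid)
  fy <- dnorm(y, th$beta0 + th$beta1 * xs, sqrt(th$sigma_eps2)) *
    dnorm(xs, th$mu[g], sqrt(th$sigma_b2))
  dens <- outer(fy, rep(1, n_grid)) *
    dnorm(outer(rep(1, n_grid), ws) - xs, 0, sqrt(th$sigma_eta2))
  z <- sum(dens)
  mx <- sum(xs * rowSums(dens)) / z
  mw <- sum(ws * colSums(dens)) / z
  vx <- sum((xs - mx)^2 * rowSums(dens)) / z
  vw <- sum((ws - mw)^2 * colSums(dens)) / z
  cxw <- sum(outer(xs - mx, ws - mw) * dens) / z
  list(mean_x = mx, mean_w = mw, var_x = vx, var_w = vw,
       rho = cxw / sqrt(vx * vw))
}

# max-min representation of the weighted isotonic regression
# (block averages via cumulative sums; equals av(values, weights, l, j))
maxmin_iso <- function(values, weights) {
  G <- length(values)
  cw <- c(0, cumsum(weights * values))
  cs <- c(0, cumsum(weights))
  avf <- function(l, j) (cw[j + 1] - cw[l]) / (cs[j + 1] - cs[l])
  vapply(seq_len(G), function(g) {
    max(vapply(seq_len(g), function(l) {
      min(vapply(g:G, function(j) avf(l, j), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# exhaustive QP oracle: enumerate all contiguous block partitions, keep those
# whose block means are nondecreasing, return the weighted-SSE minimizer
qp_iso <- function(values, weights) {
  G <- length(values)
  cw <- c(0, cumsum(weights * values))
  cs <- c(0, cumsum(weights))
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(G - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(G - 2))) > 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, G)
    means <- (cw[ends + 1] - cw[starts]) / (cs[ends + 1] - cs[starts])
    if (is.unsorted(means)) next
    fit <- rep(means, times = ends - starts + 1L)
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Gauss-Hermite oracle for the logistic-family posterior mean of X given (y, w)
gh_posterior_mean_logistic <- function(y, w, g, th, n_nodes = 80) {
  rule <- pracma::gaussHermite(n_nodes)
  m0 <- (th$sigma_b2 * w + th$sigma_eta2 * th$mu[g]) /
    (th$sigma_b2 + th$sigma_eta2)
  v0 <- th$sigma_b2 * th$sigma_eta2 / (th$sigma_b2 + th$sigma_eta2)
  xs <- m0 + sqrt(2 * v0) * rule$x
  p <- plogis(th$beta0 + th$beta1 * xs)
  lik <- if (y == 1) p else 1 - p
  sum(rule$w * lik * xs) / sum(rule$w * lik)
}

# random parameter draw for property checks (uses the ambient RNG)
rtheta <- function(G = 3, family = "linear") {
  theta(beta0 = runif(1, -2, 2), beta1 = runif(1, -1.5, 1.5),
        mu = sort(runif(G, -1, 2)), sigma_b2 = runif(1, 0.2, 2),
        sigma_eta2 = runif(1, 0.2, 2),
        sigma_eps2 = if (family == "linear") runif(1, 0.3, 2) else NULL,
        family = family)
}

# small random grouped dataset drawn from a theta (uses the ambient RNG)
rdataset <- function(th, n_per_group = 8, missing_frac = 0) {
  G <- length(th$mu)
  g <- rep(seq_len(G), each = n_per_group)
  x <- rnorm(length(g), th$mu[g], sqrt(th$sigma_b2))
  w <- x + rnorm(length(g), 0, sqrt(th$sigma_eta2))
  y <- if (identical(th$family, "linear")) {
    th$beta0 + th$beta1 * x + rnorm(length(g), 0, sqrt(th$sigma_eps2))
  } else {
    rbinom(length(g), 1, plogis(th$beta0 + th$beta1 * x))
  }
  if (missing_frac > 0) {
    w[sample(length(g), floor(missing_frac * length(g)))] <- NA_real_
  }
  tibble::tibble(group = g, y = y, w = w, x_true = x)
}

# grouped dataset whose observed group means/counts match given values exactly
dataset_with_group_means <- function(means, counts, beta0 = 0, beta1 = 1) {
  g <- rep(seq_along(means), times = counts)
  w <- unlist(mapply(function(m, n) {
    if (n == 1) return(m)
    dev <- seq(-1, 1, length.out = n)
    m + dev - mean(dev)
  }, means, counts, SIMPLIFY = FALSE))
  tibble::tibble(group = g, y = beta0 + beta1 * w, w = w)
}

table1_values <- c(0.7755, 0.6229, 1.8207, 2.2878, 1.7054)
table1_weights <- c(4, 3, 5, 3, 4)
table1_fitted <- c(0.7101, 0.7101, 1.8207, 1.9550, 1.9550)
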