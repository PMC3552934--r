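#' Weighted block average
#'
#' The weighted mean `Av(i, j)` of components `i..j` of `values` with positive
#' weights -- the block value that the pool-adjacent-violators algorithm
#' assigns when components `i..j` are pooled, and the building block of the
#' max-min representation of the isotonic regression.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @param i,j Block bounds, `1 <= i <= j <= length(values)`.
#' @return The weighted mean of `values[i:j]`.
#' @examples
#' av(c(0.7755, 0.6229, 1.8207, 2.2878, 1.7054), c(4, 3, 5, 3, 4), 1, 2)
#' @export
av <- function(values, weights, i, j) {
  if (length(values) != length(weights)) abort("lengths of `values` and `weights` differ.")
  if (any(!is.finite(weights)) || any(weights <= 0)) abort("weights must be positive.")
  if (!(i >= 1 && j >= i && j <= length(values))) abort("need 1 <= i <= j <= length(values).")
  idx <- i:j
  sum(weights[idx] * values[idx]) / sum(weights[idx])
}

#' Weighted isotonic regression by pool-adjacent-violators
#'
#' Projects a vector onto the cone of nondecreasing vectors in the weighted
#' least-squares sense: minimizes `sum(weights * (values - fit)^2)` subject to
#' `fit[1] <= ... <= fit[G]`. Adjacent strict decreases are pooled into blocks
#' whose common value is the weighted mean of the pooled inputs (equal
#' adjacent values violate nothing and are left alone). The solution equals
#' the max-min formula `fit[g] = max_{l<=g} min_{j>=g} Av(l, j)`.
#'
#' A decreasing order is obtained with `decreasing = TRUE` (inputs and fitted
#' values are negated internally).
#'
#' @param values Numeric vector to isotonize (e.g. observed group mean
#'   exposures).
#' @param weights Positive weights (e.g. observed sample sizes); recycled if
#'   scalar.
#' @param decreasing Fit a nonincreasing vector instead.
#' @return An object of class `isotonic_fit`: a list with `fitted` (the
#'   isotonized vector), `blocks` (list of pooled index ranges), `weights` and
#'   the input `values`. Supports [tidy()] and [ggplot2::autoplot()].
#' @examples
#' fit <- pava(c(0.7755, 0.6229, 1.8207, 2.2878, 1.7054), c(4, 3, 5, 3, 4))
#' fit$fitted  # 0.7101 0.7101 1.8207 1.9550 1.9550
#' @export
pava <- function(values, weights = 1, decreasing = FALSE) {
  if (!length(values)) abort("`values` must be non-empty.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  weights <- rep_len(weights, length(values))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("weights must be positive (groups with no observations are handled upstream).")
  }
  v <- if (decreasing) -values else values
  n <- length(v)
  # stack of blocks: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (k in seq_len(n)) {
    top <- top + 1L
    val[top] <- v[k]; wt[top] <- weights[k]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      w2 <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / w2
      wt[top - 1L] <- w2
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  fitted <- rep(val[seq_len(top)], times = sz[seq_len(top)])
  if (decreasing) fitted <- -fitted
  ends <- cumsum(sz[seq_len(top)])
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- purrr::map2(starts, ends, ~ .x:.y)
  structure(
    list(fitted = fitted, blocks = blocks, weights = weights,
         values = values, decreasing = decreasing),
    class = "isotonic_fit"
  )
}

#' @export
print.isotonic_fit <- function(x, ...) {
  cat("<isotonic_fit> ", length(x$values), " values, ",
      length(x$blocks), " level set(s)",
      if (x$decreasing) ", decreasing" else "", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn pava Tidy an isotonic fit into one row per component with its
#'   input value, weight, fitted value and level-set (block) index.
#' @param x An `isotonic_fit`.
#' @param ... Unused.
#' @export
tidy.isotonic_fit <- function(x, ...) {
  block <- integer(length(x$values))
  for (b in seq_along(x$blocks)) block[x$blocks[[b]]] <- b
  tibble(index = seq_along(x$values), value = x$values,
         weight = x$weights, fitted = x$fitted, block = block)
}
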