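#' Validate subject-level grouped exposure data
#'
#' A grouped dataset is a data frame with one row per subject and columns
#' `group` (integer exposure-group index, 1-based and contiguous, ordered by
#' hypothesized increasing mean exposure), `y` (outcome, fully observed;
#' numeric for the linear family, 0/1 for logistic) and `w` (error-prone
#' exposure measurement; `NA` = missing). Any further columns (e.g. a true
#' exposure `x_true` kept by the simulator) are carried along untouched.
#'
#' @param data A data frame with columns `group`, `y`, `w`.
#' @return The validated data as a tibble.
#' @examples
#' as_grouped_data(data.frame(group = c(1, 1, 2), y = c(0.2, 1, 3),
#'                            w = c(0.1, NA, 2)))
#' @export
as_grouped_data <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c("group", "y", "w"), names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  data <- as_tibble(data)
  g <- data$group
  if (!is.numeric(g) || anyNA(g) || any(g != as.integer(g)) || any(g < 1)) {
    abort("`group` must contain positive integers with no missing values.")
  }
  data$group <- as.integer(g)
  G <- max(data$group)
  if (!setequal(unique(data$group), seq_len(G))) {
    abort("group indices must be contiguous 1..G (every group non-empty).")
  }
  if (!is.numeric(data$y) || anyNA(data$y) || any(!is.finite(data$y))) {
    abort("`y` must be numeric with no missing values (outcomes are fully observed).")
  }
  if (!is.numeric(data$w)) abort("`w` must be numeric (NA = missing).")
  if (any(!is.na(data$w) & !is.finite(data$w))) {
    abort("`w` must be finite where observed.")
  }
  data
}

#' Per-group observed and missing exposure counts
#'
#' @param data A grouped dataset (see [as_grouped_data()]).
#' @return A tibble with one row per group: `group`, `n_obs` (records with a
#'   measured exposure), `n_miss` and `n_total`.
#' @examples
#' d <- data.frame(group = c(1, 1, 2), y = c(0.2, 1, 3), w = c(0.1, NA, 2))
#' group_counts(d)
#' @export
group_counts <- function(data) {
  data <- as_grouped_data(data)
  G <- max(data$group)
  n_obs <- tabulate(data$group[!is.na(data$w)], nbins = G)
  n_total <- tabulate(data$group, nbins = G)
  tibble(group = seq_len(G), n_obs = n_obs,
         n_miss = n_total - n_obs, n_total = n_total)
}

n_groups <- function(data) max(data$group)

check_binary_outcome <- function(y) {
  if (!all(y %in% c(0, 1))) {
    abort("logistic family requires a 0/1 outcome `y`.")
  }
  invisible(TRUE)
}
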