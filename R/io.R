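#' Read a grouped exposure dataset from delimited text
#'
#' Expects a comma-separated file with header `group,y,w`: `group` a 1-based
#' integer index ordered by hypothesized increasing exposure, `y` the outcome
#' (numeric, or 0/1 for logistic models), `w` the measured exposure with an
#' empty field meaning missing (never 0). Malformed rows raise an error naming
#' the offending line.
#'
#' @param path Path to the file.
#' @return A grouped-data tibble (see [as_grouped_data()]).
#' @export
read_exposure_data <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty dataset file.")
  header <- tolower(trimws(strsplit(lines[[1]], ",")[[1]]))
  need <- c("group", "y", "w")
  if (!all(need %in% header)) {
    abort("dataset file must have a header line containing columns group,y,w.")
  }
  pos <- match(need, header)
  parse_num <- function(s, what, line, allow_empty = FALSE) {
    s <- trimws(s)
    if (!nzchar(s)) {
      if (allow_empty) return(NA_real_)
      abort(paste0("line ", line, ": missing ", what, "."))
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) abort(paste0("line ", line, ": unparseable ", what, " '", s, "'."))
    v
  }
  n <- length(lines) - 1L
  g <- integer(n); y <- numeric(n); w <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], ",", fixed = TRUE)[[1]]
    length(fields) <- max(length(fields), max(pos))
    fields[is.na(fields)] <- ""
    gv <- parse_num(fields[pos[1]], "group index", i + 1L)
    if (gv != as.integer(gv) || gv < 1) {
      abort(paste0("line ", i + 1L, ": group must be a positive integer."))
    }
    g[i] <- as.integer(gv)
    y[i] <- parse_num(fields[pos[2]], "outcome y", i + 1L)
    w[i] <- parse_num(fields[pos[3]], "exposure w", i + 1L, allow_empty = TRUE)
  }
  as_grouped_data(tibble(group = g, y = y, w = w))
}

#' @describeIn read_exposure_data Write a grouped dataset (missing `w` becomes
#'   an empty field).
#' @param data A grouped dataset.
#' @export
write_exposure_data <- function(data, path) {
  data <- as_grouped_data(data)
  utils::write.csv(data[, c("group", "y", "w")], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

fmt6 <- function(x) {
  ifelse(is.na(x), "", trimws(formatC(x, digits = 6, format = "g")))
}

#' Write estimation results to delimited text
#'
#' One row per fitted method with the point estimates, the slope standard
#' error, the inflated-SE flag (group-based methods), convergence information
#' and the estimated group means serialized as a bracketed list. Numbers are
#' written with 6 significant digits for reproducible diffs. A plain-text
#' metadata sidecar `<path>.meta` records the package version and any seed and
#' options supplied.
#'
#' @param fits A `semiecol_fit` or list of them.
#' @param path Output path.
#' @param seed,options Optional run metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(fits, path, seed = NULL, options = NULL) {
  if (inherits(fits, "semiecol_fit")) fits <- list(fits)
  rows <- purrr::map_chr(fits, function(f) {
    mu <- if (is.null(f$mu_hat)) "" else
      paste0("[", paste(fmt6(f$mu_hat), collapse = ";"), "]")
    paste(f$method, fmt6(f$beta0_hat), fmt6(f$beta1_hat), fmt6(f$se_beta1),
          tolower(f$se_inflated), tolower(f$converged),
          ifelse(is.na(f$n_iterations), "", f$n_iterations), mu, sep = ",")
  })
  writeLines(c("method,beta0_hat,beta1_hat,se_beta1,se_inflated,converged,n_iterations,mu_hat",
               rows), path)
  meta <- c(paste0("package_version: ", as.character(packageVersion("semiecol"))),
            if (!is.null(seed)) paste0("seed: ", seed),
            if (!is.null(options)) paste0("options: ", paste(
              names(options), unlist(lapply(options, function(o)
                paste(format(o), collapse = " "))), sep = "=", collapse = "; ")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @describeIn write_results Read a results file back as a tibble (`mu_hat`
#'   becomes a list-column of numeric vectors).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, colClasses = "character")
  num <- function(s) ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)
  tibble(
    method = raw$method,
    beta0_hat = num(raw$beta0_hat),
    beta1_hat = num(raw$beta1_hat),
    se_beta1 = num(raw$se_beta1),
    se_inflated = raw$se_inflated == "true",
    converged = raw$converged == "true",
    n_iterations = suppressWarnings(as.integer(raw$n_iterations)),
    mu_hat = purrr::map(raw$mu_hat, function(s) {
      s <- gsub("\\[|\\]", "", s)
      if (!nzchar(s)) return(NULL)
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  )
}

#' Read a simulation configuration file
#'
#' A YAML file listing grid values for the scenario fields; vector-valued
#' entries (`delta`, `sigma_b2`, `sigma_eta2`, `n_x`, `family`) are expanded
#' into the full factorial grid of scenarios. Scalar fields (`G`, `n_y`,
#' `beta0`, `beta1`, `mu_base`, `sigma_eps2`, `n_reps`) apply to every cell;
#' `methods` and `seed` configure the experiment run.
#'
#' @param path Path to the YAML config.
#' @return A list with `scenarios` (list of [scenario()]), `methods`, `seed`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  grid <- expand.grid(
    delta = cfg$delta %||% 0.3,
    sigma_b2 = cfg$sigma_b2 %||% 0.6,
    sigma_eta2 = cfg$sigma_eta2 %||% 0.5,
    n_x = cfg$n_x %||% (cfg$n_y %||% 30L),
    family = cfg$family %||% "linear",
    stringsAsFactors = FALSE)
  scenarios <- purrr::pmap(grid, function(delta, sigma_b2, sigma_eta2, n_x, family) {
    scenario(G = cfg$G %||% 5L, n_y = cfg$n_y %||% 30L, n_x = n_x,
             delta = delta, mu_base = cfg$mu_base %||% 0.2,
             sigma_b2 = sigma_b2, sigma_eta2 = sigma_eta2,
             sigma_eps2 = cfg$sigma_eps2 %||% 1, beta0 = cfg$beta0 %||% -2,
             beta1 = cfg$beta1 %||% 0.3, family = family,
             n_reps = cfg$n_reps %||% 200L)
  })
  list(scenarios = scenarios,
       methods = cfg$methods %||% c("naive", "gbs", "cgbs", "cem"),
       seed = cfg$seed %||% 1L)
}
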