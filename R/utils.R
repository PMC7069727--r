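# internal helpers shared across modules

# run `expr` under a local RNG seeded with `seed`; NULL seed uses the
# current RNG stream (so callers can manage reproducibility themselves)
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  ok <- if (strict_min) x > min else x >= min
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict_min) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# centred moving mean with shrunken windows at the edges; NA values are
# dropped from each window (all-NA windows stay NA)
moving_mean <- function(x, width) {
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  vals <- ifelse(is.na(x), 0, x)
  cnts <- as.numeric(!is.na(x))
  cs_v <- c(0, cumsum(vals))
  cs_n <- c(0, cumsum(cnts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs_v[hi + 1L] - cs_v[lo]
  k <- cs_n[hi + 1L] - cs_n[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

# truth attached to simulator outputs ------------------------------------

#' Retrieve the ground truth attached to a simulated dataset
#'
#' Every `simulate_*()` generator attaches the parameters and latent state
#' used to build the dataset (spiked genes, true selection coefficient, true
#' replication-timing map, duplicated intervals, ...) as a `"truth"`
#' attribute. `sim_truth()` returns it.
#'
#' @param x An object returned by one of the `simulate_*()` generators.
#' @return A named list (contents depend on the generator).
#' @export
sim_truth <- function(x) {
  tr <- attr(x, "truth", exact = TRUE)
  if (is.null(tr)) abort("`x` carries no simulation truth attribute.")
  tr
}

new_sim_result <- function(data, truth, class = character()) {
  attr(data, "truth") <- truth
  class(data) <- unique(c(class, class(data)))
  data
}
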