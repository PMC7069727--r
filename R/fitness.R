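#' Generations elapsed in one growth cycle
#'
#' Doublings between sampling at 0 h and 24 h:
#' `g = log2(events_t24 / events_t0)`. When event counts are unavailable
#' the dilution factor gives the steady-state fallback
#' `g = log2(dilution_factor)` (a 1:1000 serial dilution gives ~10
#' generations per cycle).
#'
#' @param events_t0,events_t24 Total event counts at 0 h and 24 h (both
#'   > 0), or `NULL`/`NA` to use the fallback.
#' @param dilution_factor Serial-dilution factor (default 1000).
#' @return Generations elapsed (numeric).
#' @export
#' @examples
#' generations_elapsed(1e4, 8e4) # 3 doublings
#' generations_elapsed()         # 1:1000 dilution, ~10 generations
generations_elapsed <- function(events_t0 = NULL, events_t24 = NULL,
                                dilution_factor = 1000) {
  if (is.null(events_t0) || is.null(events_t24) ||
      any(is.na(events_t0)) || any(is.na(events_t24))) {
    check_number(dilution_factor, "dilution_factor", min = 1)
    return(log2(dilution_factor))
  }
  if (any(events_t0 <= 0) || any(events_t24 <= 0)) {
    abort("event counts must be > 0 (use the dilution fallback instead).")
  }
  log2(events_t24 / events_t0)
}

#' Cumulative generations and log strain ratio per competition timepoint
#'
#' For each replicate series, computes the test:reference ratio
#' `r = test_events / reference_events`, its natural log, and the
#' cumulative generations elapsed since mixing (summing per-passage
#' [generations_elapsed()]; the day-0 point contributes 0).
#'
#' @param series Competition tibble with columns `passage`, `test_events`,
#'   `reference_events` and optionally `replicate` (default single
#'   replicate), `total_t0`, `total_t24`.
#' @param dilution_factor Fallback dilution factor for passages without
#'   total counts.
#' @return Tibble with `replicate`, `passage`, `g` (cumulative
#'   generations), `ln_ratio`.
#' @export
ratio_series <- function(series, dilution_factor = 1000) {
  check_columns(series, c("passage", "test_events", "reference_events"),
                "series")
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  if (!"total_t0" %in% names(series)) series$total_t0 <- NA_real_
  if (!"total_t24" %in% names(series)) series$total_t24 <- NA_real_
  bad <- series$reference_events <= 0
  if (any(bad)) {
    abort(sprintf(
      "zero reference events at replicate %s, passage %s: ratio undefined.",
      series$replicate[bad][1], series$passage[bad][1]
    ))
  }
  series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$passage, .by_group = TRUE) |>
    dplyr::mutate(
      g_step = dplyr::if_else(
        dplyr::row_number() == 1L & .data$passage == min(.data$passage),
        0,
        dplyr::if_else(
          is.na(.data$total_t0) | is.na(.data$total_t24),
          log2(dilution_factor),
          log2(.data$total_t24 / .data$total_t0)
        )
      ),
      g = cumsum(.data$g_step),
      ln_ratio = log(.data$test_events / .data$reference_events)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("replicate", "passage", "g", "ln_ratio")
}

#' Estimate a selection coefficient from competition series
#'
#' Fits, per biological replicate, an ordinary least-squares regression of
#' `ln r` on cumulative generations; the selection coefficient `s` is the
#' slope. The reported estimate is the mean of the replicate slopes, its
#' spread their standard deviation. Replicates with fewer than two usable
#' points are dropped with a warning.
#'
#' @inheritParams ratio_series
#' @param min_replicates Error if fewer usable replicates remain
#'   (default 1; the headline assay design uses >= 3).
#' @return A `fitness_fit` object; see [tidy()] for per-replicate slopes,
#'   [glance()] for the one-row summary (`s`, `s_sd`, `n_replicates`).
#' @export
#' @examples
#' cs <- simulate_competition(s_true = 0.05, events_per_sample = Inf)
#' glance(estimate_selection(cs))
estimate_selection <- function(series, dilution_factor = 1000,
                               min_replicates = 1) {
  rs <- ratio_series(series, dilution_factor = dilution_factor)
  fits <- rs |>
    tidyr::nest(data = -"replicate") |>
    dplyr::mutate(
      n_points = purrr::map_int(.data$data, nrow),
      span_g = purrr::map_dbl(.data$data, ~ diff(range(.x$g)))
    )
  unusable <- fits$n_points < 2L | fits$span_g <= 0
  if (any(unusable)) {
    warn(sprintf("excluding %d replicate(s) with < 2 usable points.",
                 sum(unusable)))
    fits <- fits[!unusable, ]
  }
  if (nrow(fits) < max(1, min_replicates)) {
    abort("not enough usable replicates to estimate selection.")
  }
  fits <- fits |>
    dplyr::mutate(
      slope = purrr::map_dbl(.data$data, ~ coef(lm(ln_ratio ~ g, data = .x))[["g"]]),
      intercept = purrr::map_dbl(.data$data, ~ coef(lm(ln_ratio ~ g, data = .x))[[1L]])
    )
  structure(
    list(
      replicates = dplyr::select(fits, "replicate", "slope", "intercept",
                                 "n_points"),
      points = rs,
      s = mean(fits$slope),
      s_sd = if (nrow(fits) > 1L) sd(fits$slope) else NA_real_,
      n_replicates = nrow(fits)
    ),
    class = "fitness_fit"
  )
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf(
    "Selection coefficient: s = %.4f (SD %.4f, %d replicate%s)\n",
    x$s, x$s_sd, x$n_replicates, if (x$n_replicates == 1L) "" else "s"
  ))
  invisible(x)
}

#' @export
tidy.fitness_fit <- function(x, ...) {
  x$replicates
}

#' @export
glance.fitness_fit <- function(x, ...) {
  tibble(s = x$s, s_sd = x$s_sd, n_replicates = x$n_replicates)
}

#' Welch's t-test between two strains' replicate slopes
#'
#' Compares the per-replicate selection-coefficient estimates of two
#' [estimate_selection()] fits by a t-test assuming unequal variances.
#'
#' @param fit1,fit2 `fitness_fit` objects.
#' @return Tidy one-row tibble: `estimate1`, `estimate2`, `difference`,
#'   `statistic`, `p_value`, `df`.
#' @export
compare_fitness <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "fitness_fit"), inherits(fit2, "fitness_fit"))
  tt <- t.test(fit1$replicates$slope, fit2$replicates$slope,
               var.equal = FALSE)
  tibble(
    estimate1 = fit1$s, estimate2 = fit2$s,
    difference = fit1$s - fit2$s,
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter)
  )
}

#' Convert a relative fitness to the wild-type reference frame
#'
#' A selection coefficient measured against a non-wild-type reference is
#' converted with `fitness_vs_wt = reference_fitness_vs_wt * (1 + s)`:
#' e.g. +27% against a reference itself at 0.73 of wild type gives
#' 0.73 * 1.27 = 0.93, a 7% residual defect.
#'
#' @param s_vs_reference Selection coefficient against the reference.
#' @param reference_fitness_vs_wt Reference strain's fitness relative to
#'   wild type (> 0).
#' @return Fitness relative to wild type (numeric).
#' @export
#' @examples
#' convert_reference_fitness(0.27, 0.73)
convert_reference_fitness <- function(s_vs_reference, reference_fitness_vs_wt) {
  if (any(reference_fitness_vs_wt <= 0)) {
    abort("`reference_fitness_vs_wt` must be > 0.")
  }
  reference_fitness_vs_wt * (1 + s_vs_reference)
}
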