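#' Allele frequencies from Sanger chromatogram peak heights
#'
#' For each measurement (one locus at one timepoint, read in two
#' sequencing directions), the per-direction frequency is
#' `mutant / (mutant + ancestor)` peak height; the point estimate is the
#' mean across directions and the bounds are the per-direction values.
#' Estimates are then clamped: below `background` they are set to 0
#' (indistinguishable from sequencing background), above 0.95 to 1.
#' Clamping is applied after averaging, with the same monotone rule on the
#' bounds so they still bracket the point estimate.
#'
#' @param peaks Tibble with columns `locus`, `direction`, `mutant_height`,
#'   `ancestor_height`, and optionally `generation` (timepoint).
#' @param background Background noise level as a frequency (default 0.05).
#' @return Tibble per (locus, generation): `frequency`, `lower`, `upper`,
#'   `n_directions`.
#' @export
#' @examples
#' sanger_frequency(tibble::tibble(
#'   locus = "RAD9", direction = c("fwd", "rev"),
#'   mutant_height = c(28, 32), ancestor_height = c(72, 68)
#' ))
sanger_frequency <- function(peaks, background = 0.05) {
  check_columns(peaks, c("locus", "direction", "mutant_height",
                         "ancestor_height"), "peaks")
  if (any(peaks$mutant_height < 0) || any(peaks$ancestor_height < 0)) {
    abort("peak heights must be >= 0.")
  }
  if (!"generation" %in% names(peaks)) peaks$generation <- NA_real_
  clamp <- function(f) {
    dplyr::case_when(f < background ~ 0, f > 0.95 ~ 1, TRUE ~ f)
  }
  peaks |>
    dplyr::group_by(.data$locus, .data$generation) |>
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$direction)) {
        abort(sprintf("duplicate direction for locus %s.", key$locus))
      }
      tot <- df$mutant_height + df$ancestor_height
      usable <- tot > 0
      if (!any(usable)) {
        abort(sprintf("all directions have zero total peak height at locus %s.",
                      key$locus))
      }
      f <- df$mutant_height[usable] / tot[usable]
      tibble(
        frequency = clamp(mean(f)),
        lower = clamp(min(f)),
        upper = clamp(max(f)),
        n_directions = sum(usable)
      )
    }) |>
    dplyr::ungroup()
}

#' Assemble allele-frequency trajectories across timepoints
#'
#' Applies [sanger_frequency()] per measurement and returns a tidy
#' locus-by-generation table, sorted by generation within locus. Missing
#' timepoints stay absent — nothing is interpolated. Duplicate
#' (locus, generation, direction) measurements are an error.
#'
#' @inheritParams sanger_frequency
#' @return An `allele_trajectory` tibble: `locus`, `generation`,
#'   `frequency`, `lower`, `upper`, `n_directions`.
#' @export
trajectory_table <- function(peaks, background = 0.05) {
  check_columns(peaks, c("locus", "generation"), "peaks")
  dup <- duplicated(peaks[, c("locus", "generation", "direction")])
  if (any(dup)) {
    abort(sprintf("duplicate measurement: locus %s at generation %s.",
                  peaks$locus[dup][1], peaks$generation[dup][1]))
  }
  out <- sanger_frequency(peaks, background = background) |>
    dplyr::arrange(.data$locus, .data$generation)
  class(out) <- c("allele_trajectory", class(out))
  out
}

#' Classify bulk-segregant alleles as causal or hitchhiking
#'
#' After backcrossing, sporulation and growth selection of the pooled
#' progeny, causal alleles rise in frequency while neutral (hitchhiking)
#' alleles segregate randomly and stay near 0.5. An allele is called
#' causal iff its pooled frequency strictly exceeds `threshold`.
#'
#' @param frequencies Tibble with columns `locus` and `frequency`
#'   (in `[0, 1]`).
#' @param threshold Causality threshold (default 0.70; strict inequality).
#' @return The input with columns `classification`
#'   (`"causal"`/`"hitchhiker"`) and `neutral_expectation` (0.5) added.
#' @export
#' @examples
#' segregant_classify(tibble::tibble(
#'   locus = c("RAD9", "SCC2", "XYZ1"), frequency = c(0.92, 0.80, 0.50)
#' ))
segregant_classify <- function(frequencies, threshold = 0.70) {
  check_columns(frequencies, c("locus", "frequency"), "frequencies")
  if (any(frequencies$frequency < 0 | frequencies$frequency > 1)) {
    abort("frequencies must lie in [0, 1].")
  }
  frequencies |>
    dplyr::mutate(
      classification = dplyr::if_else(.data$frequency > threshold,
                                      "causal", "hitchhiker"),
      neutral_expectation = 0.5
    )
}
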