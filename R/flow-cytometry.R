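#' Percent of the genome replicated from a DNA-content histogram
#'
#' Locates the mode of the DNA-content histogram and expresses it as a
#' linear fraction of the 1C-2C span:
#' `(mode - 1C) / (2C - 1C) * 100`, in percent. A mode at the G1 (1C)
#' position gives 0%, at the G2 (2C) position 100%. Modes outside the
#' span are clipped to it with a warning. Ties between equally tall bins
#' break toward lower DNA content (earlier S-phase).
#'
#' @param histogram Tibble with columns `bin_center` (fluorescence a.u.)
#'   and `count`.
#' @param c1,c2 Annotated 1C and 2C positions on the same axis
#'   (`c2 > c1`).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' h <- tibble::tibble(bin_center = seq(80, 220, 5),
#'                     count = dnorm(seq(80, 220, 5), 150, 12))
#' percent_replicated(h, c1 = 100, c2 = 200)
percent_replicated <- function(histogram, c1, c2) {
  check_columns(histogram, c("bin_center", "count"), "histogram")
  if (c2 <= c1) abort("`c2` must exceed `c1`.")
  if (any(histogram$count < 0)) abort("counts must be >= 0.")
  h <- dplyr::arrange(histogram, .data$bin_center)
  mode_pos <- h$bin_center[which.max(h$count)]  # first max = lowest content
  if (mode_pos < c1 || mode_pos > c2) {
    warn("histogram mode lies outside [1C, 2C]; clipping.")
    mode_pos <- min(max(mode_pos, c1), c2)
  }
  (mode_pos - c1) / (c2 - c1) * 100
}

#' 1C/2C peak-height ratio of a DNA-content histogram
#'
#' Finds the tallest bin within a window around each annotated peak
#' position (window half-width `window_frac` of the 1C-2C span) and
#' returns the ratio of the 1C to the 2C peak height. A candidate bin only
#' counts as a peak if it is a local maximum of the full histogram, so a
#' unimodal G1-only profile raises an error for the missing 2C peak.
#'
#' @inheritParams percent_replicated
#' @param window_frac Peak search half-window as a fraction of the 1C-2C
#'   span (default 0.10).
#' @return The 1C/2C height ratio (numeric).
#' @export
peak_ratio <- function(histogram, c1, c2, window_frac = 0.10) {
  check_columns(histogram, c("bin_center", "count"), "histogram")
  if (c2 <= c1) abort("`c2` must exceed `c1`.")
  h <- dplyr::arrange(histogram, .data$bin_center)
  span <- c2 - c1
  find_peak <- function(center, label) {
    in_win <- which(abs(h$bin_center - center) <= window_frac * span)
    if (length(in_win) == 0L) {
      abort(sprintf("no histogram bins near the %s position.", label))
    }
    idx <- in_win[which.max(h$count[in_win])]
    left <- if (idx > 1L) h$count[idx - 1L] else -Inf
    right <- if (idx < nrow(h)) h$count[idx + 1L] else -Inf
    if (h$count[idx] <= 0 ||
        h$count[idx] < left || h$count[idx] < right) {
      abort(sprintf("%s peak not found (no local maximum near its position).",
                    label))
    }
    h$count[idx]
  }
  find_peak(c1, "1C") / find_peak(c2, "2C")
}
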