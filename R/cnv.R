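#' Median-normalise a read-depth track
#'
#' Divides every unmasked window by the genome-wide median depth of the
#' unmasked windows, so a single-copy region sits at 1.0 regardless of
#' sequencing depth. Masked windows (repeats: telomeres, rDNA, Ty) are
#' propagated as `NA` and never enter the median.
#'
#' @param track Coverage tibble with columns `chrom`, `start`, `depth` and
#'   optionally a logical `mask` column (see [apply_mask()]).
#' @return The track with `depth` replaced by its normalised value.
#' @export
normalize_depth <- function(track) {
  check_columns(track, c("chrom", "start", "depth"), "track")
  mask <- if ("mask" %in% names(track)) track$mask else rep(FALSE, nrow(track))
  usable <- !mask & !is.na(track$depth)
  if (!any(usable) || all(track$depth[usable] == 0)) {
    abort("track has no unmasked non-zero window to normalise against.")
  }
  med <- median(track$depth[usable])
  if (med == 0) abort("genome-wide median depth is zero.")
  track$depth <- track$depth / med
  track$depth[mask] <- NA_real_
  track
}

#' Flag masked windows from a BED of repeat intervals
#'
#' Adds (or overwrites) a logical `mask` column: `TRUE` for windows whose
#' midpoint falls inside any interval of `mask_bed`.
#'
#' @param track Coverage tibble (`chrom`, `start`, `end`, ...).
#' @param mask_bed Tibble of intervals (`chrom`, `start`, `end`).
#' @return The track with a `mask` column.
#' @export
apply_mask <- function(track, mask_bed) {
  check_columns(track, c("chrom", "start", "end"), "track")
  check_columns(mask_bed, c("chrom", "start", "end"), "mask_bed")
  mid <- (track$start + track$end) / 2
  gr_win <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(floor(mid) + 1L, floor(mid) + 1L)
  )
  gr_mask <- GenomicRanges::GRanges(
    mask_bed$chrom, IRanges::IRanges(mask_bed$start + 1L, mask_bed$end)
  )
  track$mask <- IRanges::overlapsAny(gr_win, gr_mask)
  track
}

#' Per-window copy-number change between evolved and ancestor tracks
#'
#' Subtracts the ancestor's normalised depth from the evolved clone's,
#' window by window, yielding copies gained (+) or lost (−) during the
#' experiment in haploid units (normalised 1.0 = one copy). Both tracks
#' must share binning; windows masked in either are `NA`.
#'
#' @param evolved_norm,ancestor_norm Median-normalised coverage tibbles
#'   (from [normalize_depth()]) on identical bins.
#' @return A `cnv_profile` tibble: `chrom`, `start`, `end`, `copy_change`.
#' @export
copy_change <- function(evolved_norm, ancestor_norm) {
  check_columns(evolved_norm, c("chrom", "start", "depth"), "evolved_norm")
  check_columns(ancestor_norm, c("chrom", "start", "depth"), "ancestor_norm")
  if (nrow(evolved_norm) != nrow(ancestor_norm) ||
      !all(evolved_norm$chrom == ancestor_norm$chrom) ||
      !all(evolved_norm$start == ancestor_norm$start)) {
    abort("evolved and ancestor tracks must share identical binning.")
  }
  out <- tibble(
    chrom = evolved_norm$chrom,
    start = evolved_norm$start,
    end = if ("end" %in% names(evolved_norm)) evolved_norm$end
          else evolved_norm$start + 100,
    copy_change = evolved_norm$depth - ancestor_norm$depth
  )
  class(out) <- c("cnv_profile", class(out))
  out
}

#' Smooth a copy-number profile with a centred moving mean
#'
#' Averages `copy_change` over `width_windows` consecutive windows per
#' chromosome; the smoothed value is reported at the centre of the
#' smoothing window. Chromosome edges use shrunken windows so ends retain
#' values; `NA` (masked) windows are dropped from each window's mean.
#'
#' @param profile A `cnv_profile` from [copy_change()].
#' @param width_windows Odd window count (default 5).
#' @return The profile with `copy_change` smoothed.
#' @export
smooth_profile <- function(profile, width_windows = 5) {
  check_columns(profile, c("chrom", "start", "copy_change"), "profile")
  if (width_windows < 1 || width_windows %% 2 == 0) {
    abort("`width_windows` must be odd and >= 1.")
  }
  profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(copy_change = moving_mean(.data$copy_change,
                                            as.integer(width_windows))) |>
    dplyr::ungroup() |>
    (\(x) { class(x) <- c("cnv_profile", class(x)); x })()
}

#' Call amplified or deleted segments from a smoothed profile
#'
#' Reports maximal runs of consecutive windows whose absolute smoothed
#' copy change meets `min_abs_change` and whose length reaches
#' `min_length_windows`. Runs are split where the sign flips or a masked
#' (`NA`) window intervenes. These thresholds are a calling convention of
#' this package (chosen to separate ±1-copy steps from ~50x Poisson depth
#' noise), not a published rule; tune them to the data at hand.
#'
#' @param profile Smoothed `cnv_profile`.
#' @param min_abs_change Minimum absolute copy change (default 0.5, half a
#'   haploid copy step).
#' @param min_length_windows Minimum run length in windows (default 50,
#'   i.e. 5 kb of 100-bp bins).
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_change`, `direction` (`"gain"`/`"loss"`).
#' @export
call_amplified_segments <- function(profile, min_abs_change = 0.5,
                                    min_length_windows = 50) {
  check_columns(profile, c("chrom", "start", "end", "copy_change"), "profile")
  check_number(min_abs_change, "min_abs_change", min = 0, strict_min = TRUE)
  check_number(min_length_windows, "min_length_windows", min = 1)
  profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      cc <- df$copy_change
      state <- dplyr::case_when(
        is.na(cc) ~ 0L,
        cc >= min_abs_change ~ 1L,
        cc <= -min_abs_change ~ -1L,
        TRUE ~ 0L
      )
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0L & r$lengths >= min_length_windows
      if (!any(keep)) {
        return(tibble(start = numeric(), end = numeric(),
                      n_windows = integer(), mean_change = numeric(),
                      direction = character()))
      }
      purrr::map_dfr(which(keep), function(i) {
        idx <- starts[i]:ends[i]
        tibble(
          start = df$start[starts[i]],
          end = df$end[ends[i]],
          n_windows = length(idx),
          mean_change = mean(cc[idx]),
          direction = if (r$values[i] > 0L) "gain" else "loss"
        )
      })
    }) |>
    dplyr::ungroup()
}
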