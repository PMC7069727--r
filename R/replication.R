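#' Scale a normalised coverage track to its sample's DNA content
#'
#' Median-normalised sequencing coverage loses the absolute 1x-2x scale;
#' multiplying the track so its genome-wide mean equals the sample's
#' relative DNA content (measured independently, e.g. as the median of the
#' cell-cycle profile) restores it.
#'
#' @param track Coverage tibble (`chrom`, `start`, `depth` or `coverage`).
#' @param dna_content Relative DNA content in `[1, 2]`.
#' @return The track rescaled (same value column).
#' @export
scale_to_dna_content <- function(track, dna_content) {
  check_number(dna_content, "dna_content", min = 1)
  if (dna_content > 2) abort("`dna_content` must lie in [1, 2].")
  col <- if ("coverage" %in% names(track)) "coverage" else "depth"
  check_columns(track, col, "track")
  vals <- track[[col]]
  m <- mean(vals, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) abort("track mean must be positive.")
  track[[col]] <- vals * (dna_content / m)
  track
}

# keep only spatial wavelengths >= cutoff_bp, via the DCT (mirrored FFT);
# removes short-range wiggles before extremum calling
dct_lowpass <- function(x, cutoff_bp, spacing_bp) {
  n <- length(x)
  if (n < 3L) return(x)
  y <- c(x, rev(x))                      # even extension -> DCT via FFT
  f <- fft(y)
  j <- seq_len(2L * n) - 1L
  j_sym <- pmin(j, 2L * n - j)           # symmetric frequency index
  wavelength <- (2 * n * spacing_bp) / pmax(j_sym, 1e-12)
  f[j_sym > 0 & wavelength < cutoff_bp] <- 0
  Re(fft(f, inverse = TRUE) / (2L * n))[seq_len(n)]
}

#' Infer replication timing (t_rep) from an S-phase coverage time course
#'
#' `t_rep` of a window is the time at which half the population has
#' replicated it — the moment its absolute coverage crosses 1.5x, midway
#' between the unreplicated (1x) and replicated (2x) bounds. Each sample is
#' optionally rescaled to its DNA content, smoothed along the genome with a
#' Savitzky-Golay polynomial filter, and then each window's first upward
#' 1.5x crossing is found by linear interpolation between the bracketing
#' timepoints. Windows already above the threshold at the first sample
#' interpolate from an implicit `(t = 0, coverage = 1.0)` anchor (cells
#' enter S-phase unreplicated); windows that never reach the threshold are
#' censored. Coverage that recrosses the threshold (noise) resolves to the
#' first upward crossing.
#'
#' @param timecourse Long tibble (`chrom`, `start`, `end`, `time_min`,
#'   `coverage`), e.g. from [simulate_replication_timecourse()] or
#'   stacked bedGraph tracks.
#' @param dna_content Optional tibble (`time_min`, `dna_content`) used to
#'   rescale each sample; defaults to the time course's own attribute when
#'   present, else no rescaling.
#' @param threshold Crossing threshold (default 1.5, the 1x/2x midpoint).
#' @param presmooth Apply Savitzky-Golay smoothing along the genome per
#'   sample (default TRUE).
#' @param sg_window,sg_order Savitzky-Golay window (bins, odd) and
#'   polynomial order.
#' @return A `replication_profile` tibble: `chrom`, `start`, `end`,
#'   `t_rep` (min; `NA` when censored), `censored`. The attribute
#'   `t_max` records the last sampled time (censored windows replicate
#'   after it).
#' @export
compute_trep <- function(timecourse, dna_content = NULL, threshold = 1.5,
                         presmooth = TRUE, sg_window = 9, sg_order = 2) {
  check_columns(timecourse, c("chrom", "start", "time_min", "coverage"),
                "timecourse")
  if (is.null(dna_content)) {
    dna_content <- attr(timecourse, "dna_content", exact = TRUE)
  }
  times <- sort(unique(timecourse$time_min))
  if (length(times) < 2L) abort("need at least two timepoints.")

  tc <- as_tibble(timecourse)
  if (!is.null(dna_content)) {
    check_columns(dna_content, c("time_min", "dna_content"), "dna_content")
    tc <- tc |>
      dplyr::group_by(.data$time_min) |>
      dplyr::group_modify(function(df, key) {
        dc <- dna_content$dna_content[dna_content$time_min == key$time_min]
        if (length(dc) != 1L) {
          abort(sprintf("no DNA content for timepoint %s.", key$time_min))
        }
        m <- mean(df$coverage, na.rm = TRUE)
        df$coverage <- df$coverage * (dc / m)
        df
      }) |>
      dplyr::ungroup()
  }
  if (presmooth) {
    if (sg_window %% 2 == 0) abort("`sg_window` must be odd.")
    tc <- tc |>
      dplyr::group_by(.data$chrom, .data$time_min) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::mutate(coverage = if (dplyr::n() > sg_window) {
        as.numeric(signal::sgolayfilt(.data$coverage, p = sg_order,
                                      n = sg_window))
      } else .data$coverage) |>
      dplyr::ungroup()
  }

  end_col <- if ("end" %in% names(tc)) "end" else NULL
  prof <- tc |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      wide <- df |>
        dplyr::select(dplyr::all_of(c("start", end_col, "time_min", "coverage"))) |>
        tidyr::pivot_wider(names_from = "time_min", values_from = "coverage",
                           names_sort = TRUE) |>
        dplyr::arrange(.data$start)
      covm <- as.matrix(wide[, as.character(times)])
      # implicit G1 anchor: unreplicated (1.0x) at t = 0
      covm <- cbind(rep(1.0, nrow(covm)), covm)
      tvec <- c(0, times)
      above <- covm >= threshold
      first_idx <- apply(above, 1L, function(a) {
        i <- which(a)
        if (length(i) == 0L) NA_integer_ else min(i)
      })
      t_rep <- rep(NA_real_, nrow(covm))
      ok <- !is.na(first_idx) & first_idx > 1L
      if (any(ok)) {
        i <- first_idx[ok]
        c_lo <- covm[cbind(which(ok), i - 1L)]
        c_hi <- covm[cbind(which(ok), i)]
        t_lo <- tvec[i - 1L]
        t_hi <- tvec[i]
        t_rep[ok] <- t_lo + (threshold - c_lo) / (c_hi - c_lo) * (t_hi - t_lo)
      }
      out <- tibble(start = wide$start, t_rep = t_rep,
                    censored = is.na(t_rep))
      if (!is.null(end_col)) out$end <- wide[[end_col]]
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::any_of(c("chrom", "start", "end")))

  structure(prof,
            t_max = max(times), threshold = threshold,
            class = c("replication_profile", class(prof)))
}

#' Total unreplicated DNA at a cutoff time
#'
#' Sums the length of all windows whose `t_rep` exceeds `t_cut` (including
#' censored windows, which replicate after the last sample).
#'
#' @param profile A `replication_profile`.
#' @param t_cut Cutoff in minutes (default 45).
#' @return Total bp (numeric).
#' @export
summarize_unreplicated <- function(profile, t_cut = 45) {
  check_columns(profile, c("start", "t_rep", "censored"), "profile")
  width <- if ("end" %in% names(profile)) profile$end - profile$start
           else rep(100, nrow(profile))
  late <- profile$censored | (!is.na(profile$t_rep) & profile$t_rep > t_cut)
  sum(width[late])
}

#' Call replication origins and terminations from a timing profile
#'
#' Low-pass filters `t_rep` along each chromosome (discrete-cosine domain,
#' discarding wavelengths below `lowpass_cutoff`) and calls local minima as
#' origins (earliest-replicating loci) and local maxima as terminations.
#' Censored gaps split the chromosome into independent domains; domains
#' shorter than the filter support are skipped with a warning. Domain
#' boundaries where the filtered timing rises toward the edge are reported
#' as boundary terminations (forks run off the domain end there).
#' Consecutive same-type extrema (ties after filtering) keep only the most
#' extreme point, so origins and terminations alternate. Adjacent
#' origin/termination pairs whose filtered timing difference is below
#' `min_prominence` are discarded (weakest pair first): they are filter
#' ringing or sampling-quantisation wiggles, not real replicon structure.
#'
#' @param profile A `replication_profile`.
#' @param lowpass_cutoff Minimum retained wavelength in bp (default
#'   20,000).
#' @param min_prominence Minimum timing difference (min) between adjacent
#'   extrema for both to be kept (default 5).
#' @return Tibble of calls: `chrom`, `pos` (window midpoint, bp), `type`
#'   (`"origin"`/`"termination"`), `t_rep` (unfiltered value at the call),
#'   `boundary` (TRUE for domain-edge terminations).
#' @export
call_origins_terminations <- function(profile, lowpass_cutoff = 20000,
                                      min_prominence = 5) {
  check_columns(profile, c("chrom", "start", "t_rep", "censored"), "profile")
  width <- if ("end" %in% names(profile)) {
    median(profile$end - profile$start)
  } else 100
  support_windows <- max(3L, ceiling(lowpass_cutoff / width))

  calls <- profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      dom <- cumsum(c(TRUE, diff(df$censored) != 0 |
                        diff(df$start) > width * 1.5))
      purrr::map_dfr(split(seq_len(nrow(df)), dom), function(idx) {
        sub <- df[idx, ]
        if (sub$censored[1]) return(tibble())
        if (nrow(sub) < support_windows) {
          warn(sprintf("domain of %d windows shorter than filter support (%d); skipped.",
                       nrow(sub), support_windows))
          return(tibble())
        }
        x <- dct_lowpass(sub$t_rep, lowpass_cutoff, width)
        extrema_calls(x, sub, width, min_prominence)
      })
    }) |>
    dplyr::ungroup()
  calls
}

# locate alternating minima (origins) / maxima (terminations) of the
# filtered signal x over the windows of `sub`
extrema_calls <- function(x, sub, width, min_prominence = 0) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse zero slopes onto the neighbouring trend so plateaus centre
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  turns <- which(diff(s) != 0) + 1L
  rows <- purrr::map_dfr(turns, function(i) {
    before <- s[i - 1L]
    after <- s[i]
    if (before < 0 && after > 0) {
      tibble(idx = i, type = "origin")
    } else if (before > 0 && after < 0) {
      tibble(idx = i, type = "termination")
    } else tibble()
  })
  # boundary terminations: filtered timing rising into the domain edge
  if (n >= 2L) {
    if (x[1] > x[2]) {
      rows <- dplyr::bind_rows(tibble(idx = 1L, type = "termination",
                                      boundary = TRUE), rows)
    }
    if (x[n] > x[n - 1L]) {
      rows <- dplyr::bind_rows(rows, tibble(idx = n, type = "termination",
                                            boundary = TRUE))
    }
  }
  if (nrow(rows) == 0L) return(tibble())
  if (!"boundary" %in% names(rows)) rows$boundary <- FALSE
  rows$boundary[is.na(rows$boundary)] <- FALSE
  rows <- dplyr::arrange(rows, .data$idx)
  # enforce alternation: within each run of same-type calls keep the extremum
  run <- cumsum(c(TRUE, rows$type[-1L] != rows$type[-nrow(rows)]))
  rows <- rows |>
    dplyr::mutate(run = run, value = x[.data$idx]) |>
    dplyr::group_by(.data$run) |>
    dplyr::slice(if (dplyr::first(.data$type) == "origin") {
      which.min(.data$value)
    } else which.max(.data$value)) |>
    dplyr::ungroup()
  # persistence simplification: drop the weakest adjacent pair until every
  # neighbouring origin/termination differs by at least min_prominence
  while (nrow(rows) >= 2L) {
    gaps <- abs(diff(rows$value))
    if (all(gaps >= min_prominence)) break
    i <- which.min(gaps)
    rows <- rows[-c(i, i + 1L), ]
  }
  if (nrow(rows) == 0L) return(tibble())
  ends <- if ("end" %in% names(sub)) sub$end else sub$start + width
  tibble(
    pos = (sub$start[rows$idx] + ends[rows$idx]) / 2,
    type = rows$type,
    t_rep = sub$t_rep[rows$idx],
    boundary = rows$boundary
  )
}

#' Estimate fork velocities from origin/termination calls
#'
#' Each origin is paired with its nearest flanking termination on each
#' side; the velocity is the distance travelled divided by the timing
#' difference, `(pos_term - pos_ori) / (t_rep_term - t_rep_ori)`. Only
#' long replicons give usable estimates — short ones make the timing
#' difference comparable to its noise — so replicons below
#' `min_replicon_length` are dropped, as are pairs with non-positive
#' elapsed time (with a warning).
#'
#' @param calls Call table from [call_origins_terminations()].
#' @param min_replicon_length Minimum origin-termination distance in bp
#'   (default 30,000).
#' @param include_boundary Use domain-edge terminations (default TRUE).
#' @return Tibble: `chrom`, `origin_pos`, `termination_pos`, `side`,
#'   `distance_bp`, `elapsed_min`, `velocity_bp_per_min`.
#' @export
estimate_fork_velocity <- function(calls, min_replicon_length = 30000,
                                   include_boundary = TRUE) {
  check_columns(calls, c("chrom", "pos", "type", "t_rep"), "calls")
  if (!include_boundary && "boundary" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$type == "origin" | !.data$boundary)
  }
  out <- calls |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      ori <- which(df$type == "origin")
      term <- which(df$type == "termination")
      purrr::map_dfr(ori, function(i) {
        purrr::map_dfr(c(-1, 1), function(dir) {
          cand <- if (dir < 0) rev(term[term < i]) else term[term > i]
          if (length(cand) == 0L) return(tibble())
          j <- cand[1L]
          tibble(
            origin_pos = df$pos[i],
            termination_pos = df$pos[j],
            side = if (dir < 0) "left" else "right",
            distance_bp = abs(df$pos[j] - df$pos[i]),
            elapsed_min = df$t_rep[j] - df$t_rep[i]
          )
        })
      })
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), origin_pos = numeric(),
                  termination_pos = numeric(), side = character(),
                  distance_bp = numeric(), elapsed_min = numeric(),
                  velocity_bp_per_min = numeric()))
  }
  bad <- out$elapsed_min <= 0
  if (any(bad)) {
    warn(sprintf("excluding %d replicon side(s) with non-positive elapsed time.",
                 sum(bad)))
  }
  out |>
    dplyr::filter(.data$elapsed_min > 0,
                  .data$distance_bp >= min_replicon_length) |>
    dplyr::mutate(velocity_bp_per_min = .data$distance_bp / .data$elapsed_min)
}
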