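#' Simulate an S-phase replication time course
#'
#' Emulates a population of cells released synchronously from G1. Each
#' origin fires in each cell at a time drawn from a Normal law truncated at
#' zero; forks then move at constant speed in both directions, and a locus
#' is replicated by the first fork to reach it. Forks crossing a stall site
#' incur that site's delay for all loci beyond it. Sequencing coverage of a
#' window at time `t` is `1 + fraction of cells that replicated it`
#' (1x unreplicated, 2x replicated); optional Gaussian depth noise is added
#' per window per sample before the track is median-normalised, as real
#' depth tracks are. The per-sample DNA content (the flow-cytometry
#' observable) is the genome-wide mean of the noiseless absolute coverage.
#'
#' The true replication-timing map (`t_rep`) recorded in the truth is the
#' per-window median replication time across the simulated population.
#'
#' @param origins Tibble with columns `position` (bp), `firing_mean` (min)
#'   and optionally `firing_sd` (min, default 0).
#' @param fork_speed Fork velocity in bp/min (> 0).
#' @param genome_length Chromosome length in bp (single contig).
#' @param window_size Bin width in bp (default 100).
#' @param stall_sites Optional tibble with columns `position` (bp) and
#'   `delay` (min) describing fork-stall sites.
#' @param timepoints Sampling times in minutes after release, strictly
#'   increasing and all > 0 (default every 15 min from 15 to 75).
#' @param n_cells Cells in the simulated population (default 10,000).
#'   Memory scales as `n_cells * genome_length / window_size` doubles.
#' @param depth_noise Gaussian SD of per-window coverage noise (0 = none).
#' @param chrom Chromosome name used in the output.
#' @param seed Optional integer seed.
#' @return A tibble (`chrom`, `start`, `end`, `time_min`, `coverage`) of
#'   median-normalised coverage per window per timepoint, with attributes:
#'   `dna_content` (see [dna_content()]) and the simulation truth
#'   ([sim_truth()]) holding the true `t_rep` map, origins, fork speed and
#'   stall sites.
#' @export
#' @examples
#' tc <- simulate_replication_timecourse(
#'   origins = tibble::tibble(position = 1e5, firing_mean = 10),
#'   genome_length = 2e5, n_cells = 50, depth_noise = 0, seed = 1
#' )
#' head(sim_truth(tc)$t_rep)
simulate_replication_timecourse <- function(origins,
                                            fork_speed = 2000,
                                            genome_length = 2e5,
                                            window_size = 100,
                                            stall_sites = NULL,
                                            timepoints = seq(15, 75, by = 15),
                                            n_cells = 10000,
                                            depth_noise = 0.15,
                                            chrom = "chr_sim",
                                            seed = NULL) {
  check_columns(origins, c("position", "firing_mean"), "origins")
  check_number(fork_speed, "fork_speed", min = 0, strict_min = TRUE)
  check_number(genome_length, "genome_length", min = window_size)
  check_number(n_cells, "n_cells", min = 1)
  if (genome_length %% window_size != 0) {
    abort("`genome_length` must be a positive multiple of `window_size`.")
  }
  if (any(origins$position < 0 | origins$position > genome_length)) {
    abort("origin outside genome.")
  }
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0) || timepoints[1] <= 0) {
    abort("`timepoints` must be strictly increasing and start after 0.")
  }
  if (!is.null(stall_sites)) {
    check_columns(stall_sites, c("position", "delay"), "stall_sites")
    if (any(stall_sites$position < 0 | stall_sites$position > genome_length)) {
      abort("stall site outside genome.")
    }
  }
  if (!"firing_sd" %in% names(origins)) origins$firing_sd <- 0

  n_win <- as.integer(genome_length / window_size)
  centers <- (seq_len(n_win) - 0.5) * window_size
  n_ori <- nrow(origins)

  # travel time from each origin to each window centre, stall delays included
  travel <- matrix(0, n_ori, n_win)
  for (o in seq_len(n_ori)) {
    xo <- origins$position[o]
    tt <- abs(centers - xo) / fork_speed
    if (!is.null(stall_sites) && nrow(stall_sites) > 0L) {
      for (s in seq_len(nrow(stall_sites))) {
        p <- stall_sites$position[s]
        crossed <- (xo < p & centers >= p) | (xo > p & centers <= p)
        tt[crossed] <- tt[crossed] + stall_sites$delay[s]
      }
    }
    travel[o, ] <- tt
  }

  res <- with_sim_seed(seed, {
    # firing times: Normal truncated at 0, per cell per origin
    firing <- matrix(0, n_cells, n_ori)
    for (o in seq_len(n_ori)) {
      mu <- origins$firing_mean[o]
      sdv <- origins$firing_sd[o]
      firing[, o] <- if (sdv <= 0) {
        rep(max(mu, 0), n_cells)
      } else {
        u <- runif(n_cells, pnorm(0, mu, sdv), 1)
        qnorm(u, mu, sdv)
      }
    }
    # replication time per cell per window: first fork to arrive
    rep_time <- firing[, 1L] + matrix(travel[1L, ], n_cells, n_win, byrow = TRUE)
    if (n_ori > 1L) {
      for (o in 2L:n_ori) {
        cand <- firing[, o] + matrix(travel[o, ], n_cells, n_win, byrow = TRUE)
        rep_time <- pmin(rep_time, cand)
      }
    }
    t_rep_true <- apply(rep_time, 2L, median)
    cov_abs <- vapply(timepoints, function(t) {
      1 + colSums(rep_time <= t) / n_cells
    }, numeric(n_win))                       # n_win x n_time
    content <- colMeans(cov_abs)
    if (depth_noise > 0) {
      cov_obs <- cov_abs + matrix(
        rnorm(length(cov_abs), sd = depth_noise), nrow(cov_abs)
      )
      cov_obs[cov_obs < 0] <- 0
    } else {
      cov_obs <- cov_abs
    }
    # median-normalise each sample, as sequencing depth tracks are
    cov_norm <- sweep(cov_obs, 2L, apply(cov_obs, 2L, median), "/")
    list(t_rep_true = t_rep_true, content = content, cov_norm = cov_norm)
  })

  tc <- tibble(
    chrom = chrom,
    start = rep((seq_len(n_win) - 1L) * window_size, times = length(timepoints)),
    end = rep(seq_len(n_win) * window_size, times = length(timepoints)),
    time_min = rep(timepoints, each = n_win),
    coverage = as.vector(res$cov_norm)
  )
  truth <- list(
    t_rep = tibble(
      chrom = chrom,
      start = (seq_len(n_win) - 1L) * window_size,
      end = seq_len(n_win) * window_size,
      t_rep_true = res$t_rep_true
    ),
    origins = origins,
    fork_speed = fork_speed,
    stall_sites = stall_sites
  )
  out <- new_sim_result(tc, truth, class = "replication_timecourse")
  attr(out, "dna_content") <- tibble(
    time_min = timepoints,
    dna_content = res$content
  )
  out
}

#' Per-sample DNA content of a replication time course
#'
#' Returns the relative DNA content (1.0 = G1, 2.0 = G2) recorded for each
#' timepoint of a time course — for simulated data the genome-wide mean of
#' the true coverage, for real data the median of the cell-cycle profile
#' supplied alongside the tracks.
#'
#' @param x A `replication_timecourse` (or any object with a `dna_content`
#'   attribute).
#' @return A tibble with columns `time_min`, `dna_content`.
#' @export
dna_content <- function(x) {
  dc <- attr(x, "dna_content", exact = TRUE)
  if (is.null(dc)) abort("`x` carries no DNA-content table.")
  dc
}
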