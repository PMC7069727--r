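#' Simulate evolved/ancestor read-depth tracks with segmental duplications
#'
#' Window read counts are drawn around `mean_depth`; inside each duplicated
#' interval the evolved track's expectation is doubled (a haploid gaining
#' one copy). Noise is Poisson on the raw counts (`noise_dispersion = 1`),
#' negative-binomial when overdispersed (`noise_dispersion > 1` gives
#' variance `dispersion * mean`), or absent (`noise_dispersion = 0`,
#' counts equal to their expectation).
#'
#' @param genome_length Genome length in bp (single contig).
#' @param duplicated_intervals Tibble with columns `start`, `end`
#'   (0-based, half-open bp coordinates) of the segments duplicated in the
#'   evolved clone; must not overlap.
#' @param mean_depth Mean read depth per window of the unduplicated genome.
#' @param noise_dispersion 0 = noiseless, 1 = Poisson, > 1 = overdispersed.
#' @param ancestor_profile Optional numeric vector (one value per window) of
#'   relative depth multipliers shared by both tracks (e.g. mappability
#'   bias); default uniform 1.
#' @param window_size Bin width in bp (default 100).
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#' @return A list with elements `evolved` and `ancestor` (coverage-track
#'   tibbles `chrom`, `start`, `end`, `depth`) and the truth attached to
#'   the list (see [sim_truth()]).
#' @export
#' @examples
#' sim <- simulate_cnv_tracks(
#'   genome_length = 1e4,
#'   duplicated_intervals = tibble::tibble(start = 2000, end = 5000),
#'   noise_dispersion = 0
#' )
#' head(sim$evolved)
simulate_cnv_tracks <- function(genome_length = 5e5,
                                duplicated_intervals = NULL,
                                mean_depth = 50,
                                noise_dispersion = 1,
                                ancestor_profile = NULL,
                                window_size = 100,
                                chrom = "chr_sim",
                                seed = NULL) {
  check_number(mean_depth, "mean_depth", min = 0, strict_min = TRUE)
  check_number(noise_dispersion, "noise_dispersion", min = 0)
  if (genome_length %% window_size != 0) {
    abort("`genome_length` must be a positive multiple of `window_size`.")
  }
  n_win <- as.integer(genome_length / window_size)
  starts <- (seq_len(n_win) - 1L) * window_size

  if (is.null(duplicated_intervals)) {
    duplicated_intervals <- tibble(start = numeric(), end = numeric())
  }
  di <- dplyr::arrange(duplicated_intervals, .data$start)
  if (nrow(di) > 0L) {
    if (any(di$start < 0 | di$end > genome_length | di$end <= di$start)) {
      abort("duplicated intervals must lie within the genome.")
    }
    if (nrow(di) > 1L && any(di$start[-1L] < di$end[-nrow(di)])) {
      abort("duplicated intervals must not overlap.")
    }
  }

  if (is.null(ancestor_profile)) ancestor_profile <- rep(1, n_win)
  if (length(ancestor_profile) != n_win) {
    abort("`ancestor_profile` must have one value per window.")
  }

  copy <- rep(1, n_win)
  centers <- starts + window_size / 2
  for (i in seq_len(nrow(di))) {
    copy[centers >= di$start[i] & centers < di$end[i]] <- 2
  }

  draw <- function(mu) {
    if (noise_dispersion == 0) return(mu)
    if (noise_dispersion == 1) return(rpois(length(mu), mu))
    # NB with variance = dispersion * mean
    size <- mu / (noise_dispersion - 1)
    rnbinom(length(mu), size = size, mu = mu)
  }
  tracks <- with_sim_seed(seed, {
    list(
      anc = draw(mean_depth * ancestor_profile),
      evo = draw(mean_depth * ancestor_profile * copy)
    )
  })

  mk <- function(depth) {
    tibble(chrom = chrom, start = starts, end = starts + window_size,
           depth = as.numeric(depth))
  }
  out <- list(evolved = mk(tracks$evo), ancestor = mk(tracks$anc))
  new_sim_result(out, list(
    duplicated_intervals = di,
    mean_depth = mean_depth,
    noise_dispersion = noise_dispersion,
    window_size = window_size
  ))
}
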