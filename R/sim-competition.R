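#' Simulate serial-dilution competition assays against a fluorescent reference
#'
#' The expected log-ratio of test to reference cells grows linearly with
#' elapsed generations, `ln r(g) = ln r0 + s_true * g`. At each passage the
#' flow cytometer samples `events_per_sample` cells; test-cell counts are
#' drawn binomially from the expected ratio (reference counts are the
#' complement), the sampling noise model for pre-gated event counts. Total
#' event counts at 0 h and 24 h are emitted so that generations per cycle can
#' be recomputed as `log2(events_t24 / events_t0)`.
#'
#' `events_per_sample = Inf` gives the noiseless limit (real-valued expected
#' counts), on which the slope estimator is exact.
#'
#' @param s_true True selection coefficient per generation.
#' @param initial_ratio Test:reference ratio at mixing (> 0).
#' @param generations_per_passage Generations elapsed per 24-h cycle
#'   (default 10, a 1:1000 serial dilution).
#' @param n_passages Number of post-mixing passages (>= 2).
#' @param events_per_sample Flow-cytometry events recorded per sampling;
#'   `Inf` for the noiseless limit.
#' @param n_replicates Independent biological replicates to simulate.
#' @param seed Optional integer seed.
#' @return A tibble with columns `replicate`, `passage`, `test_events`,
#'   `reference_events`, `total_t0`, `total_t24` (passage 0 is the day-0
#'   measurement taken right after mixing; its totals are `NA`, contributing
#'   zero elapsed generations). Simulation truth attached (see
#'   [sim_truth()]).
#' @export
#' @examples
#' cs <- simulate_competition(s_true = 0.05, seed = 1)
#' estimate_selection(cs)
simulate_competition <- function(s_true = 0.05, initial_ratio = 1,
                                 generations_per_passage = 10,
                                 n_passages = 4,
                                 events_per_sample = 50000,
                                 n_replicates = 3, seed = NULL) {
  check_number(initial_ratio, "initial_ratio", min = 0, strict_min = TRUE)
  check_number(n_passages, "n_passages", min = 2)
  check_number(events_per_sample, "events_per_sample", min = 0)
  check_number(generations_per_passage, "generations_per_passage",
               min = 0, strict_min = TRUE)

  base_t0 <- 5000
  truth <- list(
    s_true = s_true, initial_ratio = initial_ratio,
    generations_per_passage = generations_per_passage,
    events_per_sample = events_per_sample
  )

  out <- with_sim_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      passage <- 0:n_passages
      g <- passage * generations_per_passage
      p <- initial_ratio * exp(s_true * g)
      p <- p / (1 + p)
      if (is.infinite(events_per_sample)) {
        n_ev <- 1e6
        test <- n_ev * p
        ref <- n_ev - test
      } else {
        test <- rbinom(length(p), size = events_per_sample, prob = p)
        ref <- events_per_sample - test
      }
      tibble(
        replicate = rep_i,
        passage = passage,
        test_events = test,
        reference_events = ref,
        total_t0 = c(NA, rep(base_t0, n_passages)),
        total_t24 = c(NA, rep(round(base_t0 * 2^generations_per_passage),
                              n_passages))
      )
    })
  })
  new_sim_result(out, truth)
}
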