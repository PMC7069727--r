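toy_profile <- function(t_rep, start = seq_along(t_rep) * 100 - 100,
                        chrom = "c") {
  structure(
    tibble::tibble(chrom = chrom, start = start, end = start + 100,
                   t_rep = t_rep, censored = is.na(t_rep)),
    t_max = 75, threshold = 1.5,
    class = c("replication_profile", "tbl_df", "tbl", "data.frame")
  )
}

test_that("DNA-content scaling fixes the genome-wide mean", {
  tr <- tibble::tibble(chrom = "c", start = 0:9 * 100, end = 0:9 * 100 + 100,
                       coverage = runif(10, 0.5, 1.5))
  for (dc in c(1, 1.4, 2)) {
    expect_equal(mean(scale_to_dna_content(tr, dc)$coverage), dc)
  }
  # a mean-1 track is multiplied by exactly the content
  tr1 <- dplyr::mutate(tr, coverage = coverage / mean(coverage))
  expect_equal(scale_to_dna_content(tr1, 1.4)$coverage, tr1$coverage * 1.4)
  expect_error(scale_to_dna_content(tr, 2.5), "\\[1, 2\\]")
  expect_error(scale_to_dna_content(tr, 0.9), "dna_content")
})

test_that("t_rep interpolates the first upward 1.5x crossing", {
  # two windows, two timepoints: hand-interpolable values
  tc <- tibble::tibble(
    chrom = "c",
    start = rep(c(0, 100), 2), end = rep(c(100, 200), 2),
    time_min = rep(c(15, 30), each = 2),
    coverage = c(1.2, 1.0, 1.8, 1.0)
  )
  prof <- compute_trep(tc, presmooth = FALSE)
  expect_equal(prof$t_rep[prof$start == 0], 22.5)     # 1.2@15 -> 1.8@30
  expect_true(prof$censored[prof$start == 100])       # constant 1.0
  # early-replicating window: implicit (0, 1.0) anchor
  tc2 <- dplyr::mutate(tc, coverage = c(1.75, 1.2, 2.0, 1.8))
  prof2 <- compute_trep(tc2, presmooth = FALSE)
  expect_equal(prof2$t_rep[prof2$start == 0], 15 * 0.5 / 0.75)
})

test_that("unreplicated burden sums late and censored windows", {
  prof <- toy_profile(c(rep(20, 10), rep(50, 30), rep(NA, 5)))
  expect_equal(summarize_unreplicated(prof, 45), 3500)
  expect_equal(summarize_unreplicated(toy_profile(rep(20, 10)), 45), 0)
  # 30 late windows of 100 bp
  expect_equal(summarize_unreplicated(toy_profile(rep(60, 30)), 45), 3000)
})

test_that("a stall stranding 20 kb beyond 45 min is measured to the window", {
  tc <- simulate_replication_timecourse(
    origins = tibble::tibble(position = 0, firing_mean = 10),
    fork_speed = 3000, genome_length = 1e5,
    stall_sites = tibble::tibble(position = 8e4, delay = 30),
    n_cells = 50, depth_noise = 0, seed = 4
  )
  est <- summarize_unreplicated(compute_trep(tc), 45)
  expect_lte(abs(est - 2e4), 200)
})

test_that("censoring the last timepoint never changes earlier t_rep values", {
  tc <- simulate_replication_timecourse(
    origins = tibble::tibble(position = 1e5, firing_mean = 10),
    genome_length = 2e5, n_cells = 20, depth_noise = 0, seed = 1
  )
  full <- compute_trep(tc)
  shorter <- compute_trep(dplyr::filter(tc, time_min <= 60),
                          dna_content = dna_content(tc))
  kept <- !shorter$censored
  expect_true(all(!full$censored[kept]))
  expect_equal(shorter$t_rep[kept], full$t_rep[kept])
  expect_gte(sum(shorter$censored), sum(full$censored))
})

test_that("origins are timing minima, terminations maxima, alternating", {
  # V-shaped timing: single origin in the middle, no interior termination
  v <- c(seq(40, 10, length.out = 200), seq(10.2, 40, length.out = 200))
  calls <- call_origins_terminations(toy_profile(v), lowpass_cutoff = 5000)
  ori <- calls[calls$type == "origin", ]
  expect_equal(nrow(ori), 1)
  expect_lt(abs(ori$pos - 20000), 2000)
  expect_true(all(calls$boundary[calls$type == "termination"]))
  # alternation along the chromosome
  expect_true(all(rle(calls$type)$lengths == 1))
  # monotone timing: no interior origin
  mono <- call_origins_terminations(toy_profile(seq(10, 40, length.out = 300)),
                                    lowpass_cutoff = 5000)
  expect_equal(sum(mono$type == "origin"), 0)
  # flat timing: no calls at all
  flat <- call_origins_terminations(toy_profile(rep(25, 300)),
                                    lowpass_cutoff = 5000)
  expect_equal(nrow(flat), 0)
})

test_that("more aggressive low-pass filtering never creates extrema", {
  withr::with_seed(31, {
    x <- 25 + cumsum(rnorm(600, sd = 0.8))
    prof <- toy_profile(x)
    cuts <- c(5000, 10000, 20000, 40000)
    n_ori <- vapply(cuts, function(co) {
      sum(call_origins_terminations(prof, lowpass_cutoff = co,
                                    min_prominence = 0)$type == "origin")
    }, numeric(1))
    expect_true(all(diff(n_ori) <= 0))
  })
})

test_that("short domains are skipped with a warning", {
  prof <- toy_profile(c(seq(30, 10, length.out = 20)))
  expect_warning(calls <- call_origins_terminations(prof,
                                                    lowpass_cutoff = 20000),
                 "shorter than filter support")
  expect_equal(nrow(calls), 0)
})

test_that("fork velocity divides replicon distance by timing difference", {
  calls <- tibble::tibble(
    chrom = "c",
    pos = c(1e5, 1.6e5),
    type = c("origin", "termination"),
    t_rep = c(10, 40),
    boundary = FALSE
  )
  fv <- estimate_fork_velocity(calls, min_replicon_length = 3e4)
  expect_equal(fv$velocity_bp_per_min, 2000)
  expect_equal(fv$side, "right")
  # shorter than the replicon threshold: excluded
  none <- estimate_fork_velocity(calls, min_replicon_length = 1e5)
  expect_equal(nrow(none), 0)
  # non-positive elapsed time: excluded with a warning
  calls$t_rep <- c(40, 10)
  expect_warning(out <- estimate_fork_velocity(calls, 3e4), "non-positive")
  expect_equal(nrow(out), 0)
})

test_that("noiseless two-origin simulation yields the true replicon anatomy", {
  tc <- simulate_replication_timecourse(
    origins = tibble::tibble(position = c(5e4, 1.5e5), firing_mean = 10),
    fork_speed = 2000, genome_length = 2e5, n_cells = 20,
    depth_noise = 0, seed = 1
  )
  prof <- compute_trep(tc)
  tr <- sim_truth(tc)$t_rep
  expect_true(all(abs(prof$t_rep - tr$t_rep_true)[!prof$censored] <= 15))
  calls <- call_origins_terminations(prof)
  ori <- calls[calls$type == "origin", ]
  interior_term <- calls[calls$type == "termination" & !calls$boundary, ]
  expect_equal(nrow(ori), 2)
  expect_true(all(abs(sort(ori$pos) - c(5e4, 1.5e5)) <= 2000))
  expect_equal(nrow(interior_term), 1)
  expect_lt(abs(interior_term$pos - 1e5), 5000)
  # t_rep is monotone along each fork path between origin and termination
  # (checked on the unsmoothed profile: genome smoothing is for noisy data)
  raw <- compute_trep(tc, presmooth = FALSE)
  path <- raw$t_rep[raw$start >= 5e4 & raw$start <= 1e5]
  expect_true(all(diff(path) >= -1e-9))
})
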