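test_that("generations per cycle follow the event-count and dilution rules", {
  expect_equal(generations_elapsed(1e4, 1e4), 0)
  expect_equal(generations_elapsed(1e4, 8e4), 3)
  # 1:1000 serial dilution: ~10 generations/cycle
  g <- generations_elapsed()
  expect_equal(g, log2(1000))
  expect_equal(round(g), 10)
  expect_error(generations_elapsed(0, 100), "> 0")
})

test_that("ratio series gives cumulative generations and log ratios", {
  s <- tibble::tibble(
    passage = 0:2,
    test_events = c(1000, 2000, 2000),
    reference_events = c(1000, 1000, 2000),
    total_t0 = c(NA, 100, 100), total_t24 = c(NA, 800, 800)
  )
  rs <- ratio_series(s)
  expect_equal(rs$g, c(0, 3, 6))
  expect_equal(rs$ln_ratio, c(0, log(2), 0))
  s$reference_events[2] <- 0
  expect_error(ratio_series(s), "passage 1")
})

test_that("slope estimator is exact on noiseless exponential dynamics", {
  cs <- simulate_competition(s_true = 0.05, events_per_sample = Inf,
                             n_passages = 5)
  fit <- estimate_selection(cs)
  expect_equal(fit$s, 0.05, tolerance = 1e-9)
  expect_equal(fit$s_sd, 0, tolerance = 1e-9)
  expect_equal(fit$n_replicates, 3)
  # neutral strain: flat log ratio
  cs0 <- simulate_competition(s_true = 0, events_per_sample = Inf)
  rs <- ratio_series(cs0)
  expect_equal(diff(rs$ln_ratio[rs$replicate == 1]), rep(0, 4),
               tolerance = 1e-12)
  # works for other s and r0 too
  cs2 <- simulate_competition(s_true = -0.13, initial_ratio = 4,
                              events_per_sample = Inf)
  expect_equal(estimate_selection(cs2)$s, -0.13, tolerance = 1e-9)
})

test_that("swapping test and reference labels negates the estimate", {
  cs <- simulate_competition(s_true = 0.07, seed = 5)
  swapped <- dplyr::rename(cs, test_events = reference_events,
                           reference_events = test_events)
  expect_equal(estimate_selection(swapped)$s, -estimate_selection(cs)$s,
               tolerance = 1e-12)
})

test_that("estimate is invariant to uniform rescaling of event counts", {
  cs <- simulate_competition(s_true = 0.05, seed = 7)
  scaled <- dplyr::mutate(cs, test_events = test_events * 17,
                          reference_events = reference_events * 17)
  expect_equal(estimate_selection(scaled)$s, estimate_selection(cs)$s,
               tolerance = 1e-12)
})

test_that("stochastic sampling recovers the true selection coefficient", {
  est <- withr::with_seed(42, {
    vapply(1:40, function(i) {
      cs <- simulate_competition(s_true = 0.05, n_passages = 5,
                                 events_per_sample = 50000, n_replicates = 1)
      estimate_selection(cs)$s
    }, numeric(1))
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.05), 3 * se)
})

test_that("bias of the estimator shrinks as sampling noise drops", {
  bias_at <- function(events) {
    est <- withr::with_seed(99, {
      vapply(1:30, function(i) {
        cs <- simulate_competition(s_true = 0.08, events_per_sample = events,
                                   n_replicates = 1)
        estimate_selection(cs)$s
      }, numeric(1))
    })
    abs(mean(est) - 0.08)
  }
  b <- vapply(c(500, 5000, 5e5), bias_at, numeric(1))
  expect_lt(b[3], 0.005)
  expect_lt(b[3], b[1] + 0.005)
})

test_that("degenerate replicates are excluded with a warning, then error", {
  s <- tibble::tibble(
    replicate = c(1, 1, 1, 2),
    passage = c(0, 1, 2, 0),
    test_events = c(1000, 1100, 1210, 900),
    reference_events = rep(1000, 4),
    total_t0 = c(NA, 100, 100, NA), total_t24 = c(NA, 800, 800, NA)
  )
  expect_warning(fit <- estimate_selection(s), "excluding 1 replicate")
  expect_equal(fit$n_replicates, 1)
  one_pt <- s[4, ]
  suppressWarnings(expect_error(estimate_selection(one_pt), "replicates"))
})

test_that("reference-frame conversion follows f_wt = f_ref * (1 + s)", {
  expect_equal(convert_reference_fitness(0.27, 0.73), 0.9271)
  expect_equal(round(convert_reference_fitness(0.27, 0.73), 2), 0.93)
  expect_equal(convert_reference_fitness(0, 0.73), 0.73)
  expect_equal(convert_reference_fitness(0.25, 0.80), 1.00)
  expect_error(convert_reference_fitness(0.1, 0), "> 0")
})

test_that("Welch comparison detects a real fitness difference", {
  withr::with_seed(8, {
    f1 <- estimate_selection(simulate_competition(s_true = 0.10,
                                                  n_replicates = 4))
    f2 <- estimate_selection(simulate_competition(s_true = 0.00,
                                                  n_replicates = 4))
  })
  cmp <- compare_fitness(f1, f2)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$difference, 0.05)
})

test_that("tidy and glance expose replicate slopes and the summary", {
  cs <- simulate_competition(s_true = 0.05, events_per_sample = Inf)
  fit <- estimate_selection(cs)
  expect_equal(nrow(tidy(fit)), 3)
  gl <- glance(fit)
  expect_named(gl, c("s", "s_sd", "n_replicates"))
  expect_equal(gl$s, 0.05, tolerance = 1e-9)
})
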