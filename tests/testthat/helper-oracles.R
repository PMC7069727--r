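# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (direct summation, closed forms, per-locus arithmetic)
# so they never share code with the implementation they check.

# brute-force Poisson upper tail by pmf summation
brute_poisson_tail <- function(n, mu) {
  if (n == 0) return(1)
  kmax <- max(n + 50, ceiling(mu + 40 * sqrt(mu + 1)))
  sum(dpois(n:kmax, mu))
}

# Benjamini-Hochberg step-up rejections computed by hand
brute_bh_reject <- function(p, alpha, m = length(p)) {
  ord <- order(p)
  thr <- seq_along(p) * alpha / m
  passed <- which(p[ord] <= thr)
  reject <- rep(FALSE, length(p))
  if (length(passed) > 0) reject[ord[seq_len(max(passed))]] <- TRUE
  reject
}

# analytic replication time of one locus for deterministic origin firing:
# first fork to arrive wins; forks crossing a stall site carry its delay
analytic_rep_time <- function(x, origins, fork_speed, stall_sites = NULL) {
  times <- vapply(seq_len(nrow(origins)), function(o) {
    xo <- origins$position[o]
    tt <- origins$firing_mean[o] + abs(x - xo) / fork_speed
    if (!is.null(stall_sites)) {
      for (s in seq_len(nrow(stall_sites))) {
        p <- stall_sites$position[s]
        if ((xo < p && x >= p) || (xo > p && x <= p)) {
          tt <- tt + stall_sites$delay[s]
        }
      }
    }
    tt
  }, numeric(1))
  min(times)
}

# toy gene-model table with explicit lengths
toy_genes <- function(n, coding = 1500, pad = 1000) {
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    coding_length = coding,
    regulatory_pad = pad,
    effective_length = coding + pad
  )
}

# minimal mutation table: one row per (population, gene) entry
toy_mutations <- function(gene_ids, populations) {
  tibble::tibble(
    population_id = populations,
    gene_id = gene_ids,
    position = 1,
    ref = "A", alt = "T",
    effect = "nonsynonymous",
    mutant_read_fraction = 0.5
  )
}
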