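#' Estimate the per-base mutation rate of a background
#'
#' The rate is the total number of mutation records (SNPs + indels falling
#' in coding or regulatory scope) divided by the size of the coding genome,
#' regulatory padding included: `lambda = n_mutations / coding_genome_bp`.
#' Rates are computed separately per background by calling this once per
#' mutation table.
#'
#' @param mutations Mutation-record tibble (one row per called mutation).
#' @param coding_genome_bp Total effective target size in bp (> 0),
#'   typically `sum(gene_models$effective_length)`.
#' @return One-row tibble: `lambda_per_bp`, `n_mutations`,
#'   `coding_genome_bp`.
#' @export
#' @examples
#' gm <- sim_gene_models(100)
#' mut <- simulate_mutations(gm, seed = 1)
#' estimate_mutation_rate(mut, sum(gm$effective_length))
estimate_mutation_rate <- function(mutations, coding_genome_bp) {
  check_number(coding_genome_bp, "coding_genome_bp", min = 0, strict_min = TRUE)
  n <- nrow(mutations)
  tibble(
    lambda_per_bp = n / coding_genome_bp,
    n_mutations = n,
    coding_genome_bp = coding_genome_bp
  )
}

#' Poisson upper-tail p-value for recurrent mutation of a gene
#'
#' Probability of observing at least `n` mutations in a gene of effective
#' length `N` bp if mutations land uniformly at rate `lambda_per_bp`,
#' i.e. `P(X >= n)` for `X ~ Poisson(lambda * N)`.
#'
#' `legacy_tail = TRUE` instead evaluates
#' `1 - Gamma(n + 1, lambda * N) / n!` (the regularised upper incomplete
#' gamma complement), which equals `P(X >= n + 1)` — an off-by-one variant
#' of the survival probability that appears in some published pipelines.
#' The default is the mathematically correct tail.
#'
#' @param n Observed mutation count (non-negative integer, vectorised).
#' @param N Effective gene length in bp (> 0).
#' @param lambda_per_bp Per-base mutation rate (>= 0).
#' @param legacy_tail Reproduce the off-by-one printed expression.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
#' @examples
#' poisson_tail_pvalue(2, N = 1000, lambda_per_bp = 1e-3) # P(X >= 2), X~Pois(1)
poisson_tail_pvalue <- function(n, N, lambda_per_bp, legacy_tail = FALSE) {
  if (any(n < 0) || any(n != floor(n))) {
    abort("`n` must contain non-negative integers.")
  }
  if (any(N <= 0)) abort("`N` must be > 0.")
  if (any(lambda_per_bp < 0)) abort("`lambda_per_bp` must be >= 0.")
  mu <- lambda_per_bp * N
  k <- if (legacy_tail) n else n - 1
  ppois(k, mu, lower.tail = FALSE)
}

#' Multiple-testing significance flags
#'
#' Applies Bonferroni (`reject iff p <= alpha / m`) or Benjamini-Hochberg
#' step-up (`reject ranks 1..i*` where `i*` is the largest `i` with
#' `p_(i) <= i * alpha / m`) control over `m` tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @param alpha Significance level in `(0, 1)`.
#' @param m Number of tests controlled for (default `length(p_values)`;
#'   set larger when untested hypotheses — e.g. unmutated genes — count).
#' @return Tibble with `p_value`, `p_adjusted`, `significant`.
#' @export
adjust_pvalues <- function(p_values,
                           method = c("bonferroni", "benjamini_hochberg"),
                           alpha = 0.05, m = length(p_values)) {
  method <- match.arg(method)
  if (length(p_values) == 0L) {
    return(tibble(p_value = numeric(), p_adjusted = numeric(),
                  significant = logical()))
  }
  if (any(p_values < 0 | p_values > 1)) abort("p-values must lie in [0, 1].")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (m < length(p_values)) abort("`m` must be >= length(p_values).")
  adj <- p.adjust(p_values,
                  method = if (method == "bonferroni") "bonferroni" else "BH",
                  n = m)
  tibble(p_value = p_values, p_adjusted = adj, significant = adj <= alpha)
}

#' Scan for convergently mutated genes across parallel populations
#'
#' For each background the per-base mutation rate is estimated from its own
#' table ([estimate_mutation_rate()]); every mutated gene then gets a
#' Poisson upper-tail p-value against `lambda * effective_length`
#' ([poisson_tail_pvalue()]). The control-background (e.g. evolved wild
#' type) gene list is corrected by Bonferroni, the focal background (e.g.
#' the mutant lineage) by Benjamini-Hochberg, both at `alpha`. Genes
#' significant in the control background are removed from the focal result
#' before reporting — recurrence there marks adaptation to the propagation
#' regime rather than to the perturbation under study.
#'
#' @param mutant_table Mutation records of the focal (perturbed) lineage.
#' @param wt_table Mutation records of the control lineage; `NULL` skips
#'   the control filter.
#' @param gene_models Gene-model tibble (columns `gene_id` and
#'   `effective_length`, or `coding_length` + `regulatory_pad`).
#' @param alpha Significance level for both corrections (default 0.05).
#' @param m_mode `"all_genes"`: the number of tests m is the full gene-model
#'   set (default); `"mutated_genes"`: only genes with >= 1 mutation in the
#'   respective background.
#' @param legacy_tail Passed to [poisson_tail_pvalue()].
#' @return A tibble (class `convergence_scan`) with one row per mutated
#'   focal gene: `gene_id`, `n`, `populations_hit`, `effective_length`,
#'   `p_value`, `p_bonferroni`, `p_bh`, `sig_bonferroni`, `sig_bh`, sorted
#'   by `p_value`. Attributes record `lambda` per background, `m`, `alpha`
#'   and the control-significant genes that were filtered out.
#' @export
#' @examples
#' gm <- sim_gene_models(200)
#' mut <- simulate_mutations(gm, spiked_genes = gm$gene_id[1:3], seed = 1)
#' wt <- simulate_mutations(gm, seed = 2)
#' head(convergence_scan(mut, wt, gm))
convergence_scan <- function(mutant_table, wt_table, gene_models,
                             alpha = 0.05,
                             m_mode = c("all_genes", "mutated_genes"),
                             legacy_tail = FALSE) {
  m_mode <- match.arg(m_mode)
  check_columns(gene_models, "gene_id", "gene_models")
  gm <- gene_models
  if (!"effective_length" %in% names(gm)) {
    check_columns(gm, c("coding_length", "regulatory_pad"), "gene_models")
    gm$effective_length <- gm$coding_length + gm$regulatory_pad
  }
  coding_bp <- sum(gm$effective_length)

  per_background <- function(tab, label) {
    check_columns(tab, c("population_id", "gene_id"), label)
    unknown <- setdiff(unique(tab$gene_id), gm$gene_id)
    if (length(unknown) > 0L) {
      abort(sprintf("gene(s) in `%s` absent from `gene_models`: %s",
                    label, paste(unknown, collapse = ", ")))
    }
    lambda <- estimate_mutation_rate(tab, coding_bp)$lambda_per_bp
    counts <- tab |>
      dplyr::count(.data$gene_id, name = "n") |>
      dplyr::left_join(
        dplyr::distinct(tab, .data$gene_id, .data$population_id) |>
          dplyr::count(.data$gene_id, name = "populations_hit"),
        by = "gene_id"
      ) |>
      dplyr::left_join(dplyr::select(gm, "gene_id", "effective_length"),
                       by = "gene_id") |>
      dplyr::mutate(p_value = poisson_tail_pvalue(
        .data$n, .data$effective_length, lambda, legacy_tail = legacy_tail
      ))
    m <- if (m_mode == "all_genes") nrow(gm) else nrow(counts)
    list(counts = counts, lambda = lambda, m = m)
  }

  wt_sig <- character()
  lambda_wt <- NA_real_
  if (!is.null(wt_table)) {
    wt <- per_background(wt_table, "wt_table")
    lambda_wt <- wt$lambda
    wt_flags <- adjust_pvalues(wt$counts$p_value, "bonferroni",
                               alpha = alpha, m = wt$m)
    wt_sig <- wt$counts$gene_id[wt_flags$significant]
  }

  mt <- per_background(mutant_table, "mutant_table")
  bonf <- adjust_pvalues(mt$counts$p_value, "bonferroni", alpha = alpha, m = mt$m)
  bh <- adjust_pvalues(mt$counts$p_value, "benjamini_hochberg",
                       alpha = alpha, m = mt$m)
  res <- mt$counts |>
    dplyr::mutate(
      p_bonferroni = bonf$p_adjusted,
      p_bh = bh$p_adjusted,
      sig_bonferroni = bonf$significant,
      sig_bh = bh$significant
    ) |>
    dplyr::filter(!.data$gene_id %in% wt_sig) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$n))

  structure(
    res,
    lambda_mutant = mt$lambda,
    lambda_wt = lambda_wt,
    m = mt$m,
    alpha = alpha,
    wt_filtered_genes = wt_sig,
    class = c("convergence_scan", class(res))
  )
}

#' @export
glance.convergence_scan <- function(x, ...) {
  tibble(
    n_genes_tested = attr(x, "m"),
    n_genes_mutated = nrow(x),
    n_significant_bh = sum(x$sig_bh),
    n_significant_bonferroni = sum(x$sig_bonferroni),
    n_wt_filtered = length(attr(x, "wt_filtered_genes")),
    lambda_mutant = attr(x, "lambda_mutant"),
    lambda_wt = attr(x, "lambda_wt"),
    alpha = attr(x, "alpha")
  )
}
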