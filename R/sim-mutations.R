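#' Build a synthetic gene-model table
#'
#' Convenience constructor for the gene-model table consumed by
#' [simulate_mutations()] and [convergence_scan()]. Each gene gets a coding
#' length plus a fixed regulatory pad; the effective target size is
#' `N = coding_length + regulatory_pad`.
#'
#' @param n_genes Number of genes.
#' @param coding_length Coding length per gene in bp (recycled).
#' @param regulatory_pad Regulatory padding added per ORF in bp (default
#'   1,000, i.e. 500 bp on each side of the coding sequence).
#' @return A tibble with columns `gene_id`, `coding_length`,
#'   `regulatory_pad`, `effective_length`.
#' @export
#' @examples
#' sim_gene_models(5)
sim_gene_models <- function(n_genes = 1000, coding_length = 1500,
                            regulatory_pad = 1000) {
  check_number(n_genes, "n_genes", min = 1)
  if (any(coding_length <= 0)) abort("`coding_length` must be positive.")
  if (any(regulatory_pad < 0)) abort("`regulatory_pad` must be >= 0.")
  tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    coding_length = rep_len(as.numeric(coding_length), n_genes),
    regulatory_pad = rep_len(as.numeric(regulatory_pad), n_genes)
  ) |>
    dplyr::mutate(effective_length = .data$coding_length + .data$regulatory_pad)
}

#' Simulate per-population mutation tables under a Poisson null
#'
#' Draws, for every gene in every population, a mutation count from a
#' Poisson law with mean `rate_per_bp * effective_length`; genes named in
#' `spiked_genes` have their rate multiplied by `spike_multiplier`,
#' emulating convergent targets of selection. Counts are expanded into
#' per-record rows with a position inside the gene, ref/alt alleles, an
#' effect class (nonsynonymous vs regulatory, proportional to the coding
#' and pad shares of the target) and a mutant-read fraction.
#'
#' @param gene_models Gene-model tibble as from [sim_gene_models()]
#'   (columns `gene_id`, `coding_length`, `regulatory_pad` or
#'   `effective_length`).
#' @param rate_per_bp Per-base mutation rate of the background
#'   (mutations/bp over the whole experiment). Default 8e-5, the scale of
#'   an eight-population, 1,000-generation serial-dilution experiment.
#' @param spiked_genes Character vector of gene ids under convergent
#'   selection.
#' @param spike_multiplier Rate multiplier for spiked genes (>= 1).
#' @param n_populations Number of independently evolved populations.
#' @param seed Optional integer seed; a fixed seed gives bit-identical
#'   output.
#' @return A tibble of mutation records (`population_id`, `gene_id`,
#'   `position`, `ref`, `alt`, `effect`, `mutant_read_fraction`) with the
#'   simulation truth attached (see [sim_truth()]).
#' @export
#' @examples
#' gm <- sim_gene_models(50)
#' mut <- simulate_mutations(gm, rate_per_bp = 1e-4, n_populations = 4, seed = 1)
#' sim_truth(mut)$spiked_genes
simulate_mutations <- function(gene_models, rate_per_bp = 8e-5,
                               spiked_genes = character(),
                               spike_multiplier = 10,
                               n_populations = 8, seed = NULL) {
  check_columns(gene_models, c("gene_id", "coding_length"), "gene_models")
  if (nrow(gene_models) == 0L) abort("`gene_models` must contain at least one gene.")
  check_number(rate_per_bp, "rate_per_bp", min = 0)
  check_number(spike_multiplier, "spike_multiplier", min = 1)
  check_number(n_populations, "n_populations", min = 1)
  if (any(gene_models$coding_length <= 0)) abort("gene lengths must be positive.")
  gm <- gene_models
  if (!"effective_length" %in% names(gm)) {
    pad <- if ("regulatory_pad" %in% names(gm)) gm$regulatory_pad else 1000
    gm$effective_length <- gm$coding_length + pad
  }
  unknown <- setdiff(spiked_genes, gm$gene_id)
  if (length(unknown) > 0L) {
    abort(sprintf("spiked gene(s) not in `gene_models`: %s",
                  paste(unknown, collapse = ", ")))
  }

  truth <- list(
    spiked_genes = spiked_genes,
    spike_multiplier = spike_multiplier,
    rate_per_bp = rate_per_bp,
    n_populations = n_populations,
    coding_genome_bp = sum(gm$effective_length)
  )

  bases <- c("A", "C", "G", "T")
  records <- with_sim_seed(seed, {
    mult <- ifelse(gm$gene_id %in% spiked_genes, spike_multiplier, 1)
    mu <- rate_per_bp * gm$effective_length * mult
    counts <- rpois(nrow(gm) * n_populations, rep(mu, times = n_populations))
    idx <- rep(rep(seq_len(nrow(gm)), times = n_populations), counts)
    pop <- rep(rep(seq_len(n_populations), each = nrow(gm)), counts)
    n <- length(idx)
    if (n == 0L) {
      tibble(
        population_id = character(), gene_id = character(),
        position = numeric(), ref = character(), alt = character(),
        effect = character(), mutant_read_fraction = numeric()
      )
    } else {
      len <- gm$effective_length[idx]
      pos <- floor(runif(n) * len)
      coding_share <- gm$coding_length[idx] / len
      ref <- sample(bases, n, replace = TRUE)
      alt_shift <- sample.int(3L, n, replace = TRUE)
      tibble(
        population_id = sprintf("pop%02d", pop),
        gene_id = gm$gene_id[idx],
        position = pos,
        ref = ref,
        alt = bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L],
        effect = ifelse(runif(n) < coding_share, "nonsynonymous", "regulatory"),
        mutant_read_fraction = runif(n)
      )
    }
  })
  records <- dplyr::arrange(records, .data$population_id, .data$gene_id,
                            .data$position)
  new_sim_result(records, truth)
}
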