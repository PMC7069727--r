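#' Simulate point features with controlled enrichment inside zones
#'
#' Places `n_features` point features on the genome with placement density
#' multiplied by `enrichment_factor` inside the supplied zones relative to
#' the uniform background, then normalised — so with zones covering a
#' fraction `z` of the genome the expected in-zone share is
#' `f*z / (f*z + (1 - z))`.
#'
#' @param genome_length Genome length in bp (single contig).
#' @param zones Tibble with columns `start`, `end` (bp) of the enriched
#'   zones; overlaps are merged internally.
#' @param n_features Number of features to place (>= 0).
#' @param enrichment_factor In-zone density multiplier (> 0; 1 = uniform,
#'   < 1 = depletion).
#' @param feature_class Value for the BED name column.
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#' @return A BED-style tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) of 1-bp features, truth attached (see [sim_truth()]).
#' @export
simulate_feature_annotations <- function(genome_length, zones, n_features,
                                         enrichment_factor = 1,
                                         feature_class = "feature",
                                         chrom = "chr_sim",
                                         seed = NULL) {
  check_number(genome_length, "genome_length", min = 1)
  if (n_features < 0) abort("`n_features` must be >= 0.")
  check_number(enrichment_factor, "enrichment_factor", min = 0, strict_min = TRUE)
  check_columns(zones, c("start", "end"), "zones")
  if (nrow(zones) > 0L &&
      any(zones$start < 0 | zones$end > genome_length | zones$end < zones$start)) {
    abort("zones must lie within the genome.")
  }
  # merge overlapping zones
  ir <- IRanges::reduce(IRanges::IRanges(zones$start + 1L, zones$end))
  zstart <- IRanges::start(ir) - 1L
  zwidth <- IRanges::width(ir)
  zone_bp <- sum(zwidth)
  out_bp <- genome_length - zone_bp

  w_in <- enrichment_factor * zone_bp
  p_in <- w_in / (w_in + out_bp)
  if (zone_bp == 0) p_in <- 0
  if (out_bp == 0) p_in <- 1

  pos <- with_sim_seed(seed, {
    in_zone <- runif(n_features) < p_in
    pos <- numeric(n_features)
    n_in <- sum(in_zone)
    if (n_in > 0L) {
      # uniform over the merged zone bp
      u <- runif(n_in) * zone_bp
      cum <- cumsum(zwidth)
      idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      pos[in_zone] <- zstart[idx] + (u - c(0, cum)[idx])
    }
    n_out <- n_features - n_in
    if (n_out > 0L) {
      # uniform over the complement via cumulative gap lengths
      gaps_start <- c(0, zstart + zwidth)
      gaps_end <- c(zstart, genome_length)
      gw <- gaps_end - gaps_start
      keep <- gw > 0
      gaps_start <- gaps_start[keep]; gw <- gw[keep]
      u <- runif(n_out) * sum(gw)
      cum <- cumsum(gw)
      idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      pos[!in_zone] <- gaps_start[idx] + (u - c(0, cum)[idx])
    }
    floor(pos)
  })

  feats <- tibble(
    chrom = chrom, start = pos, end = pos + 1,
    name = feature_class, score = 0L, strand = "."
  ) |>
    dplyr::arrange(.data$start)
  new_sim_result(feats, list(
    enrichment_factor = enrichment_factor,
    zone_bp = zone_bp,
    genome_length = genome_length,
    p_in_zone = p_in,
    n_features = n_features
  ))
}
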