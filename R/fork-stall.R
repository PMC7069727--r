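#' Build fork-stall zones around late fork positions
#'
#' Each fork position (e.g. the boundary of a region still unreplicated at
#' 45 min) becomes the centre of a zone extending `flank` bp on each side,
#' clipped to the chromosome and merged where overlapping.
#'
#' @param positions Tibble with columns `chrom`, `pos` (bp).
#' @param genome Tibble with columns `chrom`, `length` (bp).
#' @param flank Half-width of each zone in bp (default 5,000).
#' @return A `stall_zones` tibble (`chrom`, `start`, `end`) with
#'   attributes `zone_bp` and `genome_bp`.
#' @export
#' @examples
#' build_stall_zones(
#'   tibble::tibble(chrom = "chrI", pos = 1e5),
#'   genome = tibble::tibble(chrom = "chrI", length = 1e6)
#' )
build_stall_zones <- function(positions, genome, flank = 5000) {
  check_columns(positions, c("chrom", "pos"), "positions")
  check_columns(genome, c("chrom", "length"), "genome")
  check_number(flank, "flank", min = 0)
  genome_bp <- sum(genome$length)
  if (nrow(positions) > 0L) {
    len <- genome$length[match(positions$chrom, genome$chrom)]
    if (anyNA(len)) abort("position on a chromosome absent from `genome`.")
    if (any(positions$pos < 0 | positions$pos > len)) {
      abort("fork position outside its chromosome.")
    }
  }
  if (nrow(positions) == 0L) {
    zones <- tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    gr <- GenomicRanges::GRanges(
      positions$chrom,
      IRanges::IRanges(
        pmax(positions$pos - flank, 0) + 1L,
        pmin(positions$pos + flank,
             genome$length[match(positions$chrom, genome$chrom)])
      )
    )
    gr <- GenomicRanges::reduce(gr)
    zones <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr))
    )
  }
  structure(zones,
            zone_bp = sum(zones$end - zones$start),
            genome_bp = genome_bp,
            class = c("stall_zones", class(zones)))
}

#' Test feature classes for enrichment in fork-stall zones
#'
#' Counts how many features fall inside the zones (by midpoint, or by any
#' overlap), computes the expectation under genome-uniform placement
#' (`expected = n_features * zone_bp / genome_bp`), and compares observed
#' vs expected over the in-zone/out-of-zone cells by a 1-df chi-square
#' goodness-of-fit test. When the features carry a `class`/`name` column,
#' one test is reported per class.
#'
#' @param features BED-style tibble (`chrom`, `start`, `end`, optionally
#'   `class` or `name`).
#' @param zones A `stall_zones` object from [build_stall_zones()].
#' @param by Membership rule: `"midpoint"` (default) or `"any_overlap"`.
#' @param correct Apply Yates' continuity correction (default FALSE).
#' @return Tibble per feature class: `feature_class`, `n_total`,
#'   `observed_in_zones`, `expected_in_zones`, `chi_square`, `p_value`,
#'   `direction` (`"over"`/`"under"`/`"none"`), `low_count` (TRUE when an
#'   expected cell < 1; the test is still reported).
#' @export
feature_enrichment <- function(features, zones,
                               by = c("midpoint", "any_overlap"),
                               correct = FALSE) {
  by <- match.arg(by)
  check_columns(features, c("chrom", "start", "end"), "features")
  zone_bp <- attr(zones, "zone_bp", exact = TRUE)
  genome_bp <- attr(zones, "genome_bp", exact = TRUE)
  if (is.null(zone_bp) || is.null(genome_bp)) {
    abort("`zones` must come from build_stall_zones().")
  }
  cls_col <- intersect(c("class", "name"), names(features))[1]
  feats <- features
  feats$feature_class <- if (is.na(cls_col)) "all" else features[[cls_col]]

  gr_zone <- GenomicRanges::GRanges(
    zones$chrom, IRanges::IRanges(zones$start + 1L, zones$end)
  )
  gr_feat <- if (by == "midpoint") {
    mid <- floor((feats$start + feats$end) / 2)
    GenomicRanges::GRanges(feats$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  } else {
    GenomicRanges::GRanges(feats$chrom,
                           IRanges::IRanges(feats$start + 1L, feats$end))
  }
  feats$in_zone <- IRanges::overlapsAny(gr_feat, gr_zone)

  frac <- zone_bp / genome_bp
  feats |>
    dplyr::group_by(.data$feature_class) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      observed_in_zones = sum(.data$in_zone),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      expected_in_zones = .data$n_total * frac,
      chi_square = purrr::map2_dbl(
        .data$observed_in_zones, .data$n_total,
        function(o, n) {
          e_in <- n * frac
          e_out <- n * (1 - frac)
          if (e_in == 0 || e_out == 0) return(0)
          adj <- if (correct) 0.5 else 0
          d_in <- max(abs(o - e_in) - adj, 0)
          d_out <- max(abs((n - o) - e_out) - adj, 0)
          d_in^2 / e_in + d_out^2 / e_out
        }
      ),
      p_value = pchisq(.data$chi_square, df = 1, lower.tail = FALSE),
      direction = dplyr::case_when(
        .data$observed_in_zones > .data$expected_in_zones ~ "over",
        .data$observed_in_zones < .data$expected_in_zones ~ "under",
        TRUE ~ "none"
      ),
      low_count = .data$expected_in_zones < 1 |
        (.data$n_total - .data$expected_in_zones) < 1
    )
}
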