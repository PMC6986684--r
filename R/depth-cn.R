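#' Expected single-copy coverage
#'
#' Genome-wide average depth at single-copy sites: total aligned bases
#' divided by genome size. This is the denominator that turns region mean
#' depth into a copy-number estimate.
#'
#' @param total_aligned_bases Total aligned bases for the library (bp).
#' @param genome_size Genome size (bp); 818 Mb for female plants, 843 Mb for
#'   male plants.
#' @return Expected coverage in depth units. Vectorized over both arguments.
#' @examples
#' expected_coverage(8.43e9, 843e6) # 10x
#' @export
expected_coverage <- function(total_aligned_bases, genome_size) {
  if (!is.numeric(total_aligned_bases) || !is.numeric(genome_size) ||
      any(is.na(total_aligned_bases)) || any(is.na(genome_size)) ||
      any(total_aligned_bases <= 0) || any(genome_size <= 0)) {
    stop_invalid("total_aligned_bases and genome_size must be positive numbers")
  }
  total_aligned_bases / genome_size
}

#' Mean depth over a region
#'
#' Sums per-base depth over all positions of a region (BED half-open
#' coordinates; positions absent from the depth table count as 0) and
#' divides by region length `end - start`.
#'
#' @param depth A depth tibble with columns `contig`, `pos` (1-based),
#'   `depth`, as from [read_depth_tsv()].
#' @param region A one-row region (list or tibble row) with `contig`,
#'   `start` (0-based), `end` (exclusive).
#' @return Mean depth (depth units).
#' @export
mean_region_depth <- function(depth, region) {
  check_columns(depth, c("contig", "pos", "depth"), "depth table")
  len <- region$end - region$start
  if (is.na(len) || len < 1) stop_invalid("empty region: end must exceed start")
  in_region <- depth$contig == region$contig &
    depth$pos > region$start & depth$pos <= region$end
  sum(depth$depth[in_region]) / len
}

#' Estimate gene copy number for one region
#'
#' Copy number is the region's mean depth divided by the expected
#' single-copy coverage ("scaled depth"). A single-copy locus sequenced at
#' the genome-wide average depth therefore estimates CN 1.
#'
#' @inheritParams mean_region_depth
#' @param total_aligned_bases,genome_size Library size and genome size (bp)
#'   defining the expected coverage.
#' @return Non-negative copy-number estimate (continuous, not rounded).
#' @export
estimate_cn <- function(depth, region, total_aligned_bases, genome_size = 818e6) {
  e <- expected_coverage(total_aligned_bases, genome_size)
  mean_region_depth(depth, region) / e
}

#' Total gene-family copy number from a collapsed reference
#'
#' When the alignment reference is modified to include only one
#' representative of a near-identical paralog family, reads from every
#' family member co-map onto it, so scaled depth over the representative
#' estimates the *total* family copy number. The caller is responsible for
#' having produced `depth` against such a collapsed reference.
#'
#' @inheritParams estimate_cn
#' @param representative The single family-representative region.
#' @return Total family copy number (non-negative real).
#' @export
collapse_family_cn <- function(depth, representative, total_aligned_bases,
                               genome_size = 818e6) {
  estimate_cn(depth, representative, total_aligned_bases, genome_size)
}

#' Sample-by-paralog copy-number table
#'
#' Applies [estimate_cn()] to every sample and region. Rows follow the
#' sample-sheet order, columns the region order; a sample with no depth
#' records on a region's contig gets CN 0.
#'
#' @param depths A long depth tibble with columns `sample_id`, `contig`,
#'   `pos`, `depth` covering all samples (rows may be absent for zero-depth
#'   positions).
#' @param regions A region tibble (`contig`, `start`, `end`, `name`,
#'   `family`), e.g. from [read_regions_bed()].
#' @param samples A sample sheet tibble with `sample_id`, `cultivar`,
#'   `lineage`, `total_aligned_bases`, `genome_size`.
#' @return A `cn_table` tibble: metadata columns `sample_id`, `cultivar`,
#'   `lineage`, then one numeric column per paralog.
#' @export
estimate_cn_table <- function(depths, regions, samples) {
  check_columns(depths, c("sample_id", "contig", "pos", "depth"), "depth table")
  regions <- validate_regions(regions)
  samples <- validate_sample_sheet(samples)
  missing_meta <- setdiff(unique(depths$sample_id), samples$sample_id)
  if (length(missing_meta) > 0) {
    stop_config(sprintf("sample(s) missing from the sample sheet: %s",
                        paste(missing_meta, collapse = ", ")))
  }
  if (any(is.na(samples$total_aligned_bases)) || any(is.na(samples$genome_size))) {
    bad <- samples$sample_id[is.na(samples$total_aligned_bases) | is.na(samples$genome_size)]
    stop_config(sprintf("missing coverage model (aligned bases / genome size) for: %s",
                        paste(bad, collapse = ", ")))
  }

  depth_by_sample <- split(depths[c("contig", "pos", "depth")], depths$sample_id)
  cn <- purrr::map(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    d <- depth_by_sample[[s$sample_id]] %||%
      tibble::tibble(contig = character(), pos = numeric(), depth = numeric())
    purrr::map_dbl(seq_len(nrow(regions)), function(j) {
      estimate_cn(d, regions[j, ], s$total_aligned_bases, s$genome_size)
    })
  })
  mat <- do.call(rbind, cn)
  colnames(mat) <- regions$name
  out <- dplyr::bind_cols(
    samples[c("sample_id", "cultivar", "lineage")],
    tibble::as_tibble(mat)
  )
  class(out) <- c("cn_table", class(out))
  out
}

#' Pivot a copy-number table to long format
#'
#' @param cn_table A `cn_table` from [estimate_cn_table()].
#' @return A tibble with columns `sample_id`, `cultivar`, `lineage`,
#'   `paralog`, `cn`.
#' @export
cn_long <- function(cn_table) {
  tidyr::pivot_longer(tibble::as_tibble(cn_table),
                      cols = -c("sample_id", "cultivar", "lineage"),
                      names_to = "paralog", values_to = "cn")
}

#' @export
print.cn_table <- function(x, ...) {
  paralogs <- setdiff(names(x), c("sample_id", "cultivar", "lineage"))
  cat(sprintf("Copy-number table: %d samples x %d paralogs\n",
              nrow(x), length(paralogs)))
  NextMethod()
}

#' Heatmap of a copy-number table
#'
#' @param object A `cn_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cn_table <- function(object, ...) {
  long <- cn_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$paralog, y = .data$sample_id,
                                     fill = .data$cn)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "CN") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lineage),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
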