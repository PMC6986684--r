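#' Read a per-base depth table
#'
#' Reads the three-column text format emitted by standard depth tools
#' (`samtools depth`-style): contig, 1-based position, depth, tab-separated,
#' no header. Positions absent from the file are treated as depth 0 by every
#' downstream computation.
#'
#' @param path Path to the depth file.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble with columns `sample_id`, `contig`, `pos` (1-based),
#'   `depth`.
#' @export
read_depth_tsv <- function(path, sample_id = NULL) {
  d <- readr::read_tsv(path, col_names = c("contig", "pos", "depth"),
                       col_types = readr::cols(
                         contig = readr::col_character(),
                         pos = readr::col_double(),
                         depth = readr::col_double()
                       ), progress = FALSE)
  if (any(d$depth < 0, na.rm = TRUE)) {
    stop_invalid(sprintf("negative depth values in '%s'", path))
  }
  if (anyDuplicated(d[c("contig", "pos")]) > 0) {
    stop_invalid(sprintf("duplicated (contig, position) rows in '%s'", path))
  }
  if (!is.null(sample_id)) d <- dplyr::mutate(d, sample_id = sample_id, .before = 1)
  d
}

#' Read region annotations from BED
#'
#' BED coordinates are 0-based half-open; this is the single place where the
#' convention is reconciled with 1-based depth positions (a region covers
#' depth positions `start + 1` through `end`). Column 4 is the region name,
#' column 5 an optional family label (e.g. CBDAS-like / THCAS-like /
#' CBCAS-like / unknown).
#'
#' @param path Path to a BED file with at least 4 columns.
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `family`.
#' @export
read_regions_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (ncol(raw) < 4) stop_invalid("BED file must have at least 4 columns (chrom, start, end, name)")
  regions <- tibble::tibble(
    contig = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    name = raw[[4]],
    family = if (ncol(raw) >= 5) raw[[5]] else "unknown"
  )
  validate_regions(regions)
}

validate_regions <- function(regions) {
  check_columns(regions, c("contig", "start", "end", "name"), "region table")
  if (!"family" %in% names(regions)) regions$family <- "unknown"
  if (any(regions$start < 0) || any(regions$start >= regions$end)) {
    stop_invalid("regions must satisfy 0 <= start < end (BED half-open)")
  }
  if (anyDuplicated(regions$name) > 0) {
    stop_invalid("region names must be unique within an annotation set")
  }
  tibble::as_tibble(regions)
}

#' Read the sample sheet
#'
#' Delimited text with header columns `sample_id`, `cultivar`, `lineage`,
#' `total_aligned_bases` and optionally `genome_size` (default: the female
#' genome size, 818 Mb; supply the male value, 843 Mb, per sample where
#' known).
#'
#' @param path Path to the sample sheet (TSV or CSV, sniffed from extension).
#' @param default_genome_size Genome size used where the sheet has none (bp).
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, default_genome_size = 818e6) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  s <- reader(path, col_types = readr::cols(), progress = FALSE)
  check_columns(s, c("sample_id", "cultivar", "lineage", "total_aligned_bases"),
                "sample sheet")
  if (!"genome_size" %in% names(s)) s$genome_size <- default_genome_size
  s$genome_size[is.na(s$genome_size)] <- default_genome_size
  validate_sample_sheet(s)
}

validate_sample_sheet <- function(s) {
  lineages <- c("broad-leaf", "narrow-leaf", "hemp", "unassigned")
  bad <- setdiff(unique(s$lineage), lineages)
  if (length(bad) > 0) {
    stop_invalid(sprintf("unknown lineage label(s): %s (allowed: %s)",
                         paste(bad, collapse = ", "),
                         paste(lineages, collapse = ", ")))
  }
  if (anyDuplicated(s$sample_id) > 0) stop_invalid("duplicate sample_id in sample sheet")
  if (any(s$total_aligned_bases <= 0) || any(s$genome_size <= 0)) {
    stop_invalid("total_aligned_bases and genome_size must be positive")
  }
  tibble::as_tibble(s)
}

#' Read a chemotype table
#'
#' Long format: `cultivar`, `cannabinoid` (e.g. THC, CBD, CBC), `percent`
#' (by dry weight), `provenance` (`individual` or `average`), and optionally
#' `sample_id` for per-individual values.
#'
#' @param path Path to the chemotype TSV.
#' @return A tibble.
#' @export
read_chemotype_tsv <- function(path) {
  ch <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_columns(ch, c("cultivar", "cannabinoid", "percent"), "chemotype table")
  if (!"provenance" %in% names(ch)) ch$provenance <- "average"
  if (any(ch$percent < 0, na.rm = TRUE)) stop_invalid("chemotype percents must be >= 0")
  tibble::as_tibble(ch)
}

#' Read coding sequences from FASTA
#'
#' @param path Path to a (possibly aligned) FASTA file.
#' @return A named character vector of uppercase nucleotide sequences.
#' @export
read_coding_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a copy-number table as TSV (samples in rows, paralogs in columns)
#'
#' @param cn_table A `cn_table` as returned by [estimate_cn_table()].
#' @param path Output path.
#' @export
write_cn_table <- function(cn_table, path) {
  readr::write_tsv(cn_table, path)
  invisible(path)
}
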