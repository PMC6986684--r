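#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length * library_size)`: expression proportional
#' to fragment count after normalizing for transcript length (kb) and
#' sequencing yield (millions of mapped fragments).
#'
#' @param count Fragment count (>= 0).
#' @param length Transcript length in bp (> 0).
#' @param library_size Total mapped fragments in the library (> 0).
#' @return FPKM. Vectorized.
#' @export
fpkm <- function(count, length, library_size) {
  if (any(length <= 0, na.rm = TRUE) || any(library_size <= 0, na.rm = TRUE)) {
    stop_invalid("length and library_size must be positive")
  }
  if (any(count < 0, na.rm = TRUE)) stop_invalid("counts must be >= 0")
  count * 1e9 / (length * library_size)
}

#' Cross-condition expression comparison table
#'
#' Computes FPKM per transcript and condition plus all pairwise log2 fold
#' changes. Zeros are handled with a pseudocount added to both sides of
#' each ratio (fold changes involving a zero FPKM are flagged). An empty
#' `significance` column preserves the layout of downstream
#' differential-expression tables; this report performs no testing.
#'
#' @param counts A tibble with columns `transcript`, `length` (bp), and one
#'   integer count column per condition.
#' @param library_sizes Named numeric vector (or two-column tibble
#'   `condition`, `library_size`) of total mapped fragments per condition.
#' @param pseudocount FPKM pseudocount used in fold changes (default 0.1).
#' @return A tibble: `transcript`, `length`, `fpkm_<condition>` columns,
#'   `log2fc_<a>_vs_<b>` columns, `zero_flag_<a>_vs_<b>` flags, and an
#'   all-`NA` `significance` column. Row order follows a stable sort on
#'   transcript name so the report is invariant to input row order.
#' @export
expression_report <- function(counts, library_sizes, pseudocount = 0.1) {
  check_columns(counts, c("transcript", "length"), "counts table")
  if (anyDuplicated(counts$transcript) > 0) {
    stop_invalid("duplicate transcript names in counts table")
  }
  if (is.data.frame(library_sizes)) {
    library_sizes <- setNames(library_sizes$library_size, library_sizes$condition)
  }
  conditions <- setdiff(names(counts), c("transcript", "length"))
  if (length(conditions) < 2) stop_invalid("need at least 2 conditions")
  missing_ls <- setdiff(conditions, names(library_sizes))
  if (length(missing_ls) > 0) {
    stop_config(sprintf("no library size for condition(s): %s",
                        paste(missing_ls, collapse = ", ")))
  }
  counts <- dplyr::arrange(counts, .data$transcript)
  out <- counts[c("transcript", "length")]
  for (cond in conditions) {
    out[[paste0("fpkm_", cond)]] <-
      fpkm(counts[[cond]], counts$length, library_sizes[[cond]])
  }
  pairs <- combn(conditions, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    fa <- out[[paste0("fpkm_", a)]]
    fb <- out[[paste0("fpkm_", b)]]
    out[[sprintf("log2fc_%s_vs_%s", a, b)]] <-
      log2((fa + pseudocount) / (fb + pseudocount))
    out[[sprintf("zero_flag_%s_vs_%s", a, b)]] <- fa == 0 | fb == 0
  }
  out$significance <- NA_character_
  attr(out, "pseudocount") <- pseudocount
  out
}
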