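# Sequence characterization of the synthase paralog family: pairwise
# distance, counting-based dN/dS (Nei-Gojobori style, pathway-averaged,
# Jukes-Cantor corrected), premature-stop detection, and a neighbour-joining
# tree utility.

GENETIC_CODE_VEC <- as.character(Biostrings::GENETIC_CODE)
names(GENETIC_CODE_VEC) <- names(Biostrings::GENETIC_CODE)
STOP_CODONS <- names(GENETIC_CODE_VEC)[GENETIC_CODE_VEC == "*"]
NUCS <- c("A", "C", "G", "T")

seq_chars <- function(x) {
  if (length(x) != 1L || !is.character(x) || nchar(x) == 0) {
    stop_invalid("sequences must be non-empty single character strings")
  }
  strsplit(toupper(x), "")[[1]]
}

#' Proportion of differing sites (p-distance)
#'
#' Sites where either sequence carries a gap (`-`) or `N` are removed
#' pairwise before counting.
#'
#' @param a,b Nucleotide sequences of equal length (character strings).
#' @return Proportion of mismatching sites among comparable sites, in
#'   `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) stop_invalid("sequences must have equal length")
  ok <- ca %in% NUCS & cb %in% NUCS
  if (!any(ok)) stop_invalid("no comparable sites after removing gaps and Ns")
  mean(ca[ok] != cb[ok])
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differences into an evolutionary
#' distance, `-(3/4) log(1 - 4p/3)`; defined for `p < 0.75`.
#'
#' @param p Observed proportion of differences.
#' @return Corrected distance (substitutions per site).
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) stop_invalid("p must be finite and >= 0")
  if (any(p >= 0.75)) {
    rlang::abort("p >= 0.75: Jukes-Cantor distance is saturated (undefined)",
                 class = c("cnvchemo_saturation_error", "cnvchemo_error"))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix
#'
#' @param seqs Named character vector of aligned sequences.
#' @param model `"p"` (default) for p-distance or `"jc"` for Jukes-Cantor.
#' @return A symmetric matrix with zero diagonal, taxa in input order.
#' @export
distance_matrix <- function(seqs, model = c("p", "jc")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) > 0) {
    stop_invalid("sequences must have unique names")
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      p <- p_distance(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- if (model == "jc") jukes_cantor(p) else p
    }
  }
  d
}

# Fraction of the three possible changes at each codon position that are
# synonymous, excluding changes that create stop codons from both numerator
# and denominator (so each site still contributes exactly one site and the
# codon's synonymous + nonsynonymous site counts sum to 3).
codon_site_counts <- function(codon) {
  aa <- GENETIC_CODE_VEC[[codon]]
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    alt_counts <- c(syn = 0L, nonstop = 0L)
    for (nuc in setdiff(NUCS, chars[pos])) {
      mutant <- chars
      mutant[pos] <- nuc
      mutant <- paste(mutant, collapse = "")
      if (mutant %in% STOP_CODONS) next
      alt_counts[["nonstop"]] <- alt_counts[["nonstop"]] + 1L
      if (GENETIC_CODE_VEC[[mutant]] == aa) alt_counts[["syn"]] <- alt_counts[["syn"]] + 1L
    }
    if (alt_counts[["nonstop"]] > 0) {
      syn <- syn + alt_counts[["syn"]] / alt_counts[["nonstop"]]
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all mutational pathways (orderings of the differing positions). Pathways
# passing through an intermediate stop codon are excluded; if every pathway
# is blocked, all pathways are used as a fallback.
codon_path_counts <- function(codon_a, codon_b) {
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  orderings <- if (length(diffs) == 1) list(diffs) else {
    perms <- permutations_of(diffs)
    perms
  }
  tally <- function(order, allow_stop) {
    cur <- ca
    syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      codon_from <- paste(cur, collapse = "")
      codon_to <- paste(nxt, collapse = "")
      if (!allow_stop && codon_to %in% STOP_CODONS &&
          codon_to != codon_b) {
        return(NULL)
      }
      aa_from <- GENETIC_CODE_VEC[[codon_from]]
      aa_to <- GENETIC_CODE_VEC[[codon_to]]
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  counts <- purrr::compact(purrr::map(orderings, tally, allow_stop = FALSE))
  if (length(counts) == 0) counts <- purrr::map(orderings, tally, allow_stop = TRUE)
  Reduce(`+`, counts) / length(counts)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(x, frame = 0) {
  chars <- seq_chars(x)
  chars <- chars[(frame + 1):length(chars)]
  n_codons <- length(chars) %/% 3
  if (n_codons < 1) stop_invalid("sequence too short for a single codon at this frame")
  substring(paste(chars[1:(3 * n_codons)], collapse = ""),
            3 * (seq_len(n_codons) - 1) + 1, 3 * seq_len(n_codons))
}

#' Counting-based dN/dS for an aligned codon pair
#'
#' Nei-Gojobori-style estimation: per-codon synonymous-site fractions from
#' the standard genetic code, difference counts averaged with equal weight
#' over all mutational pathways for multi-hit codons, proportions converted
#' to distances with the Jukes-Cantor correction. Codons containing a gap,
#' an `N`, or a stop in either sequence are dropped pairwise. Mutational
#' pathways through intermediate stop codons are excluded, and mutations
#' creating stops do not count as synonymous-site opportunities (see
#' `exclude_stop_paths` to disable the pathway rule).
#'
#' @param a,b Aligned coding sequences of equal length, a multiple of 3.
#' @param exclude_stop_paths Exclude pathways through intermediate stops
#'   (default TRUE).
#' @return A one-row tibble with columns `codons` (compared codon count),
#'   `S`, `N` (synonymous / nonsynonymous sites), `Sd`, `Nd` (differences),
#'   `pS`, `pN`, `dS`, `dN`, and `dnds` (`NA` when `dS` = 0: the ratio is
#'   undefined, not zero or infinite).
#' @export
nei_gojobori <- function(a, b, exclude_stop_paths = TRUE) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb) || length(ca) %% 3 != 0) {
    rlang::abort("sequences must be aligned, equal length, a multiple of 3",
                 class = c("cnvchemo_frame_error", "cnvchemo_error"))
  }
  codons_a <- split_codons(a)
  codons_b <- split_codons(b)
  clean <- function(codon) all(strsplit(codon, "")[[1]] %in% NUCS)
  keep <- vapply(codons_a, clean, logical(1)) &
    vapply(codons_b, clean, logical(1)) &
    !(codons_a %in% STOP_CODONS) & !(codons_b %in% STOP_CODONS)
  codons_a <- codons_a[keep]; codons_b <- codons_b[keep]
  if (length(codons_a) == 0) {
    stop_invalid("no comparable codons after dropping gap/N/stop codons")
  }

  sites_a <- vapply(codons_a, codon_site_counts, numeric(2))
  sites_b <- vapply(codons_b, codon_site_counts, numeric(2))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- 3 * length(codons_a) - S

  path_fun <- if (exclude_stop_paths) codon_path_counts else
    function(x, y) codon_path_counts_all(x, y)
  diffs <- purrr::map2(codons_a, codons_b, path_fun)
  Sd <- sum(purrr::map_dbl(diffs, "syn"))
  Nd <- sum(purrr::map_dbl(diffs, "nonsyn"))

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  # Proportions at or beyond 3/4 saturate the correction; report NA rather
  # than fail so short or highly diverged pairs still yield counts.
  safe_jc <- function(p) if (p < 0.75) jukes_cantor(p) else NA_real_
  dS <- safe_jc(pS)
  dN <- safe_jc(pN)
  tibble::tibble(
    codons = length(codons_a), S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN,
    dnds = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  )
}

codon_path_counts_all <- function(codon_a, codon_b) {
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  diffs <- which(ca != cb)
  if (length(diffs) == 0) return(c(syn = 0, nonsyn = 0))
  orderings <- permutations_of(diffs)
  counts <- purrr::map(orderings, function(order) {
    cur <- ca; syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- cb[pos]
      if (GENETIC_CODE_VEC[[paste(cur, collapse = "")]] ==
          GENETIC_CODE_VEC[[paste(nxt, collapse = "")]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  })
  Reduce(`+`, counts) / length(counts)
}

#' All-pairs family characterization table
#'
#' One row per unordered sequence pair with p-distance and the full
#' dN/dS decomposition.
#'
#' @param seqs Named character vector of aligned coding sequences.
#' @return A tibble with columns `seq_a`, `seq_b`, `p_dist`, then the
#'   [nei_gojobori()] columns.
#' @export
pairwise_family_table <- function(seqs) {
  if (length(seqs) < 2) stop_invalid("need at least two sequences")
  pairs <- combn(names(seqs), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dplyr::bind_cols(
      tibble::tibble(seq_a = i, seq_b = j,
                     p_dist = p_distance(seqs[[i]], seqs[[j]])),
      nei_gojobori(seqs[[i]], seqs[[j]])
    )
  })
}

#' Combined distance / dN/dS matrix
#'
#' Square matrix with pairwise distance in the upper triangle and dN/dS in
#' the lower triangle (NA where dS = 0), the layout used for publication
#' supplementary tables.
#'
#' @inheritParams pairwise_family_table
#' @param model Distance model for the upper triangle ("p" or "jc").
#' @return A square matrix with NA diagonal.
#' @export
family_matrix <- function(seqs, model = c("p", "jc")) {
  model <- match.arg(model)
  tab <- pairwise_family_table(seqs)
  nm <- names(seqs)
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(nrow(tab))) {
    i <- match(tab$seq_a[k], nm); j <- match(tab$seq_b[k], nm)
    d <- if (model == "jc") jukes_cantor(tab$p_dist[k]) else tab$p_dist[k]
    m[min(i, j), max(i, j)] <- d
    m[max(i, j), min(i, j)] <- tab$dnds[k]
  }
  m
}

#' Detect premature stop codons in a reading frame
#'
#' Scans codons from the given frame offset and reports every in-frame stop
#' (TAA/TAG/TGA). A sequence is flagged truncated when a stop occurs
#' strictly before the final complete codon; a terminal stop alone is a
#' normal full-length reading frame. Incomplete tail codons are ignored.
#'
#' @param x A nucleotide sequence (character string).
#' @param frame 0-based frame offset (0, 1 or 2).
#' @return A list with `stop_codon_positions` (sorted 1-based codon
#'   indices), `n_codons`, and `is_truncated`.
#' @export
detect_premature_stop <- function(x, frame = 0) {
  if (!frame %in% 0:2) stop_invalid("frame must be 0, 1 or 2")
  codons <- split_codons(x, frame)
  stops <- which(codons %in% STOP_CODONS)
  list(
    stop_codon_positions = as.integer(stops),
    n_codons = length(codons),
    is_truncated = any(stops < length(codons))
  )
}

#' Truncation report for a sequence set
#'
#' @param seqs Named character vector of sequences.
#' @param frame 0-based frame offset applied to every sequence.
#' @return A tibble with one row per sequence: `name`, `n_codons`,
#'   `n_stops`, `first_stop` (1-based codon index, NA if none),
#'   `stop_positions` (comma-separated), `is_truncated`.
#' @export
truncation_report <- function(seqs, frame = 0) {
  purrr::imap_dfr(seqs, function(s, nm) {
    r <- detect_premature_stop(s, frame)
    tibble::tibble(
      name = nm,
      n_codons = r$n_codons,
      n_stops = length(r$stop_codon_positions),
      first_stop = if (length(r$stop_codon_positions)) r$stop_codon_positions[1] else NA_integer_,
      stop_positions = paste(r$stop_codon_positions, collapse = ","),
      is_truncated = r$is_truncated
    )
  })
}

#' Neighbour-joining tree from a distance matrix
#'
#' Plumbing utility producing the unrooted binary NJ topology; negative
#' branch-length estimates are clamped to zero.
#'
#' @param d A symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop_invalid("neighbour joining needs at least 3 taxa")
  if (!isSymmetric(unname(m)) || any(!is.finite(m)) || any(diag(m) != 0)) {
    stop_invalid("distance matrix must be symmetric and finite with zero diagonal")
  }
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
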