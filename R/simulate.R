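# Synthetic-data generators with known truth. Every generator is a pure
# function of its arguments and a seed; one master seed fans out to
# per-generator child seeds so adding a generator never perturbs existing
# fixtures.

#' Simulate a per-base depth profile with planted copy numbers
#'
#' Depth at each position of a region is drawn independently from
#' `Poisson(true_cn * expected_coverage)` (or set exactly to the mean with
#' `noise = "none"`). Positions outside the annotated regions are omitted,
#' matching the depth-emitter convention that absent positions are zero.
#'
#' @param regions A region tibble (`contig`, `start`, `end`, `name`,
#'   `family`) with an additional `true_cn` column of positive reals.
#' @param expected_coverage Genome-wide single-copy coverage (depth units).
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @return A list: `depth` (tibble `contig`, `pos`, `depth`) and `truth`
#'   (the input regions with `true_cn`).
#' @export
simulate_depth <- function(regions, expected_coverage, noise = c("poisson", "none"),
                           seed = 1) {
  noise <- match.arg(noise)
  regions <- validate_regions(regions)
  check_columns(regions, "true_cn", "scenario regions")
  if (any(regions$true_cn <= 0)) stop_invalid("true_cn must be positive")
  check_positive_scalar(expected_coverage, "expected_coverage")
  depth <- withr::with_seed(child_seed(seed, "depth"), {
    purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      pos <- seq(r$start + 1, r$end)
      lambda <- r$true_cn * expected_coverage
      d <- if (noise == "poisson") rpois(length(pos), lambda) else rep(lambda, length(pos))
      tibble::tibble(contig = r$contig, pos = pos, depth = as.numeric(d))
    })
  })
  list(depth = depth, truth = regions)
}

#' Simulate a study-shaped cohort with planted copy numbers
#'
#' Generates a multi-sample cohort mirroring the shape of a diversity
#' panel: by default 67 samples across three lineages (15 broad-leaf,
#' 31 narrow-leaf, 16 hemp) plus 5 unassigned, 11 paralog regions, and
#' integer copy numbers drawn uniformly from `cn_range` per sample and
#' region. Sequencing is emulated at a common expected single-copy
#' coverage.
#'
#' @param seed Integer seed.
#' @param lineage_sizes Named integer vector of samples per lineage.
#' @param n_regions Number of paralog regions.
#' @param region_length Region length in bp.
#' @param expected_coverage Single-copy coverage (depth units).
#' @param cn_range Integer vector of candidate true copy numbers.
#' @param genome_size Genome size (bp) used to back-compute aligned bases.
#' @param noise `"poisson"` or `"none"`.
#' @return A list: `depths` (long tibble with `sample_id`), `samples`
#'   (sample sheet), `regions`, and `truth` (tibble `sample_id`, `paralog`,
#'   `true_cn`).
#' @export
simulate_cohort <- function(seed = 1,
                            lineage_sizes = c(`broad-leaf` = 15, `narrow-leaf` = 31,
                                              hemp = 16, unassigned = 5),
                            n_regions = 11, region_length = 1600,
                            expected_coverage = 20, cn_range = 1:10,
                            genome_size = 818e6,
                            noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  n <- sum(lineage_sizes)
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    cultivar = sprintf("cv%02d", ((seq_len(n) - 1) %/% 2) + 1),
    lineage = rep(names(lineage_sizes), lineage_sizes),
    total_aligned_bases = expected_coverage * genome_size,
    genome_size = genome_size
  )
  regions <- tibble::tibble(
    contig = sprintf("ctg%02d", seq_len(n_regions)),
    start = 1000, end = 1000 + region_length,
    name = sprintf("par%02d", seq_len(n_regions)),
    family = rep(c("CBDAS-like", "THCAS-like", "CBCAS-like", "unknown"),
                 length.out = n_regions)
  )
  withr::with_seed(child_seed(seed, "cohort"), {
    truth <- tidyr::expand_grid(sample_id = samples$sample_id,
                                paralog = regions$name)
    truth$true_cn <- sample(cn_range, nrow(truth), replace = TRUE)
    depths <- purrr::map_dfr(seq_len(n), function(i) {
      sid <- samples$sample_id[i]
      tr <- truth[truth$sample_id == sid, ]
      purrr::map_dfr(seq_len(nrow(regions)), function(j) {
        r <- regions[j, ]
        pos <- seq(r$start + 1, r$end)
        lambda <- tr$true_cn[match(r$name, tr$paralog)] * expected_coverage
        d <- if (noise == "poisson") rpois(length(pos), lambda) else rep(lambda, length(pos))
        tibble::tibble(sample_id = sid, contig = r$contig, pos = pos,
                       depth = as.numeric(d))
      })
    })
    list(depths = depths, samples = samples, regions = regions, truth = truth)
  })
}

#' Simulate a Yule tree with Brownian co-evolving traits
#'
#' Grows a pure-birth tree, evolves a predictor `x` by Brownian motion
#' (variance `bm_sigma^2` per unit branch length), and builds the response
#' as `y = intercept + slope * x + BM residual + iid residual`, where the
#' BM residual is an independent Brownian trait with rate `resid_bm_sigma`
#' and the iid residual is `N(0, residual_sigma^2)` per tip. With
#' `star = TRUE` a star phylogeny with unit terminal branches replaces the
#' Yule tree, making tip traits independent.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Yule birth rate.
#' @param slope,intercept True linear relation between `x` and `y`.
#' @param bm_sigma BM rate of the predictor.
#' @param resid_bm_sigma BM rate of the phylogenetic residual of `y`.
#' @param residual_sigma SD of the independent residual of `y`.
#' @param star Use a star tree instead of a Yule tree.
#' @param seed Integer seed.
#' @return A list: `tree` (`phylo`), `traits` (tibble `tip`, `x`, `y`), and
#'   `truth` (the generating parameters).
#' @export
simulate_tree_and_traits <- function(n_tips, birth_rate = 1, slope = 1.5,
                                     intercept = 0, bm_sigma = 1,
                                     resid_bm_sigma = 1, residual_sigma = 0,
                                     star = FALSE, seed = 1) {
  if (n_tips < 3) stop_invalid("n_tips must be >= 3")
  withr::with_seed(child_seed(seed, "tree"), {
    tree <- if (star) {
      tr <- ape::stree(n_tips, type = "star")
      tr$edge.length <- rep(1, nrow(tr$edge))
      tr
    } else {
      ape::rphylo(n_tips, birth = birth_rate, death = 0)
    }
    V <- ape::vcv.phylo(tree)
    L <- t(chol(V + diag(1e-12, n_tips)))
    x <- unname(drop(L %*% rnorm(n_tips))) * bm_sigma
    eps_phy <- unname(drop(L %*% rnorm(n_tips))) * resid_bm_sigma
    eps_iid <- rnorm(n_tips, sd = residual_sigma)
    y <- intercept + slope * x + eps_phy + eps_iid
    list(
      tree = tree,
      traits = tibble::tibble(tip = tree$tip.label, x = x, y = y),
      truth = list(slope = slope, intercept = intercept, bm_sigma = bm_sigma,
                   resid_bm_sigma = resid_bm_sigma,
                   residual_sigma = residual_sigma)
    )
  })
}

#' Simulate a diverged codon-sequence pair with controlled dN/dS
#'
#' Draws a stop-free ancestor of `n_codons` codons, then applies
#' `n_substitutions` accepted single-nucleotide substitutions. Proposals
#' that would create a stop codon are rejected; nonsynonymous proposals are
#' accepted with probability `min(1, omega)` and synonymous proposals with
#' probability `min(1, 1/omega)` (with `omega = 0` only synonymous changes
#' are ever accepted), so the realized nonsynonymous:synonymous substitution
#' ratio follows the target. Premature stops can then be planted by
#' overwriting stated codons of the derived sequence with TAA.
#'
#' @param n_codons Ancestor length in codons.
#' @param n_substitutions Number of accepted substitutions.
#' @param omega Target nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param planted_stop_codons Integer codon indices to overwrite with TAA
#'   in the derived sequence (1-based; must be <= `n_codons`).
#' @param seed Integer seed.
#' @return A list: `ancestor`, `derived` (character strings), and
#'   `substitutions` (tibble `site`, `codon`, `from`, `to`, `class`).
#' @export
simulate_codon_pair <- function(n_codons, n_substitutions, omega = 1,
                                planted_stop_codons = integer(0), seed = 1) {
  if (n_codons < 1) stop_invalid("n_codons must be >= 1")
  if (omega < 0) stop_invalid("omega must be >= 0")
  if (length(planted_stop_codons) > 0 &&
      (any(planted_stop_codons < 1) || any(planted_stop_codons > n_codons))) {
    stop_invalid("planted stop positions must lie within 1..n_codons")
  }
  sense_codons <- setdiff(names(GENETIC_CODE_VEC), STOP_CODONS)
  withr::with_seed(child_seed(seed, "codon"), {
    anc_codons <- sample(sense_codons, n_codons, replace = TRUE)
    der <- strsplit(paste(anc_codons, collapse = ""), "")[[1]]
    log <- list()
    accepted <- 0L
    p_nonsyn <- min(1, omega)
    p_syn <- if (omega > 1) 1 / omega else 1
    guard <- 0L
    while (accepted < n_substitutions) {
      guard <- guard + 1L
      if (guard > 1e6) stop_invalid("substitution sampler failed to converge")
      site <- sample.int(3L * n_codons, 1)
      codon_idx <- (site - 1L) %/% 3L + 1L
      old_codon <- paste(der[(3 * codon_idx - 2):(3 * codon_idx)], collapse = "")
      nuc <- sample(setdiff(NUCS, der[site]), 1)
      cand <- der
      cand[site] <- nuc
      new_codon <- paste(cand[(3 * codon_idx - 2):(3 * codon_idx)], collapse = "")
      if (new_codon %in% STOP_CODONS) next
      syn <- GENETIC_CODE_VEC[[old_codon]] == GENETIC_CODE_VEC[[new_codon]]
      p_acc <- if (syn) p_syn else p_nonsyn
      if (runif(1) > p_acc) next
      old_nuc <- der[site]
      der <- cand
      accepted <- accepted + 1L
      log[[accepted]] <- tibble::tibble(
        site = site, codon = codon_idx, from = old_nuc, to = nuc,
        class = if (syn) "synonymous" else "nonsynonymous"
      )
    }
    derived <- der
    for (ci in planted_stop_codons) {
      derived[(3 * ci - 2):(3 * ci)] <- c("T", "A", "A")
    }
    list(
      ancestor = paste(anc_codons, collapse = ""),
      derived = paste(derived, collapse = ""),
      substitutions = if (length(log)) dplyr::bind_rows(log) else
        tibble::tibble(site = integer(), codon = integer(), from = character(),
                       to = character(), class = character())
    )
  })
}

#' Two-clade confounding fixture
#'
#' A deterministic dataset in which two deeply split clades differ strongly
#' in both copy number and chemotype, while the slope *within* each clade
#' is exactly zero by construction (the within-clade response is orthogonal
#' to the predictor). The naive Pearson correlation across all tips is
#' therefore strong, but it is entirely explained by shared ancestry, and
#' the phylogenetically corrected fit finds no association — the signature
#' pattern of phylogenetic confounding.
#'
#' @param n_per_clade Tips per clade (>= 4).
#' @param clade_offset Between-clade shift applied to both traits.
#' @param stem_length Branch length of each clade's stem (deep split).
#' @return A list: `tree`, `traits` (tibble `tip`, `x`, `y`).
#' @export
confounded_clades_fixture <- function(n_per_clade = 8, clade_offset = 5,
                                      stem_length = 10) {
  if (n_per_clade < 4) stop_invalid("n_per_clade must be >= 4")
  tipsA <- sprintf("A%02d", seq_len(n_per_clade))
  tipsB <- sprintf("B%02d", seq_len(n_per_clade))
  clade <- function(tips) paste0("(", paste0(tips, ":1", collapse = ","), ")")
  nwk <- sprintf("(%s:%g,%s:%g);", clade(tipsA), stem_length,
                 clade(tipsB), stem_length)
  tree <- ape::read.tree(text = nwk)
  # Within-clade: x on a symmetric grid, y its centred square — exactly
  # orthogonal, so the within-clade regression slope is identically zero.
  xw <- seq(-1, 1, length.out = n_per_clade)
  yw <- xw^2 - mean(xw^2)
  traits <- tibble::tibble(
    tip = c(tipsA, tipsB),
    x = c(xw, xw + clade_offset),
    y = c(yw, yw + clade_offset)
  )
  list(tree = tree, traits = traits)
}

#' Simulate expression counts with planted fold changes
#'
#' Draws Poisson counts per transcript and condition around
#' `baseline_fpkm * fold` expected expression, so reported FPKM fold
#' changes can be checked against planted truth.
#'
#' @param n_transcripts Number of transcripts.
#' @param conditions Character vector of condition names.
#' @param library_size Total mapped fragments per condition (recycled).
#' @param length_bp Transcript length (recycled).
#' @param baseline_fpkm Baseline expression in FPKM.
#' @param fold_matrix Optional matrix (transcripts x conditions) of fold
#'   changes applied to the baseline; defaults to all 1.
#' @param seed Integer seed.
#' @return A list: `counts` (tibble for [expression_report()]),
#'   `library_sizes` (named vector), `truth` (expected FPKM matrix).
#' @export
simulate_expression <- function(n_transcripts = 12,
                                conditions = c("flower", "root"),
                                library_size = 2e7, length_bp = 1500,
                                baseline_fpkm = 50, fold_matrix = NULL,
                                seed = 1) {
  lens <- rep_len(length_bp, n_transcripts)
  libs <- setNames(rep_len(library_size, length(conditions)), conditions)
  if (is.null(fold_matrix)) {
    fold_matrix <- matrix(1, n_transcripts, length(conditions))
  }
  expected_fpkm <- baseline_fpkm * fold_matrix
  withr::with_seed(child_seed(seed, "expression"), {
    counts <- tibble::tibble(
      transcript = sprintf("tx%03d", seq_len(n_transcripts)),
      length = lens
    )
    for (j in seq_along(conditions)) {
      lambda <- expected_fpkm[, j] * lens * libs[[j]] / 1e9
      counts[[conditions[j]]] <- rpois(n_transcripts, lambda)
    }
    dimnames(expected_fpkm) <- list(counts$transcript, conditions)
    list(counts = counts, library_sizes = libs, truth = expected_fpkm)
  })
}
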