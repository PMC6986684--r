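test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  # gap/N sites removed pairwise
  expect_equal(p_distance("AA-A", "AAAA"), 0)
  expect_equal(p_distance("ANCT", "AGCA"), 1 / 3)
  expect_error(p_distance("NNN", "AAA"), class = "cnvchemo_invalid_input")
  expect_error(p_distance("AAA", "AAAA"), class = "cnvchemo_invalid_input")
  # random pair against a site-by-site oracle
  set.seed(3)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  expect_equal(p_distance(a, b), sum(ca != cb) / 300)
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_error(jukes_cantor(0.75), class = "cnvchemo_saturation_error")
  # approaches p for small p, strictly increasing
  expect_equal(jukes_cantor(1e-6), 1e-6, tolerance = 1e-3)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jukes_cantor(p)) > 0))
})

test_that("per-codon synonymous site fractions match mutant enumeration", {
  counts <- cnvchemo:::codon_site_counts("TTT")
  expect_equal(unname(counts["syn"]), 1 / 3)
  expect_equal(unname(counts["nonsyn"]), 8 / 3)
  for (codon in c("ATG", "TGG", "CTA", "GGG", "AGA", "TAT")) {
    expect_equal(unname(cnvchemo:::codon_site_counts(codon)["syn"]),
                 oracle_syn_sites(codon), tolerance = 1e-12, label = codon)
  }
  # every sense codon's site counts sum to 3
  for (codon in all_sense_codons()) {
    expect_equal(sum(cnvchemo:::codon_site_counts(codon)), 3,
                 tolerance = 1e-12, label = codon)
  }
})

test_that("two-hit codon pathways are averaged with equal weight", {
  counts <- cnvchemo:::codon_path_counts("TTT", "GTA")
  expect_equal(unname(counts["syn"]), 0.5)
  expect_equal(unname(counts["nonsyn"]), 1.5)
})

test_that("nei_gojobori is symmetric and zero for identical sequences", {
  same <- nei_gojobori("ATGAAATTTGGG", "ATGAAATTTGGG")
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$dnds))

  sim <- simulate_codon_pair(120, 15, omega = 0.7, seed = 8)
  ab <- nei_gojobori(sim$ancestor, sim$derived)
  ba <- nei_gojobori(sim$derived, sim$ancestor)
  expect_equal(ab, ba)
  expect_error(nei_gojobori("ATGAA", "ATGAA"), class = "cnvchemo_frame_error")
  expect_error(nei_gojobori("---", "---"), class = "cnvchemo_invalid_input")
})

test_that("difference counts match exhaustive pathway enumeration", {
  codons <- all_sense_codons()
  set.seed(21)
  pick <- sample(codons, 18)
  for (a in pick) for (b in pick) {
    nd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (nd > 2) next
    got <- cnvchemo:::codon_path_counts(a, b)
    want <- oracle_path_counts(a, b)
    expect_equal(unname(got["syn"]), unname(want["syn"]), tolerance = 1e-12,
                 label = paste(a, b))
    expect_equal(unname(got["nonsyn"]), unname(want["nonsyn"]), tolerance = 1e-12,
                 label = paste(a, b))
  }
})

test_that("pure synonymous divergence gives dN = 0; pure nonsynonymous gives dS = 0", {
  syn_only <- simulate_codon_pair(200, 12, omega = 0, seed = 4)
  r <- nei_gojobori(syn_only$ancestor, syn_only$derived)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  # hand-built nonsynonymous-only divergence: AAA(K)->ACA(T), GGG(G)->GCG(A)
  r2 <- nei_gojobori("AAAGGGTTT", "ACAGCGTTT")
  expect_equal(r2$Sd, 0)
  expect_equal(r2$dS, 0)
  expect_gt(r2$dN, 0)
})

test_that("premature stops are located exactly and terminal stops are not truncation", {
  r <- detect_premature_stop("ATGTAAGGG")
  expect_identical(r$stop_codon_positions, 2L)
  expect_true(r$is_truncated)
  expect_false(detect_premature_stop("ATGGGGTAA")$is_truncated)
  # frame offset shifts the codon grid
  shifted <- detect_premature_stop(paste0("G", "ATGTAAGGG"), frame = 1)
  expect_identical(shifted$stop_codon_positions, 2L)
  # planted stop in a long randomized ORF is recovered at the exact codon
  sim <- simulate_codon_pair(300, 10, omega = 0.5,
                             planted_stop_codons = 50, seed = 77)
  rep <- truncation_report(c(anc = sim$ancestor, der = sim$derived))
  expect_false(rep$is_truncated[rep$name == "anc"])
  expect_true(rep$is_truncated[rep$name == "der"])
  expect_identical(rep$first_stop[rep$name == "der"], 50L)
})

test_that("all planted-stop CBDAS-like fixtures are flagged truncated", {
  fixtures <- purrr::map(1:3, function(i) {
    simulate_codon_pair(180, 8, omega = 0.5,
                        planted_stop_codons = 30 + 10 * i, seed = 200 + i)$derived
  })
  names(fixtures) <- sprintf("CBDAS_like_%d", 1:3)
  rep <- truncation_report(unlist(fixtures))
  expect_true(all(rep$is_truncated))
})

test_that("NJ reproduces the 3-taxon closed form and 4-taxon additivity", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  # three-point formulas: a = (dAB + dAC - dBC)/2, etc.
  tip_edges <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(tip_edges["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(tip_edges["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(tip_edges["C"]), (4 + 5 - 3) / 2)

  # additive 4-taxon matrix: ((A:1,B:2):1,(C:3,D:1):1) path lengths
  nwk <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:1):0.5);")
  d4 <- cophenetic(nwk)
  tr4 <- nj_tree(d4)
  expect_equal(cophenetic(tr4)[rownames(d4), colnames(d4)], d4, tolerance = 1e-10)

  expect_error(nj_tree(matrix(0, 2, 2)), class = "cnvchemo_invalid_input")
  asym <- d3; asym[1, 2] <- 9
  expect_error(nj_tree(asym), class = "cnvchemo_invalid_input")
})

test_that("family tables carry distance and dN/dS for every pair", {
  sims <- purrr::map(1:3, function(i) {
    simulate_codon_pair(150, 10, omega = 0.5, seed = 300 + i)
  })
  seqs <- c(ref = sims[[1]]$ancestor,
            par1 = sims[[1]]$derived, par2 = sims[[2]]$derived)
  tab <- pairwise_family_table(seqs)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_dist >= 0 & tab$p_dist <= 1))
  m <- family_matrix(seqs)
  # upper triangle distance, lower triangle dN/dS
  expect_equal(m["ref", "par1"], tab$p_dist[tab$seq_a == "ref" & tab$seq_b == "par1"])
  expect_equal(m["par1", "ref"], tab$dnds[tab$seq_a == "ref" & tab$seq_b == "par1"])
  d <- distance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
})
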