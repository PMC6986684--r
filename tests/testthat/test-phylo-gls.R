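test_that("BM covariance equals shared root-to-tip path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- bm_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(V), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))
  # ultrametric tree: constant diagonal
  expect_equal(unname(diag(V)), rep(2, 3))

  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1.5, 5)
  expect_equal(unname(bm_covariance(star)), 1.5 * diag(5))

  expect_equal(unname(bm_covariance(tr, "C")), matrix(2, 1, 1))
  expect_error(bm_covariance(tr, c("A", "Z")), class = "cnvchemo_invalid_input")
})

test_that("PGLS with identity covariance reproduces OLS to 1e-10", {
  set.seed(19)
  for (sigma2 in c(1, 0.25, 9)) {
    x <- rnorm(25); y <- 0.7 + 1.3 * x + rnorm(25)
    f <- pgls_fit(y, x, sigma2 * diag(25))
    ols <- summary(lm(y ~ x))
    expect_equal(unname(f$coefficients), unname(ols$coefficients[, 1]),
                 tolerance = 1e-10)
    expect_equal(unname(f$se), unname(ols$coefficients[, 2]), tolerance = 1e-10)
    expect_equal(unname(f$p_values), unname(ols$coefficients[, 4]),
                 tolerance = 1e-10)
    expect_equal(f$r_squared, ols$r.squared, tolerance = 1e-10)
  }
})

test_that("an exact linear relation is recovered exactly under any valid V", {
  tr <- ape::rphylo(12, 1, 0)
  V <- bm_covariance(tr)
  x <- seq_len(12)
  f <- pgls_fit(2 * x + 1, x, V)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-8)
  expect_lt(f$sigma2, 1e-16)
  expect_equal(f$correlation_coefficient, 1)
})

test_that("slope is equivariant under predictor scaling", {
  s <- simulate_tree_and_traits(20, slope = 1.5, seed = 6)
  V <- bm_covariance(s$tree, s$traits$tip)
  f1 <- pgls_fit(s$traits$y, s$traits$x, V)
  f2 <- pgls_fit(s$traits$y, 4 * s$traits$x, V)
  expect_equal(f2$coefficients[["x"]], f1$coefficients[["x"]] / 4,
               tolerance = 1e-12)
  expect_equal(f2$p_values[["x"]], f1$p_values[["x"]], tolerance = 1e-12)
})

test_that("PGLS matches nlme::gls with Brownian correlation", {
  skip_if_not_installed("nlme")
  s <- simulate_tree_and_traits(30, slope = 1.5, residual_sigma = 0, seed = 42)
  V <- bm_covariance(s$tree, s$traits$tip)
  f <- pgls_fit(s$traits$y, s$traits$x, V)
  dat <- as.data.frame(s$traits)
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(phy = s$tree, form = ~tip))
  tab <- summary(g)$tTable
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(tab[, "Std.Error"]), tolerance = 1e-10)
  expect_equal(unname(f$p_values), unname(tab[, "p-value"]), tolerance = 1e-10)
})

test_that("slope recovery and CI coverage are calibrated on BM simulations", {
  n_rep <- 150
  slopes <- numeric(n_rep); cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_tree_and_traits(50, slope = 1.5, residual_sigma = 0,
                                  seed = 3000 + i)
    V <- bm_covariance(s$tree, s$traits$tip)
    f <- pgls_fit(s$traits$y, s$traits$x, V)
    slopes[i] <- f$coefficients[["x"]]
    half <- qt(0.975, f$df) * f$se[["x"]]
    cover[i] <- abs(f$coefficients[["x"]] - 1.5) <= half
  }
  expect_lt(abs(mean(slopes) - 1.5), 0.06)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("tidy, glance and autoplot expose the fit", {
  s <- simulate_tree_and_traits(15, seed = 2)
  f <- pgls_fit(s$traits$y, s$traits$x, bm_covariance(s$tree, s$traits$tip))
  td <- tidy(f)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_identical(names(td),
                   c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(f)
  expect_equal(gl$nobs, 15)
  expect_equal(sign(gl$correlation), sign(td$estimate[2]))
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("total cannabinoid applies the decarboxylation factor", {
  expect_equal(total_cannabinoid(0, 0), 0)
  expect_equal(total_cannabinoid(1.0, 10.0), 9.77)
  expect_equal(total_cannabinoid(2, 3, factor = 1), 5)
  expect_error(total_cannabinoid(-1, 0), class = "cnvchemo_invalid_input")
})

test_that("corrected and uncorrected p agree on a star phylogeny", {
  set.seed(61)
  n <- 24
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("S%03d", seq_len(n))
  cn <- tibble::tibble(
    sample_id = star$tip.label,
    cultivar = sprintf("cv%02d", seq_len(n)),
    lineage = "hemp",
    parA = runif(n, 1, 8)
  )
  class(cn) <- c("cn_table", class(cn))
  chem <- tibble::tibble(cultivar = cn$cultivar, sample_id = cn$sample_id,
                         cannabinoid = "THC",
                         percent = 0.5 * cn$parA + rnorm(n, sd = 0.3),
                         provenance = "individual")
  assoc <- correlate_cn_chemotype(cn, chem, star, "THC")
  expect_equal(assoc$p_pgls, assoc$p_pearson, tolerance = 1e-8)
  expect_equal(assoc$r_pgls, assoc$r_pearson, tolerance = 1e-8)
  expect_equal(assoc$n_individual, nrow(cn))
})

test_that("phylogenetic confounding separates corrected from naive p-values", {
  fx <- confounded_clades_fixture()
  cn <- tibble::tibble(sample_id = fx$traits$tip,
                       cultivar = fx$traits$tip, lineage = "hemp",
                       parA = fx$traits$x - min(fx$traits$x))
  class(cn) <- c("cn_table", class(cn))
  chem <- tibble::tibble(cultivar = cn$cultivar, sample_id = cn$sample_id,
                         cannabinoid = "CBD",
                         percent = fx$traits$y - min(fx$traits$y),
                         provenance = "individual")
  assoc <- correlate_cn_chemotype(cn, chem, fx$tree, "CBD")
  expect_lt(assoc$p_pearson, 0.01)
  expect_gt(assoc$p_pgls, 0.1)
})

test_that("cultivar averages back individual gaps, and 'total' sums cannabinoids", {
  s <- simulate_tree_and_traits(10, seed = 44)
  tips <- s$tree$tip.label
  cn <- tibble::tibble(sample_id = tips,
                       cultivar = rep(c("cvA", "cvB"), each = 5),
                       lineage = "hemp", parA = seq(1, 10))
  class(cn) <- c("cn_table", class(cn))
  chem <- tibble::tibble(
    cultivar = rep(c("cvA", "cvB"), each = 2),
    sample_id = NA_character_,
    cannabinoid = rep(c("THC", "CBD"), 2),
    percent = c(10, 1, 2, 8),
    provenance = "average"
  )
  assoc <- correlate_cn_chemotype(cn, chem, s$tree, "THC")
  expect_equal(assoc$n, 10)
  expect_equal(assoc$n_individual, 0)
  tot <- correlate_cn_chemotype(cn, chem, s$tree, "total")
  expect_equal(tot$cannabinoid, "total")
  # insufficient matching is an explicit classed error
  orphan <- dplyr::filter(chem, cultivar == "none")
  expect_error(correlate_cn_chemotype(cn, orphan, s$tree, "THC"),
               class = "cnvchemo_insufficient_data")
})

test_that("CN-vs-CN paralog correlations return one row per pair", {
  coh <- simulate_cohort(seed = 5, lineage_sizes = c(hemp = 8, `broad-leaf` = 8),
                         n_regions = 3, region_length = 300)
  cn <- estimate_cn_table(coh$depths, coh$regions, coh$samples)
  tt <- simulate_tree_and_traits(16, seed = 5)
  tt$tree$tip.label <- cn$sample_id
  pairs <- correlate_cn_pairs(cn, tt$tree)
  expect_equal(nrow(pairs), choose(3, 2))
  expect_true(all(pairs$n == 16))
})
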