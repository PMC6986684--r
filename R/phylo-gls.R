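# Phylogenetic generalized least squares under Brownian motion: the error
# covariance between two tips is the shared root-to-tip path length, so the
# GLS estimator downweights resemblance that is explained by relatedness
# alone.

#' Brownian-motion covariance matrix from a tree
#'
#' `V[i, j]` is the depth of the most recent common ancestor of tips `i`
#' and `j` (shared root-to-tip path length); the diagonal holds root-to-tip
#' distances. For an ultrametric tree the diagonal is constant.
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param tips Optional ordered subset of tip labels; defaults to all tips
#'   in tree order.
#' @return A symmetric positive-semidefinite matrix with `tips` as
#'   dimnames.
#' @export
bm_covariance <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo")) stop_invalid("tree must be an ape 'phylo' object")
  V <- ape::vcv.phylo(tree)
  if (is.null(tips)) tips <- tree$tip.label
  unknown <- setdiff(tips, rownames(V))
  if (length(unknown) > 0) {
    stop_invalid(sprintf("tip(s) not on the tree: %s", paste(unknown, collapse = ", ")))
  }
  V[tips, tips, drop = FALSE]
}

#' Fit a bivariate phylogenetic GLS regression
#'
#' Fits `y = a + b x` by generalized least squares with error covariance
#' proportional to `V`: `beta = (X' V^-1 X)^-1 X' V^-1 y`. Standard errors
#' come from `sigma2 * (X' V^-1 X)^-1` with
#' `sigma2 = r' V^-1 r / (n - 2)`, t statistics use `n - 2` degrees of
#' freedom, and the correlation coefficient is the sign-preserving square
#' root of the GLS R-squared (residual sum of squares in the `V^-1` metric
#' against the GLS-mean-centred total). With `V` the identity the fit
#' reduces exactly to ordinary least squares.
#'
#' If `V` is numerically non-positive-definite a small ridge
#' (`1e-10 * mean diagonal`) is added with a warning.
#'
#' @param y Response vector.
#' @param x Predictor vector.
#' @param V Covariance matrix (e.g. from [bm_covariance()]), dimensions
#'   matching `length(y)`.
#' @return An object of class `pgls_fit`.
#' @export
pgls_fit <- function(y, x, V) {
  n <- length(y)
  if (length(x) != n || !all(dim(V) == n)) {
    stop_invalid("dimensions of y, x and V must agree")
  }
  if (n < 3) stop_invalid("need at least 3 observations")
  V <- as.matrix(V)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    rlang::warn("V is not positive definite; adding a 1e-10 ridge")
    V <- V + diag(1e-10 * mean(diag(V)), n)
    ch <- tryCatch(chol(V), error = function(e) {
      rlang::abort("V remains singular after ridge",
                   class = c("cnvchemo_conditioning_error", "cnvchemo_error"))
    })
  }
  # Whiten with the Cholesky factor: solving L' z = v maps GLS to OLS.
  X <- cbind(`(Intercept)` = 1, x = x)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  dimnames(beta) <- list(colnames(X), NULL)
  resid_w <- yw - Xw %*% beta
  df <- n - 2L
  sigma2 <- sum(resid_w^2) / df
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  tstat <- drop(beta) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)

  # GLS R^2 against the GLS intercept-only mean.
  onew <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - mu * onew)^2)
  r2 <- if (tss > 0) 1 - sum(resid_w^2) / tss else 1
  r2 <- min(max(r2, 0), 1)
  r <- unname(sign(beta["x", 1])) * sqrt(r2)

  out <- list(
    coefficients = drop(beta), se = setNames(se, rownames(beta)),
    t = setNames(tstat, rownames(beta)), p_values = setNames(p, rownames(beta)),
    sigma2 = sigma2, r_squared = r2, correlation_coefficient = r,
    df = df, n = n, y = y, x = x
  )
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic GLS fit (n = %d)\n  slope = %.4g (SE %.4g, t = %.3g, p = %.4g)\n  intercept = %.4g\n  r = %.4g\n",
    x$n, x$coefficients["x"], x$se["x"], x$t["x"], x$p_values["x"],
    x$coefficients["(Intercept)"], x$correlation_coefficient))
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t),
    p.value = unname(x$p_values)
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    correlation = x$correlation_coefficient,
    sigma2 = x$sigma2, df.residual = x$df, nobs = x$n
  )
}

#' @export
autoplot.pgls_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$x, y = object$y)
  b <- object$coefficients
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = b["(Intercept)"], slope = b["x"],
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("r = %.3f, p = %.3g (phylogenetically corrected)",
                         object$correlation_coefficient, object$p_values["x"])) +
    ggplot2::theme_minimal()
}

#' Total cannabinoid content from acidic and neutral forms
#'
#' Heating converts the acidic cannabinoids (THCA, CBDA, CBCA) to their
#' neutral forms with loss of CO2; total potential content is
#' `neutral + factor * acid`, with the default factor 0.877 the molar-mass
#' ratio of the neutral to the acidic form.
#'
#' @param neutral_pct,acid_pct Percent by dry weight (>= 0).
#' @param factor Decarboxylation mass-conversion factor.
#' @return Total percent by dry weight. Vectorized.
#' @export
total_cannabinoid <- function(neutral_pct, acid_pct, factor = 0.877) {
  if (any(neutral_pct < 0, na.rm = TRUE) || any(acid_pct < 0, na.rm = TRUE) ||
      factor < 0) {
    stop_invalid("cannabinoid percents and factor must be >= 0")
  }
  neutral_pct + factor * acid_pct
}

# Per-sample chemotype values: individual measurements where available,
# cultivar averages otherwise. Provenance is retained.
match_chemotype <- function(samples, chemotypes, cannabinoid) {
  if (identical(cannabinoid, "total")) {
    ch <- chemotypes |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("cultivar", "sample_id", "provenance")))) |>
      dplyr::summarise(percent = sum(.data$percent), .groups = "drop") |>
      dplyr::mutate(cannabinoid = "total")
  } else {
    ch <- dplyr::filter(chemotypes, .data$cannabinoid == !!cannabinoid)
  }
  has_sample <- "sample_id" %in% names(ch)
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    indiv <- if (has_sample) dplyr::filter(ch, !is.na(.data$sample_id),
                                           .data$sample_id == s$sample_id) else ch[0, ]
    if (nrow(indiv) > 0) {
      return(tibble::tibble(sample_id = s$sample_id, percent = mean(indiv$percent),
                            provenance = "individual"))
    }
    cv <- dplyr::filter(ch, .data$cultivar == s$cultivar)
    if (nrow(cv) == 0) {
      return(tibble::tibble(sample_id = s$sample_id, percent = NA_real_,
                            provenance = NA_character_))
    }
    tibble::tibble(sample_id = s$sample_id, percent = mean(cv$percent),
                   provenance = "average")
  })
}

#' Phylogenetically corrected copy-number / chemotype association
#'
#' For every paralog, regresses the chemotype (percent dry weight of the
#' requested cannabinoid, or the sum over all cannabinoids when
#' `cannabinoid = "total"`) on estimated copy number by PGLS under Brownian
#' motion, and reports the uncorrected Pearson correlation alongside for
#' comparison. Chemotype values are per-sample where individual
#' measurements exist and cultivar averages otherwise.
#'
#' @param cn_table A `cn_table` from [estimate_cn_table()].
#' @param chemotypes A chemotype tibble (see [read_chemotype_tsv()]).
#' @param tree A rooted `phylo` whose tips are sample ids.
#' @param cannabinoid Cannabinoid label (e.g. `"THC"`, `"CBD"`, `"CBC"`) or
#'   `"total"`.
#' @return A tibble with one row per paralog: `paralog`, `cannabinoid`,
#'   `n`, `slope`, `r_pgls`, `p_pgls`, `r_pearson`, `p_pearson`,
#'   `n_individual` (samples using individual chemotype values).
#' @export
correlate_cn_chemotype <- function(cn_table, chemotypes, tree, cannabinoid) {
  samples <- tibble::as_tibble(cn_table)[c("sample_id", "cultivar", "lineage")]
  chem <- match_chemotype(samples, chemotypes, cannabinoid)
  matched <- samples$sample_id[!is.na(chem$percent) &
                                 samples$sample_id %in% tree$tip.label]
  if (length(matched) < 3) {
    unmatched <- setdiff(samples$sample_id, matched)
    rlang::abort(
      sprintf("fewer than 3 samples with CN, chemotype and tree placement; unmatched: %s",
              paste(unmatched, collapse = ", ")),
      class = c("cnvchemo_insufficient_data", "cnvchemo_error"))
  }
  V <- bm_covariance(tree, matched)
  idx <- match(matched, samples$sample_id)
  y <- chem$percent[idx]
  n_indiv <- sum(chem$provenance[idx] == "individual", na.rm = TRUE)
  paralogs <- setdiff(names(cn_table), c("sample_id", "cultivar", "lineage"))
  purrr::map_dfr(paralogs, function(p) {
    x <- cn_table[[p]][idx]
    fit <- pgls_fit(y, x, V)
    pear <- suppressWarnings(cor.test(x, y))
    tibble::tibble(
      paralog = p, cannabinoid = cannabinoid, n = length(matched),
      slope = fit$coefficients[["x"]],
      r_pgls = fit$correlation_coefficient, p_pgls = fit$p_values[["x"]],
      r_pearson = unname(pear$estimate), p_pearson = pear$p.value,
      n_individual = n_indiv
    )
  })
}

#' Phylogenetically corrected CN-vs-CN correlations between paralogs
#'
#' @param cn_table A `cn_table`.
#' @param tree A rooted `phylo` whose tips are sample ids.
#' @return A tibble with one row per unordered paralog pair.
#' @export
correlate_cn_pairs <- function(cn_table, tree) {
  samples <- tibble::as_tibble(cn_table)
  matched <- intersect(samples$sample_id, tree$tip.label)
  if (length(matched) < 3) stop_invalid("fewer than 3 samples on the tree")
  V <- bm_covariance(tree, matched)
  idx <- match(matched, samples$sample_id)
  paralogs <- setdiff(names(cn_table), c("sample_id", "cultivar", "lineage"))
  pairs <- combn(paralogs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    fit <- pgls_fit(samples[[b]][idx], samples[[a]][idx], V)
    tibble::tibble(paralog_x = a, paralog_y = b, n = length(matched),
                   slope = fit$coefficients[["x"]],
                   r_pgls = fit$correlation_coefficient,
                   p_pgls = fit$p_values[["x"]])
  })
}
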