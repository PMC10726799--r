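#' Spearman rank correlation with p-value
#'
#' Average-rank Spearman correlation. For small samples (n < 10) without ties
#' the p-value is exact (enumeration of the rank permutation distribution);
#' otherwise it comes from the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), both non-constant.
#' @return One-row tibble with `rho`, `p`, `n`.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))  # rho = 0.8
#' @export
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("spearman_test needs at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input has no rank correlation")
  rho <- cor(x, y, method = "spearman")
  p <- spearman_p(rho, x, y, n)
  tibble(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, x, y, n, df = n - 2) {
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n < 10 && no_ties && df == n - 2) {
    return(suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    ))
  }
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * pt(-abs(tstat), df = df)
}

#' Age-adjusted (partial) Spearman correlation
#'
#' Partial rank correlation of `x` and `y` given covariates, computed from
#' the precision matrix of the Spearman correlation matrix of
#' `(x, y, covariates)`; the p-value uses the t statistic with n - 2 - k
#' degrees of freedom for k covariates. With no covariates this is exactly
#' [spearman_test()]. Used to ask whether a microbe-metabolite association
#' survives correction for age.
#'
#' @param x,y Numeric vectors.
#' @param covariates A numeric vector, matrix or data frame of covariates
#'   (may be `NULL` or empty for the unadjusted correlation).
#' @return One-row tibble with `rho`, `p`, `n`, `n_covariates`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  z <- covariate_matrix(covariates, length(x))
  if (is.null(z) || ncol(z) == 0) return(spearman_test(x, y))
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(z)
  if (n <= k + 3) abort("need n > k + 3 samples for k covariates")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input has no rank correlation")
  S <- cor(cbind(x, y, z), method = "spearman")
  P <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(P)) {
    # Exact collinearity (e.g. y identical to a covariate): the conditional
    # variance of one margin is zero, so there is no partial association left.
    return(tibble(rho = 0, p = 1, n = n, n_covariates = k))
  }
  rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  rho <- max(-1, min(1, rho))
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * pt(-abs(tstat), df = df)
  }
  tibble(rho = rho, p = p, n = n, n_covariates = k)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (is.numeric(covariates) && !is.matrix(covariates)) {
    covariates <- matrix(covariates, ncol = 1)
  }
  if (length(covariates) == 0) return(NULL)
  if (!is.numeric(covariates)) abort("covariates must be numeric")
  if (nrow(covariates) != n) abort("covariates must match the sample count")
  covariates
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' returned in the input order (a validated front end to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Nonparametric group comparisons
#'
#' Rank-based tests for differences between sample groups, as used for
#' Shannon index, host phenotypes and metabolite levels across age groups.
#'
#' * `"wilcoxon-pairwise"`: two-sided Wilcoxon rank-sum test for every pair
#'   of groups;
#' * `"kruskal-wallis"`: one overall Kruskal-Wallis test;
#' * `"fisher-exact"`: Fisher's exact test; `values` must then be a
#'   contingency table (matrix) and `groups` is ignored.
#'
#' @param values Numeric vector (or a contingency matrix for
#'   `"fisher-exact"`).
#' @param groups Group labels aligned with `values`.
#' @param mode One of `"wilcoxon-pairwise"`, `"kruskal-wallis"`,
#'   `"fisher-exact"`.
#' @return Tibble with one row per test: `group_a`, `group_b` (NA for the
#'   omnibus tests), `statistic`, `p`, `n_a`, `n_b`.
#' @export
group_tests <- function(values, groups = NULL,
                        mode = c("wilcoxon-pairwise", "kruskal-wallis",
                                 "fisher-exact")) {
  mode <- match.arg(mode)
  if (mode == "fisher-exact") {
    if (!is.matrix(values)) abort("fisher-exact needs a contingency matrix")
    ft <- fisher.test(values)
    return(tibble(group_a = NA_character_, group_b = NA_character_,
                  statistic = unname(if (!is.null(ft$estimate)) ft$estimate else NA_real_),
                  p = ft$p.value, n_a = sum(values), n_b = NA_integer_))
  }
  groups <- as.character(groups)
  if (length(groups) != length(values)) {
    abort("values and groups must have equal length")
  }
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least two groups")
  if (any(sizes == 0)) abort("every group needs at least one observation")
  if (mode == "kruskal-wallis") {
    kt <- kruskal.test(values, factor(groups))
    return(tibble(group_a = NA_character_, group_b = NA_character_,
                  statistic = unname(kt$statistic), p = kt$p.value,
                  n_a = length(values), n_b = NA_integer_))
  }
  pairs <- combn(sort(names(sizes)), 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    va <- values[groups == pr[1]]
    vb <- values[groups == pr[2]]
    wt <- suppressWarnings(wilcox.test(va, vb))
    tibble(group_a = pr[1], group_b = pr[2],
           statistic = unname(wt$statistic), p = wt$p.value,
           n_a = length(va), n_b = length(vb))
  }) |> list_rbind()
}

#' Long-format association table between two feature tables
#'
#' Correlates every feature of `a` with every feature of `b` across shared
#' samples (Spearman, optionally adjusted for covariates such as age via
#' [partial_spearman()]) and appends BH q-values over all pairs.
#'
#' @param a,b Abundance tibbles sharing sample columns.
#' @param adjust Optional named list or data frame of per-sample covariates
#'   (rows aligned with the shared sample order) for partial correlation.
#' @return Tibble with `feature_a`, `feature_b`, `rho`, `p`, `q`, `n`.
#' @export
correlate_features <- function(a, b, adjust = NULL) {
  ma <- abundance_matrix(a)
  mb <- abundance_matrix(b)
  shared <- intersect(colnames(ma), colnames(mb))
  if (length(shared) < 4) abort("need at least 4 shared samples")
  ma <- ma[, shared, drop = FALSE]
  mb <- mb[, shared, drop = FALSE]
  z <- covariate_matrix(adjust, length(shared))
  grid <- tidyr::expand_grid(feature_a = rownames(ma), feature_b = rownames(mb))
  res <- purrr::map2(grid$feature_a, grid$feature_b, function(fa, fb) {
    r <- if (is.null(z)) spearman_test(ma[fa, ], mb[fb, ])
         else partial_spearman(ma[fa, ], mb[fb, ], z)
    tibble(feature_a = fa, feature_b = fb, rho = r$rho, p = r$p, n = r$n)
  }) |> list_rbind()
  res$q <- bh_fdr(res$p)
  res[, c("feature_a", "feature_b", "rho", "p", "q", "n")]
}
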