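#' Shannon diversity index
#'
#' Shannon entropy `H' = -sum(a_i * ln a_i)` in nats, with the profile
#' renormalized internally and zero abundances contributing nothing. High
#' values indicate even, diverse communities; the maximum is `ln(S)` for `S`
#' features.
#'
#' @param profile Nonnegative abundance vector with at least one positive
#'   entry.
#' @return Entropy in nats.
#' @examples
#' shannon(rep(1, 10))          # ln 10
#' shannon(c(0.5, 0.25, 0.25))  # 1.039721
#' @export
shannon <- function(profile) {
  if (any(profile < 0, na.rm = TRUE)) abort("abundances must be nonnegative")
  tot <- sum(profile, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) abort("all-zero profile has no diversity")
  p <- profile[profile > 0] / tot
  -sum(p * log(p))
}

#' Per-sample Shannon index of an abundance table
#'
#' @param tbl Abundance tibble.
#' @return Tibble with `sample_id` and `shannon`.
#' @export
shannon_table <- function(tbl) {
  m <- abundance_matrix(tbl)
  tibble(sample_id = colnames(m), shannon = apply(m, 2, shannon))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` between sample profiles;
#' 0 for identical samples, 1 for disjoint supports. Bray-Curtis is bounded
#' in \[0, 1\] but is not a metric (the triangle inequality can fail).
#' Computation is delegated to [vegan::vegdist()].
#'
#' @param tbl Abundance tibble (features x samples).
#' @return A symmetric `dist`-convertible matrix with sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(tbl) {
  m <- abundance_matrix(tbl)
  zero <- colnames(m)[colSums(m) == 0]
  if (length(zero) > 0) {
    abort(paste0("all-zero sample(s) have undefined Bray-Curtis distance: ",
                 paste(zero, collapse = ", ")))
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Within-group beta diversity
#'
#' Collects, for each group, the pairwise dissimilarities among its samples
#' (intragroup beta diversity) and compares groups by two-sided Wilcoxon
#' rank-sum tests on those distance sets. Used to ask whether community
#' composition is more variable in some age groups than others.
#'
#' @param dist Square dissimilarity matrix with sample-id dimnames (e.g. from
#'   [bray_curtis()]).
#' @param groups Named vector or factor of group labels; names (if present)
#'   must match the distance matrix sample ids, otherwise order is used.
#' @return A list of class `gutage_beta` with `distances` (tibble: `group`,
#'   `sample_a`, `sample_b`, `distance`) and `tests` (pairwise Wilcoxon
#'   p-values).
#' @export
intragroup_beta <- function(dist, groups) {
  dist <- as.matrix(dist)
  ids <- rownames(dist)
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups))) abort("groups missing some sample ids")
    groups <- groups[ids]
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warn(paste0("excluding group(s) with fewer than 2 samples: ",
                paste(singletons, collapse = ", ")))
  }
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) == 0) abort("no group has at least 2 samples")
  dists <- purrr::map(keep, function(g) {
    idx <- which(groups == g)
    prs <- combn(idx, 2)
    tibble(group = g,
           sample_a = ids[prs[1, ]], sample_b = ids[prs[2, ]],
           distance = dist[cbind(prs[1, ], prs[2, ])])
  }) |> list_rbind()
  tests <- if (length(keep) >= 2) {
    group_tests(dists$distance, dists$group, mode = "wilcoxon-pairwise")
  } else {
    tibble(group_a = character(), group_b = character(),
           statistic = numeric(), p = numeric(),
           n_a = integer(), n_b = integer())
  }
  structure(list(distances = dists, tests = tests), class = "gutage_beta")
}

#' @export
print.gutage_beta <- function(x, ...) {
  med <- x$distances |>
    group_by(.data$group) |>
    summarise(median_distance = median(.data$distance), n_pairs = n(),
              .groups = "drop")
  cat("Within-group beta diversity\n")
  print(med)
  if (nrow(x$tests) > 0) {
    cat("Pairwise Wilcoxon tests:\n")
    print(x$tests)
  }
  invisible(x)
}

# Square root of the Jensen-Shannon divergence between probability columns.
# Zeros are replaced by a small pseudocount before renormalization so the
# Kullback-Leibler terms stay finite.
jsd_distance <- function(m, pseudocount = 1e-9) {
  m[m == 0] <- pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  n <- ncol(m)
  kld <- function(p, q) sum(p * log(p / q))
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mid <- (m[, i] + m[, j]) / 2
      d[i, j] <- d[j, i] <- sqrt(0.5 * kld(m[, i], mid) + 0.5 * kld(m[, j], mid))
    }
  }
  d
}

# Distance-based Calinski-Harabasz index: between/within sum-of-squares ratio
# computed from pairwise squared distances only (no coordinates needed).
ch_index <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  k <- length(unique(labels))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(unique(labels), function(g) {
    idx <- labels == g
    sum(d2[idx, idx]) / (2 * sum(idx))
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Enterotype clustering of genus profiles
#'
#' Clusters samples by community composition: the distance is the square root
#' of the Jensen-Shannon divergence between genus profiles, clustering is by
#' partitioning around medoids ([cluster::pam()]) for each candidate `k`, and
#' the returned `k_opt` maximizes the distance-based Calinski-Harabasz index.
#' Each cluster's driver taxon is the genus with the highest mean relative
#' abundance within the cluster.
#'
#' @param genus_tbl Genus-level abundance tibble.
#' @param k_range Candidate cluster counts (default 2:6). A single value
#'   skips the index search.
#' @param pseudocount Zero replacement used inside the divergence.
#' @return A list of class `gutage_enterotype` with `labels` (tibble:
#'   `sample_id`, `cluster`), `k_opt`, `ch` (index per k), `drivers` (tibble:
#'   `cluster`, `driver`, `mean_abundance`), and the distance matrix.
#' @export
enterotype <- function(genus_tbl, k_range = 2:6, pseudocount = 1e-9) {
  m <- abundance_matrix(normalize_relative(genus_tbl))
  n <- ncol(m)
  if (max(k_range) >= n) abort("k_range too large for the number of samples")
  if (all(apply(m, 1, function(r) max(r) - min(r) == 0))) {
    abort("all profiles identical: no cluster structure to recover")
  }
  d <- jsd_distance(m, pseudocount)
  fits <- purrr::map(k_range, function(k) cluster::pam(as.dist(d), k = k))
  ch <- purrr::map_dbl(fits, function(f) {
    if (length(k_range) == 1) return(NA_real_)
    ch_index(d, f$clustering)
  })
  best <- if (length(k_range) == 1) 1L else which.max(ch)
  fit <- fits[[best]]
  labels <- tibble(sample_id = colnames(m),
                   cluster = unname(fit$clustering))
  drivers <- labels |>
    group_by(.data$cluster) |>
    summarise(driver = rownames(m)[which.max(rowMeans(m[, .data$sample_id, drop = FALSE]))],
              mean_abundance = max(rowMeans(m[, .data$sample_id, drop = FALSE])),
              .groups = "drop")
  structure(list(labels = labels, k_opt = k_range[best],
                 ch = setNames(ch, k_range), drivers = drivers,
                 distance = d),
            class = "gutage_enterotype")
}

#' @export
print.gutage_enterotype <- function(x, ...) {
  cat("Enterotype clustering: k_opt =", x$k_opt, "\n")
  print(x$drivers)
  invisible(x)
}

# Gower-centered inner-product matrix of a squared distance matrix:
# G = -(1/2) J D^2 J with J = I - 11'/n. tr(G) is the total sum of squares.
gower_center <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  -0.5 * j %*% d2 %*% j
}

# Hat matrix of the covariate (factor -> dummies), intercept included.
permanova_hat <- function(variable, n) {
  if (is.character(variable) || is.factor(variable) || is.logical(variable)) {
    x <- model.matrix(~ factor(variable))
  } else {
    x <- cbind(1, as.numeric(variable))
  }
  if (qr(x)$rank < ncol(x)) abort("constant covariate has no effect to test")
  x %*% solve(crossprod(x)) %*% t(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' PERMANOVA effect size of a single covariate
#'
#' Permutational multivariate analysis of variance for one covariate against
#' a dissimilarity matrix. The squared distances are Gower-centered into
#' `G = -1/2 J D^2 J`; with hat matrix `H` of the covariate design, the
#' model sum of squares is `tr(HG)` (valid because `H` is idempotent), the
#' total is `tr(G)`, `R^2 = SS_model / SS_total`, and the pseudo-F compares
#' model and residual mean squares. Significance comes from permuting sample
#' labels: `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` (add-one
#' convention, so p is never 0). With `exact = TRUE` all `n!` permutations
#' are enumerated instead and `p = #\{F_perm >= F_obs\} / n!` (the identity
#' permutation is in the enumeration, so again p > 0).
#'
#' @param dist Square dissimilarity matrix (or `dist`) with sample dimnames.
#' @param variable Per-sample covariate (numeric, factor or character),
#'   aligned with the distance matrix.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all permutations (only sensible for n <= 8).
#' @return One-row tibble with `r2`, `f`, `p`, `df_model`, `n_perm`.
#' @export
permanova_r2 <- function(dist, variable, n_perm = 999, seed = 1,
                         exact = FALSE) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(variable) != n) abort("covariate must match the sample count")
  if (length(unique(variable)) < 2) abort("constant covariate has no effect to test")
  g <- gower_center(d)
  h <- permanova_hat(variable, n)
  df_model <- round(sum(diag(h))) - 1
  df_resid <- n - df_model - 1
  if (df_resid <= 0) abort("no residual degrees of freedom")
  ss_total <- sum(diag(g))
  f_of <- function(perm) {
    gp <- g[perm, perm]
    ss_model <- sum(h * gp)  # tr(H G_p): H symmetric idempotent
    (ss_model / df_model) / ((ss_total - ss_model) / df_resid)
  }
  f_obs <- f_of(seq_len(n))
  ss_model_obs <- sum(h * g)
  r2 <- ss_model_obs / ss_total
  if (exact) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, f_of)
    p <- sum(f_perm >= f_obs - 1e-12) / nrow(perms)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      f_of(sample.int(n))
    }, numeric(1)))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  }
  tibble(r2 = r2, f = f_obs, p = p, df_model = df_model,
         n_perm = if (exact) factorial(n) else n_perm)
}

# Sequential (cumulative) model R^2 for an ordered set of covariates.
permanova_combined_r2 <- function(dist, covariates) {
  d <- as.matrix(dist)
  n <- nrow(d)
  g <- gower_center(d)
  x <- matrix(1, n, 1)
  for (v in covariates) {
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      x <- cbind(x, model.matrix(~ factor(v))[, -1, drop = FALSE])
    } else {
      x <- cbind(x, as.numeric(v))
    }
  }
  qrx <- qr(x)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  h <- q %*% t(q)
  # the intercept direction contributes tr(11'G)/n = 0 because G is
  # double-centered, so tr(HG) is the covariate model SS directly
  sum(h * g) / sum(diag(g))
}

#' PERMANOVA effect-size decomposition with redundancy removal
#'
#' Decomposes the variance of a dissimilarity matrix (e.g. the serum
#' metabolome) over a table of host covariates in three steps:
#'
#' 1. single-covariate [permanova_r2()] for every covariate; keep those with
#'    permutation p < `alpha`;
#' 2. redundancy filter: walking the kept covariates in descending R^2, drop
#'    any whose absolute Pearson correlation with an already-retained
#'    covariate exceeds `redundancy_r` (the higher-R^2 member of a redundant
#'    pair survives);
#' 3. combined effect size: total model R^2 of a sequential fit of all
#'    retained covariates (descending R^2 order).
#'
#' @param dist Square dissimilarity matrix.
#' @param covariates Data frame of per-sample covariates (numeric or
#'   categorical), rows aligned with the distance matrix.
#' @param alpha Significance threshold for keeping a covariate.
#' @param redundancy_r Absolute Pearson correlation above which two
#'   covariates are considered redundant.
#' @param n_perm,seed Passed to [permanova_r2()].
#' @return A list of class `gutage_effectsize`: `table` (tibble with
#'   `variable`, `r2`, `p`, `kept`, `redundant_with`) and `combined_r2`.
#' @export
effect_size_decomposition <- function(dist, covariates, alpha = 0.05,
                                      redundancy_r = 0.5, n_perm = 999,
                                      seed = 1) {
  if (!is.data.frame(covariates) || ncol(covariates) < 2) {
    abort("need a data frame with at least 2 covariates")
  }
  single <- imap(covariates, function(v, nm) {
    res <- permanova_r2(dist, v, n_perm = n_perm, seed = seed)
    tibble(variable = nm, r2 = res$r2, p = res$p)
  }) |> list_rbind()
  single <- single[order(-single$r2), ]
  single$kept <- single$p < alpha
  single$redundant_with <- NA_character_
  retained <- character(0)
  for (i in seq_len(nrow(single))) {
    if (!single$kept[i]) next
    v <- single$variable[i]
    clash <- NULL
    for (r in retained) {
      rho <- suppressWarnings(
        cor(as.numeric(factor(covariates[[v]])),
            as.numeric(factor(covariates[[r]]))))
      if (is.finite(rho) && abs(rho) > redundancy_r) { clash <- r; break }
    }
    if (is.null(clash)) {
      retained <- c(retained, v)
    } else {
      single$kept[i] <- FALSE
      single$redundant_with[i] <- clash
    }
  }
  combined <- if (length(retained) == 0) 0 else {
    permanova_combined_r2(dist, covariates[retained])
  }
  structure(list(table = as_tibble(single), combined_r2 = combined,
                 retained = retained),
            class = "gutage_effectsize")
}

#' @export
print.gutage_effectsize <- function(x, ...) {
  cat("PERMANOVA effect-size decomposition\n")
  print(x$table)
  cat(sprintf("Combined R2 of %d retained covariate(s): %.4f\n",
              length(x$retained), x$combined_r2))
  invisible(x)
}

# Run code with a local RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
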