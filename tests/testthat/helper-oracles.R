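# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths.

# Adjusted Rand index between a clustering and the planted labels, with
# unclustered features counted as their own singleton clusters.
recovery_ari <- function(membership, species_truth) {
  lab <- membership$group_id[match(species_truth$feature_id,
                                   membership$feature_id)]
  if (any(is.na(lab))) {
    lab[is.na(lab)] <- paste0("unclustered_", seq_len(sum(is.na(lab))))
  }
  mclust::adjustedRandIndex(lab, species_truth$group_id)
}

# All permutations of 1..n by simple recursion (insertion construction),
# independent of the package's enumerator.
oracle_permutations <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1), drop = FALSE], k,
            out[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  out
}

# Brute-force PERMANOVA: explicit centering matrix, explicit hat matrix,
# F computed as tr(H G_p H) via full matrix products, exhaustive
# permutations. Ties against the observed F counted with the same 1e-12
# guard that defines the operation.
oracle_permanova <- function(d, x) {
  d <- as.matrix(d)
  n <- nrow(d)
  one <- matrix(1, n, n)
  j <- diag(n) - one / n
  g <- -0.5 * j %*% (d^2) %*% j
  xm <- cbind(1, x)
  h <- xm %*% solve(t(xm) %*% xm) %*% t(xm)
  df_m <- ncol(xm) - 1
  df_r <- n - ncol(xm)
  ss_tot <- sum(diag(g))
  fstat <- function(perm) {
    gp <- g[perm, perm]
    ssm <- sum(diag(h %*% gp %*% h))
    (ssm / df_m) / ((ss_tot - ssm) / df_r)
  }
  perms <- oracle_permutations(n)
  f_obs <- fstat(seq_len(n))
  f_all <- apply(perms, 1, fstat)
  list(r2 = sum(diag(h %*% g %*% h)) / ss_tot,
       f = f_obs,
       p = sum(f_all >= f_obs - 1e-12) / nrow(perms))
}

# Product-of-coefficients mediation oracle: two least-squares fits and the
# delta-method standard error of a_hat * b_hat.
oracle_product_of_coefficients <- function(x, m, y) {
  fm <- lm(m ~ x)
  fy <- lm(y ~ x + m)
  a <- coef(fm)["x"]; b <- coef(fy)["m"]
  se_a <- sqrt(vcov(fm)["x", "x"]); se_b <- sqrt(vcov(fy)["m", "m"])
  list(acme = unname(a * b),
       se = unname(sqrt(a^2 * se_b^2 + b^2 * se_a^2)))
}

# Small planted co-abundance matrix: `blocks` species profiles, `per_block`
# genes each, multiplicative log-normal gene noise.
planted_blocks <- function(blocks = 2, per_block = 50, n_samples = 30,
                           noise_sd = 0.05, seed = 42) {
  set.seed(seed)
  base <- matrix(rlnorm(blocks * n_samples, 0, 1.5), blocks)
  m <- base[rep(seq_len(blocks), each = per_block), ] *
    matrix(rlnorm(blocks * per_block * n_samples, 0, noise_sd),
           blocks * per_block)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(n_samples)))
  list(tbl = as_abundance(m),
       labels = rep(sprintf("block%d", seq_len(blocks)), each = per_block))
}
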