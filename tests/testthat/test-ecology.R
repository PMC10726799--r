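test_that("shannon evaluates the entropy formula with renormalization", {
  expect_equal(shannon(rep(1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon(c(0, 5, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  # invariance under feature permutation and rescaling
  v <- c(4, 1, 3, 2)
  expect_equal(shannon(v), shannon(rev(v)))
  expect_equal(shannon(v), shannon(v / sum(v)))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("bray_curtis matches the formula and flags empty samples", {
  m <- matrix(c(1, 0, 0.5, 0.5, 1, 0), 2, 3,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  d <- bray_curtis(as_abundance(m))
  expect_equal(d["a", "b"], 0.5)       # (|1-.5|+|0-.5|)/2
  expect_equal(d["a", "c"], 0)         # identical
  expect_equal(d, t(d))
  disj <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(bray_curtis(as_abundance(disj))["a", "b"], 1)
  withzero <- matrix(c(1, 1, 0, 0), 2, 2,
                     dimnames = list(c("f1", "f2"), c("a", "empty")))
  expect_error(bray_curtis(as_abundance(withzero)), "empty")
})

test_that("intragroup beta separates tight from dispersed groups", {
  set.seed(10)
  tight <- matrix(rlnorm(5 * 10, 0, 0.05), 5)
  loose <- matrix(rlnorm(5 * 10, 0, 1.5), 5)
  m <- cbind(tight, loose)
  dimnames(m) <- list(paste0("f", 1:5), paste0("s", 1:20))
  d <- bray_curtis(normalize_relative(as_abundance(m)))
  groups <- setNames(rep(c("old", "young"), each = 10), colnames(m))
  res <- intragroup_beta(d, groups)
  med <- tapply(res$distances$distance, res$distances$group, median)
  expect_lt(med["old"], med["young"])
  expect_lt(res$tests$p, 0.01)
  # literally identical groups: identical within-group distance sets
  block <- matrix(rlnorm(5 * 10, 0, 1), 5)
  twin <- cbind(block, block)
  dimnames(twin) <- list(paste0("f", 1:5), paste0("s", 1:20))
  same <- bray_curtis(normalize_relative(as_abundance(twin)))
  res2 <- intragroup_beta(same, setNames(rep(c("g1", "g2"), each = 10),
                                         colnames(twin)))
  expect_gt(res2$tests$p, 0.9)
  expect_warning(intragroup_beta(d, setNames(c("solo", rep(c("a", "b"),
                                                           length.out = 19)),
                                             colnames(m))),
                 "fewer than 2")
})

test_that("enterotyping recovers well-separated community types", {
  set.seed(11)
  k <- 3; per <- 20; n_genus <- 8
  m <- matrix(rlnorm(n_genus * k * per, 0, 0.3), n_genus)
  for (i in seq_len(k)) m[i, ((i - 1) * per + 1):(i * per)] <- 30
  dimnames(m) <- list(paste0("genus", seq_len(n_genus)),
                      paste0("s", seq_len(k * per)))
  truth <- rep(seq_len(k), each = per)
  et <- enterotype(as_abundance(m), k_range = 2:5)
  expect_equal(et$k_opt, 3)
  expect_gte(mclust::adjustedRandIndex(et$labels$cluster, truth), 0.9)
  # driver taxa are the dominating genera
  expect_setequal(et$drivers$driver, c("genus1", "genus2", "genus3"))
  # single k skips the index search
  single <- enterotype(as_abundance(m), k_range = 2)
  expect_equal(single$k_opt, 2)
  expect_true(all(is.na(single$ch)))
  flat <- matrix(1, 4, 10, dimnames = list(paste0("g", 1:4),
                                           paste0("s", 1:10)))
  expect_error(enterotype(as_abundance(flat), k_range = 2), "identical")
})

test_that("permanova_r2 agrees with vegan on R2 and is seed-reproducible", {
  set.seed(12)
  m <- matrix(rlnorm(8 * 24, 0, 1), 8,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:24)))
  x <- rnorm(24)
  d <- bray_curtis(normalize_relative(as_abundance(m)))
  got <- permanova_r2(d, x, n_perm = 99, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ x, permutations = 99)
  expect_equal(got$r2, ref$R2[1], tolerance = 1e-10)
  expect_equal(got$f, ref$F[1], tolerance = 1e-10)
  again <- permanova_r2(d, x, n_perm = 99, seed = 5)
  expect_identical(got, again)
  # categorical covariates work; constant ones do not
  expect_s3_class(permanova_r2(d, rep(c("a", "b"), 12), n_perm = 49), "tbl_df")
  expect_error(permanova_r2(d, rep("a", 24)), "constant")
})

test_that("disjoint groups reach the permutation floor", {
  m <- cbind(matrix(rlnorm(10 * 10, 0, 0.2), 10),
             matrix(0, 10, 10))
  m <- rbind(m, cbind(matrix(0, 10, 10),
                      matrix(rlnorm(10 * 10, 0, 0.2), 10)))
  dimnames(m) <- list(paste0("f", 1:20), paste0("s", 1:20))
  d <- bray_curtis(normalize_relative(as_abundance(m)))
  res <- permanova_r2(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)
})

test_that("effect-size decomposition filters, deduplicates and combines", {
  set.seed(13)
  n <- 40
  grad <- rnorm(n)
  m <- matrix(rlnorm(6 * n, 0, 0.3), 6)
  m[1, ] <- m[1, ] * exp(grad)          # composition tracks grad
  dimnames(m) <- list(paste0("f", 1:6), paste0("s", 1:n))
  d <- bray_curtis(normalize_relative(as_abundance(m)))
  covs <- data.frame(grad = grad,
                     grad_copy = grad,           # perfectly redundant
                     noise = rnorm(n))
  res <- effect_size_decomposition(d, covs, n_perm = 199, seed = 2)
  tab <- res$table
  expect_true(sum(tab$kept[tab$variable %in% c("grad", "grad_copy")]) == 1)
  dropped <- tab[tab$variable %in% c("grad", "grad_copy") & !tab$kept, ]
  expect_false(is.na(dropped$redundant_with))
  expect_false(tab$kept[tab$variable == "noise"] &&
                 tab$p[tab$variable == "noise"] >= 0.05)
  # combined model R2 at least the best retained single R2 (nested models)
  expect_gte(res$combined_r2, max(tab$r2[tab$kept]) - 1e-12)
  # covariate input order does not matter
  res2 <- effect_size_decomposition(d, covs[, c(3, 2, 1)], n_perm = 199,
                                    seed = 2)
  expect_equal(res$combined_r2, res2$combined_r2)
  expect_equal(sort(res$retained),
               sort(sub("grad_copy", "grad", res2$retained)))
})
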