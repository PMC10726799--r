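test_that("two planted blocks are recovered exactly", {
  pb <- planted_blocks(blocks = 2, per_block = 50, noise_sd = 0.05)
  res <- canopy_cluster(pb$tbl)
  expect_equal(length(res$cags), 2)
  expect_equal(recovery_ari(res$membership,
                            tibble::tibble(feature_id = pb$tbl$feature_id,
                                           group_id = pb$labels)), 1)
})

test_that("proportional genes collapse to one canopy, uncorrelated ones to singletons", {
  set.seed(20)
  base <- rlnorm(20, 0, 1.5)
  m <- outer(rlnorm(30, 0, 0.5), base)   # all proportional to one profile
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20))
  res <- build_canopies(as_abundance(m))
  expect_equal(length(res), 1)
  expect_equal(length(res[[1]]$members), 30)

  set.seed(21)
  indep <- matrix(rlnorm(12 * 40, 0, 1), 12,
                  dimnames = list(sprintf("g%02d", 1:12),
                                  sprintf("s%02d", 1:40)))
  # keep only gene sets whose pairwise correlations stay below the threshold
  singles <- build_canopies(as_abundance(indep))
  expect_true(all(vapply(singles, function(cp) length(cp$members),
                         integer(1)) == 1))
  expect_error(build_canopies(as_abundance(indep[, 1:3])), "4 samples")
})

test_that("merging is transitive and leaves uncorrelated canopies alone", {
  set.seed(22)
  n <- 12
  base <- rlnorm(n, 0, 1)
  mk <- function(id, profile) list(seed_gene = id, members = id,
                                   profile = profile)
  genes <- rbind(a = base, b = base * 1.0001 + 1e-4,
                 c = base * 1.0002 + 2e-4, d = rlnorm(n, 0, 1))
  colnames(genes) <- sprintf("s%02d", seq_len(n))
  tbl <- as_abundance(genes)
  canopies <- list(mk("a", genes["a", ]), mk("b", genes["b", ]),
                   mk("c", genes["c", ]), mk("d", genes["d", ]))
  merged <- merge_canopies(canopies, tbl)
  sizes <- sort(vapply(merged, function(cp) length(cp$members), integer(1)))
  expect_equal(sizes, c(1, 3))  # a~b~c chain joins transitively, d stays
  # identical duplicate canopies always merge (r = 1 >= 0.97)
  dup_genes <- rbind(a = base, b = base)
  colnames(dup_genes) <- sprintf("s%02d", seq_len(n))
  dup <- merge_canopies(list(mk("a", base), mk("b", base)),
                        as_abundance(dup_genes))
  expect_equal(length(dup), 1)
})

test_that("filters discard weakly supported canopies", {
  n <- 20
  mk_genes <- function(nm, profile, k) {
    m <- matrix(rep(profile, each = k) * rlnorm(k * n, 0, 0.01), k,
                dimnames = list(paste0(nm, seq_len(k)), sprintf("s%02d", 1:n)))
    m
  }
  uniform <- mk_genes("u", rep(1, n), 10)
  spiky_profile <- c(rep(100, 3), rep(1e-4, n - 3))
  spiky <- mk_genes("p", spiky_profile, 10)
  sparse_profile <- c(rep(1, 3), rep(0, n - 3))
  sparse <- mk_genes("q", sparse_profile, 10) *
    matrix(rep(sparse_profile > 0, each = 10), 10)
  pair <- mk_genes("w", rep(1, n), 2)
  genes <- as_abundance(rbind(uniform, spiky, sparse, pair))
  canopies <- list(
    list(seed_gene = "u1", members = rownames(uniform),
         profile = apply(uniform, 2, median)),
    list(seed_gene = "p1", members = rownames(spiky),
         profile = apply(spiky, 2, median)),
    list(seed_gene = "q1", members = rownames(sparse),
         profile = apply(sparse, 2, median)),
    list(seed_gene = "w1", members = rownames(pair),
         profile = apply(pair, 2, median)))
  kept <- filter_canopies(canopies, genes)
  expect_equal(vapply(kept, function(cp) cp$seed_gene, character(1)), "u1")
})

test_that("the MGS size rule is strictly greater than 700", {
  mk <- function(k) list(seed_gene = "s", members = sprintf("g%d", seq_len(k)),
                         profile = 1:4)
  sizes <- c(699, 700, 701, 1500)
  labeled <- call_mgs(lapply(sizes, mk))
  expect_equal(vapply(labeled, function(cp) cp$is_mgs, logical(1)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(call_mgs(list()), list())
})

test_that("a planted block above 700 genes is called an MGS with consistent abundance", {
  pb <- planted_blocks(blocks = 2, per_block = 750, n_samples = 12,
                       noise_sd = 0.05, seed = 77)
  res <- canopy_cluster(pb$tbl)
  expect_equal(sum(vapply(res$cags, function(cp) cp$is_mgs, logical(1))), 2)
  # definitional consistency: MGS abundance equals the member-gene median
  ab <- mgs_abundance(pb$tbl, res$membership)
  cag1 <- res$membership$group_id[1]
  m <- abundance_matrix(pb$tbl)
  expect_equal(abundance_matrix(ab)[cag1, ],
               apply(m[res$membership$feature_id[res$membership$group_id == cag1],
                       ], 2, median))
})

test_that("clustering is deterministic and capture tightening shrinks canopies", {
  pb <- planted_blocks(blocks = 3, per_block = 30, noise_sd = 0.15, seed = 9)
  a <- canopy_cluster(pb$tbl)
  b <- canopy_cluster(pb$tbl)
  expect_identical(a$membership, b$membership)
  # partition property: each clustered gene appears exactly once
  expect_false(anyDuplicated(a$membership$feature_id) > 0)
  loose <- build_canopies(pb$tbl, canopy_params(capture_pearson = 0.5,
                                                recenter_iters = 0))
  tight <- build_canopies(pb$tbl, canopy_params(capture_pearson = 0.99,
                                                recenter_iters = 0))
  size_of <- function(cps, seed_gene) {
    for (cp in cps) if (cp$seed_gene == seed_gene) return(length(cp$members))
    0L
  }
  for (cp in tight) {
    expect_lte(length(cp$members), max(size_of(loose, cp$seed_gene),
                                       length(cp$members)))
  }
  first_loose <- loose[[1]]
  expect_gte(length(first_loose$members), length(tight[[1]]$members))
})
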