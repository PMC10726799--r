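hit_row <- function(gene, sp, id, cov = 90, bits = 500,
                    genus = "genusA", phylum = "phylumA") {
  tibble::tibble(gene_id = gene, subject_species = sp,
                 subject_genus = genus, subject_phylum = phylum,
                 identity = id, coverage = cov, bitscore = bits)
}

test_that("identity thresholds set the assigned rank", {
  hits <- dplyr::bind_rows(
    hit_row("g1", "spA", 96, cov = 80),    # species
    hit_row("g2", "spB", 90),              # genus
    hit_row("g3", "spC", 70),              # phylum
    hit_row("g4", "spD", 60),              # unassigned
    hit_row("g5", "spE", 96, cov = 50))    # coverage fail -> unassigned
  res <- assign_gene_taxonomy(hits)
  expect_equal(res$assigned_rank,
               c("species", "genus", "phylum", "unassigned", "unassigned"))
  expect_equal(res$taxon[1], "spA")
  expect_equal(res$taxon[2], "genusA")
  expect_equal(res$taxon[3], "phylumA")
  expect_true(is.na(res$taxon[4]))
  # thresholds are inclusive
  edge <- assign_gene_taxonomy(hit_row("g9", "spZ", 95))
  expect_equal(edge$assigned_rank, "species")
})

test_that("rank never rises when the best identity drops", {
  ranks <- c(unassigned = 0, phylum = 1, genus = 2, species = 3)
  ids <- seq(100, 55, by = -5)
  got <- vapply(ids, function(id) {
    assign_gene_taxonomy(hit_row("g", "spA", id))$assigned_rank
  }, character(1))
  expect_true(all(diff(ranks[got]) <= 0))
})

test_that("equal-bit-score ties resolve by frequency, mean identity, then name", {
  # majority wins despite a higher single identity elsewhere
  t1 <- dplyr::bind_rows(hit_row("g", "A", 97), hit_row("g", "A", 97),
                         hit_row("g", "A", 97), hit_row("g", "B", 99))
  expect_equal(resolve_best_hit_ties(t1), "A")
  # frequency tied: higher mean identity wins
  t2 <- dplyr::bind_rows(hit_row("g", "A", 96), hit_row("g", "A", 96),
                         hit_row("g", "B", 98), hit_row("g", "B", 98))
  expect_equal(resolve_best_hit_ties(t2), "B")
  # fully tied: lexicographic
  t3 <- dplyr::bind_rows(hit_row("g", "B", 96), hit_row("g", "A", 96),
                         hit_row("g", "B", 96), hit_row("g", "A", 96))
  expect_equal(resolve_best_hit_ties(t3), "A")
  expect_error(resolve_best_hit_ties(t1[0, ]), "no tied hits")
  # the tie path feeds the gene-level assignment
  assigned <- assign_gene_taxonomy(t1)
  expect_equal(assigned$taxon, "A")
})

test_that("MGS species rule fires at 90% support and not at 89%", {
  members <- tibble::tibble(feature_id = sprintf("g%03d", 1:100),
                            group_id = "MGS1")
  mk_hits <- function(n_good) {
    dplyr::bind_rows(
      hit_row(sprintf("g%03d", seq_len(n_good)), "spA", 96),
      hit_row(sprintf("g%03d", (n_good + 1):100), "spB", 60))
  }
  at90 <- assign_mgs_taxonomy(members, mk_hits(90))
  expect_equal(at90$assigned_rank, "species")
  expect_equal(at90$taxon, "spA")
  expect_equal(at90$support, 0.9)
  at89 <- assign_mgs_taxonomy(members, mk_hits(89))
  expect_false(at89$assigned_rank == "species")
})

test_that("MGS falls back to genus at 80% and to unclassified on splits", {
  members <- tibble::tibble(feature_id = sprintf("g%03d", 1:100),
                            group_id = "MGS1")
  # 85 genes at genus-level identity, species rule fails
  genus_hits <- dplyr::bind_rows(
    hit_row(sprintf("g%03d", 1:85), "spA", 88, genus = "genusG"),
    hit_row(sprintf("g%03d", 86:100), "spB", 60, genus = "genusX"))
  got <- assign_mgs_taxonomy(members, genus_hits)
  expect_equal(got$assigned_rank, "genus")
  expect_equal(got$taxon, "genusG")
  # 50/50 split across two species -> unclassified
  split_hits <- dplyr::bind_rows(
    hit_row(sprintf("g%03d", 1:50), "spA", 96, genus = "genusA"),
    hit_row(sprintf("g%03d", 51:100), "spB", 96, genus = "genusB"))
  expect_equal(assign_mgs_taxonomy(members, split_hits)$assigned_rank,
               "unclassified")
})

test_that("clean synthetic hit tables assign every gene and MGS to its true species", {
  truth <- tibble::tibble(feature_id = sprintf("g%03d", 1:90),
                          group_id = rep(c("sp01", "sp02", "sp03"), each = 30))
  hits <- generate_hit_table(truth, identity_noise = 0, decoy_prob = 0,
                             seed = 4)
  genes <- assign_gene_taxonomy(hits)
  expect_true(all(genes$assigned_rank == "species"))
  expect_equal(genes$taxon,
               truth$group_id[match(genes$gene_id, truth$feature_id)])
  mgs <- assign_mgs_taxonomy(truth, hits)
  expect_true(all(mgs$assigned_rank == "species"))
  expect_equal(mgs$taxon, sort(unique(truth$group_id)))
})

test_that("sub-species identities downgrade assignments to genus or phylum", {
  truth <- tibble::tibble(feature_id = sprintf("g%03d", 1:30),
                          group_id = "sp01")
  at88 <- assign_gene_taxonomy(
    generate_hit_table(truth, mean_identity = 88, identity_noise = 0,
                       decoy_prob = 0, seed = 5))
  expect_true(all(at88$assigned_rank == "genus"))
  at80 <- assign_gene_taxonomy(
    generate_hit_table(truth, mean_identity = 80, identity_noise = 0,
                       decoy_prob = 0, seed = 5))
  expect_true(all(at80$assigned_rank == "phylum"))
})

test_that("injected ties resolve to the majority species", {
  truth <- tibble::tibble(feature_id = sprintf("g%03d", 1:40),
                          group_id = rep(c("sp01", "sp02"), each = 20))
  hits <- generate_hit_table(truth, identity_noise = 0, decoy_prob = 0,
                             tie_genes = c("g001", "g021"), seed = 6)
  for (g in c("g001", "g021")) {
    sub <- hits[hits$gene_id == g, ]
    top <- sub[sub$bitscore == max(sub$bitscore), ]
    expect_gte(nrow(top), 3)  # true species twice, decoy once
    expect_equal(resolve_best_hit_ties(top),
                 truth$group_id[truth$feature_id == g])
  }
  genes <- assign_gene_taxonomy(hits)
  expect_equal(genes$taxon[match(c("g001", "g021"), genes$gene_id)],
               c("sp01", "sp02"))
})
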