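small_cfg <- function(...) {
  cohort_config(n_samples = 60, n_species = 10, genes_per_species = 25,
                n_metabolites = 15, ...)
}

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(small_cfg(seed = 7))
  b <- generate_cohort(small_cfg(seed = 7))
  expect_identical(a$gene_abundance, b$gene_abundance)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$hits, b$hits)
  c <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$gene_abundance, c$gene_abundance))
})

test_that("cohort invariants hold: composition, truth alignment, valid clinicals", {
  co <- generate_cohort(small_cfg(seed = 3))
  g <- abundance_matrix(co$gene_abundance)
  expect_true(all(abs(colSums(g) - 1) < 1e-9))
  s <- abundance_matrix(co$species_abundance)
  expect_true(all(abs(colSums(s) - 1) < 1e-9))
  expect_true(all(g >= 0))
  # every gene maps to exactly one species
  expect_equal(sort(co$species_truth$feature_id), sort(rownames(g)))
  expect_false(anyDuplicated(co$species_truth$feature_id) > 0)
  # metabolites and subjects align with the sample axis
  expect_equal(colnames(abundance_matrix(co$metabolites)),
               co$subjects$sample_id)
  expect_true(all(co$subjects$scr >= 0.3))
  ages <- co$subjects$age
  expect_true(all(ages >= 20 & ages <= 111))
  # creatinine rises with age by construction
  expect_gt(cor(ages, co$subjects$scr), 0.3)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_species = 0), "positive")
  expect_error(cohort_config(age_range = c(80, 20)), "increasing")
  expect_error(cohort_config(dropout_prob = 1), "\\[0, 1\\)")
  expect_error(cohort_config(gene_noise_sd = -1), "nonnegative")
})

test_that("zero slopes and zero noise give age-independent species", {
  cfg <- cohort_config(n_samples = 80, n_species = 6, genes_per_species = 5,
                       n_age_linked_species = 0, species_noise_sd = 0,
                       gene_noise_sd = 0, dropout_prob = 0,
                       n_metabolites = 0, seed = 5)
  co <- generate_cohort(cfg)
  s <- abundance_matrix(co$species_abundance)
  # all log-profiles constant across samples: no rank association with age
  # (a constant profile has an undefined correlation, which counts as none)
  for (i in seq_len(nrow(s))) {
    cc <- suppressWarnings(cor(s[i, ], co$subjects$age, method = "spearman"))
    expect_lt(abs(ifelse(is.na(cc), 0, cc)), 1e-9,
              label = sprintf("species %d vs age", i))
  }
})

test_that("planted age-linked species are recovered by rank correlation", {
  cfg <- cohort_config(n_samples = 150, n_species = 12,
                       genes_per_species = 5, n_age_linked_species = 4,
                       species_age_slopes = 0.02, species_noise_sd = 0.3,
                       n_metabolites = 0, mediation_chains = NULL, seed = 9)
  co <- generate_cohort(cfg)
  s <- abundance_matrix(co$species_abundance)
  ps <- apply(s, 1, function(v) {
    cor.test(v, co$subjects$age, method = "spearman", exact = FALSE)$p.value
  })
  q <- bh_fdr(ps)
  planted <- co$truth$age_slopes$species[co$truth$age_slopes$slope != 0]
  expect_length(planted, 4)
  expect_true(all(q[planted] < 0.05))
})

test_that("mediation chain triplets have the stated structure", {
  ch <- generate_mediation_chain(500, a = 0.5, b = 0.5, c_prime = 0,
                                 noise_m = 1, noise_y = 1, seed = 2)
  expect_equal(ch$truth$acme, 0.25)
  fit_m <- lm(m ~ x, data = ch$data)
  fit_y <- lm(y ~ x + m, data = ch$data)
  expect_lt(abs(coef(fit_m)["x"] - 0.5), 0.15)
  expect_lt(abs(coef(fit_y)["m"] - 0.5), 0.15)
  # null chains have zero population ACME
  expect_equal(generate_mediation_chain(50, a = 0, b = 0.7)$truth$acme, 0)
  expect_equal(generate_mediation_chain(50, a = 0.7, b = 0)$truth$acme, 0)
  expect_error(generate_mediation_chain(5), "n >= 10")
  expect_identical(generate_mediation_chain(100, seed = 3)$data,
                   generate_mediation_chain(100, seed = 3)$data)
})

test_that("cohort chains plant the forward covariance structure", {
  cfg <- cohort_config(n_samples = 1000, seed = 13,
                       n_species = 10, genes_per_species = 10,
                       n_metabolites = 12,
                       mediation_chains = tibble::tibble(
                         species = "sp10", metabolite = "met012",
                         a = 0.5, b = 0.5, c_prime = 0,
                         noise_m = 0.3, noise_y = 1))
  co <- generate_cohort(cfg)
  lat <- co$truth$chain_latents
  z_age <- as.numeric(scale(co$subjects$age))
  # mediator model: m on x recovers a
  expect_lt(abs(coef(lm(lat$m ~ lat$x))[2] - 0.5), 0.1)
  # outcome model: age on x and m shows the mediated path, not a direct one
  # (coefficient SEs here are ~0.1 because x and m are strongly correlated)
  fit <- lm(z_age * sqrt(0.5^2 * (0.5^2 + 0.3^2) + 1) ~ lat$x + lat$m)
  expect_lt(abs(coef(fit)["lat$m"] - 0.5), 0.3)
  expect_lt(abs(coef(fit)["lat$x"]), 0.25)
  # the latent drives the planted species' measured abundance
  sp_ab <- abundance_matrix(co$species_abundance)["sp10", ]
  expect_gt(cor(log(sp_ab), lat$x), 0.7)
  # and the mediator metabolite carries m
  met <- abundance_matrix(co$metabolites)["met012", ]
  expect_gt(cor(met, lat$m), 0.95)
})

test_that("age groups bin at 60, 90 and 100", {
  expect_equal(as.character(age_group(c(20, 59.9, 60, 89.9, 90, 99.9, 100, 110))),
               c("<60", "<60", "60-89", "60-89", "90-99", "90-99",
                 "100+", "100+"))
})

test_that("write_cohort emits the full TSV bundle with a manifest", {
  withr::with_tempdir({
    co <- generate_cohort(small_cfg(seed = 2))
    write_cohort(co, "out")
    files <- c("gene_abundance.tsv", "species_abundance.tsv",
               "species_truth.tsv", "metabolites.tsv", "subjects.tsv",
               "hits.tsv", "qpcr.tsv", "manifest.json")
    expect_true(all(file.exists(file.path("out", files))))
    back <- read_abundance(file.path("out", "gene_abundance.tsv"))
    expect_equal(abundance_matrix(back),
                 abundance_matrix(co$gene_abundance), tolerance = 1e-12)
    man <- jsonlite::read_json(file.path("out", "manifest.json"))
    expect_equal(man$config$seed, 2)
  })
})
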