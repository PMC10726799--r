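#' Synthetic cohort configuration
#'
#' Parameters of the planted-truth cohort generator. Defaults describe the
#' desk-scale study design used throughout the package's validation suite:
#' 150 subjects aged 20-111, 30 species with 200 genes each, heavy-tailed
#' (log-normal) compositional abundances, a handful of age-linked species
#' with +/-0.02 per-year slopes on log-abundance, metabolites produced as
#' linear functions of producer-species abundance plus Gaussian noise, and
#' explicit exposure -> mediator -> age chains with stated coefficients.
#'
#' @param n_samples Number of subjects.
#' @param n_species Number of planted species.
#' @param genes_per_species Gene count per species; length-2 range or a
#'   single fixed count.
#' @param age_range Uniform age range in years.
#' @param n_age_linked_species How many species get an age slope.
#' @param species_age_slopes Signed slopes on log-abundance per year,
#'   recycled over the age-linked species.
#' @param species_noise_sd SD of the per-sample species log-abundance noise
#'   (default 1.5: gut species abundances span orders of magnitude).
#' @param gene_noise_sd SD of the per-gene multiplicative (log-scale) noise.
#' @param dropout_prob Fraction of each gene's weakest signals lost to the
#'   detection limit: per gene, the lowest `dropout_prob` quantile of its
#'   noisy abundances is zeroed, after gene noise and before
#'   renormalization.
#' @param n_metabolites Number of serum metabolites.
#' @param producer_map Data frame (`metabolite`, `species`, `coef`) linking
#'   metabolites to producer species; `NULL` builds a default map in which
#'   the first third of the metabolites each have one producer species.
#' @param metabolite_noise_sd SD of metabolite measurement noise.
#' @param mediation_chains Data frame (`species`, `metabolite`, `a`, `b`,
#'   `c_prime`, `noise_m`, `noise_y`) of planted chains; `NULL` plants one
#'   default chain (a = b = 0.5, c' = 0, noise_m = 0.3, noise_y = 1).
#' @param seed Integer seed; identical configs generate bit-identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 150, n_species = 30,
                          genes_per_species = 200, age_range = c(20, 111),
                          n_age_linked_species = 5,
                          species_age_slopes = c(0.02, -0.02),
                          species_noise_sd = 1.5,
                          gene_noise_sd = 0.2, dropout_prob = 0.1,
                          n_metabolites = 60, producer_map = NULL,
                          metabolite_noise_sd = 0.5,
                          mediation_chains = NULL, seed = 1) {
  if (n_samples < 1 || n_species < 1 || n_metabolites < 0) {
    abort("counts must be positive")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("age_range must be an increasing (min, max) pair")
  }
  if (dropout_prob < 0 || dropout_prob >= 1) abort("dropout_prob must be in [0, 1)")
  if (species_noise_sd < 0 || gene_noise_sd < 0 || metabolite_noise_sd < 0) {
    abort("noise SDs must be nonnegative")
  }
  if (n_age_linked_species > n_species) {
    abort("cannot age-link more species than exist")
  }
  if (length(genes_per_species) == 1) {
    genes_per_species <- rep(genes_per_species, 2)
  }
  if (is.null(producer_map) && n_metabolites > 0) {
    n_prod <- max(1, floor(n_metabolites / 3))
    producer_map <- tibble(
      metabolite = sprintf("met%03d", seq_len(n_prod)),
      species = sprintf("sp%02d", ((seq_len(n_prod) - 1) %% n_species) + 1),
      coef = 50)
  }
  if (is.null(mediation_chains) && n_metabolites > 0) {
    # exposure species and mediator metabolite chosen outside the
    # age-linked and producer-driven sets so the chain is the only signal
    mediation_chains <- tibble(
      species = sprintf("sp%02d", n_species),
      metabolite = sprintf("met%03d", n_metabolites),
      a = 0.5, b = 0.5, c_prime = 0, noise_m = 0.3, noise_y = 1)
  }
  structure(as.list(environment()), class = "cohort_config")
}

species_names <- function(n) sprintf("sp%02d", seq_len(n))

# Deterministic fabricated lineage: 3 species per genus, 4 genera per phylum.
species_lineage <- function(species) {
  idx <- as.integer(sub("^sp", "", species))
  genus <- ((idx - 1) %/% 3) + 1
  phylum <- ((genus - 1) %/% 4) + 1
  tibble(subject_species = species,
         subject_genus = sprintf("genus%02d", genus),
         subject_phylum = sprintf("phylum%02d", phylum))
}

#' Generate a synthetic multi-omics cohort with planted truth
#'
#' Draws ages uniformly over the configured range, species log-abundances as
#' `mu_s + slope_s * (age - midpoint) + N(0, species_noise_sd)` (log-normal
#' after exponentiation, renormalized per sample), gene abundances as species
#' abundance times a fixed per-gene multiplier times multiplicative
#' log-normal noise, followed by dropout and per-sample renormalization.
#' Metabolites are linear functions of producer-species relative abundance
#' plus Gaussian noise. For each mediation chain, latent `(x, m)` are drawn
#' from the conditional Gaussian of the chain model `x -> m -> y` given the
#' standardized age, so the chain's covariance structure is planted exactly
#' without disturbing the uniform age design; `x` becomes the exposure
#' species' log-abundance deviation and `m` shifts the mediator metabolite.
#' Serum creatinine increases with age (`0.6 + 0.004 * age + N(0, 0.1)`,
#' floored at 0.3) so the eGFR branches on both sides of the sex-specific
#' knots are exercised.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: `gene_abundance`,
#'   `species_abundance`, `metabolites` (abundance tibbles), `species_truth`
#'   (gene -> species map), `subjects` (tibble with `sample_id`, `age`,
#'   `sex`, `scr`, `age_group`), `hits` (alignment hit table), `qpcr`
#'   (telomere plate), and `truth` (planted slopes, producer coefficients,
#'   chain coefficients and latents).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("config must be a cohort_config()")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("s%03d", seq_len(n))
  sp <- species_names(cfg$n_species)

  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "female", "male")
  scr <- pmax(0.3, 0.6 + 0.004 * age + rnorm(n, 0, 0.1))
  subjects <- tibble(sample_id = samples, age = age, sex = sex, scr = scr,
                     age_group = age_group(age))

  slopes <- rep(0, cfg$n_species)
  linked <- seq_len(cfg$n_age_linked_species)
  slopes[linked] <- rep_len(cfg$species_age_slopes, length(linked))
  mid_age <- mean(cfg$age_range)

  mu <- rnorm(cfg$n_species, 0, 1.5)
  log_ab <- matrix(mu, cfg$n_species, n) +
    outer(slopes, age - mid_age) +
    matrix(rnorm(cfg$n_species * n, 0, cfg$species_noise_sd), cfg$n_species, n)

  chains <- cfg$mediation_chains
  chain_latents <- NULL
  if (!is.null(chains) && nrow(chains) > 0) {
    z_age <- as.numeric(scale(age))
    lat <- purrr::map(seq_len(nrow(chains)), function(i) {
      ch <- chains[i, ]
      xm <- chain_conditional_xm(z_age, ch$a, ch$b, ch$c_prime,
                                 ch$noise_m, ch$noise_y)
      tibble(chain = i, sample_id = samples, x = xm$x, m = xm$m)
    }) |> list_rbind()
    chain_latents <- lat
    for (i in seq_len(nrow(chains))) {
      si <- match(chains$species[i], sp)
      if (is.na(si)) abort("chain refers to unknown species")
      xi <- lat$x[lat$chain == i]
      log_ab[si, ] <- mu[si] + xi  # the chain latent is the species signal
    }
  }

  species_ab <- exp(log_ab)
  species_ab <- sweep(species_ab, 2, colSums(species_ab), "/")
  dimnames(species_ab) <- list(sp, samples)

  n_genes_per <- round(runif(cfg$n_species, cfg$genes_per_species[1],
                             cfg$genes_per_species[2]))
  gene_species <- rep(sp, n_genes_per)
  gene_ids <- sprintf("gene%05d", seq_along(gene_species))
  g <- length(gene_ids)
  multiplier <- rlnorm(g, 0, 1)
  noise <- matrix(rlnorm(g * n, 0, cfg$gene_noise_sd), g, n)
  gene_ab <- species_ab[gene_species, , drop = FALSE] * multiplier * noise
  if (cfg$dropout_prob > 0) {
    # detection-limit dropout: each gene's weakest signals are lost, so per
    # gene the lowest dropout_prob fraction of samples is zeroed
    cut <- apply(gene_ab, 1, quantile, probs = cfg$dropout_prob)
    gene_ab[gene_ab <= cut] <- 0
  }
  gene_ab <- sweep(gene_ab, 2, pmax(colSums(gene_ab), .Machine$double.xmin), "/")
  dimnames(gene_ab) <- list(gene_ids, samples)

  mets <- NULL
  if (cfg$n_metabolites > 0) {
    met_ids <- sprintf("met%03d", seq_len(cfg$n_metabolites))
    base <- matrix(rnorm(cfg$n_metabolites * n, 10, cfg$metabolite_noise_sd),
                   cfg$n_metabolites, n, dimnames = list(met_ids, samples))
    if (!is.null(cfg$producer_map)) {
      for (i in seq_len(nrow(cfg$producer_map))) {
        pm <- cfg$producer_map[i, ]
        base[pm$metabolite, ] <- base[pm$metabolite, ] +
          pm$coef * species_ab[pm$species, ]
      }
    }
    if (!is.null(chain_latents)) {
      for (i in seq_len(nrow(chains))) {
        mi <- chains$metabolite[i]
        if (!mi %in% met_ids) abort("chain refers to unknown metabolite")
        base[mi, ] <- 10 + chain_latents$m[chain_latents$chain == i]
      }
    }
    mets <- as_abundance(pmax(base, 0))
  }

  truth <- list(
    age_slopes = tibble(species = sp, slope = slopes),
    producers = cfg$producer_map,
    chains = chains,
    chain_latents = chain_latents)

  species_truth <- tibble(feature_id = gene_ids, group_id = gene_species)
  hits <- generate_hit_table(species_truth, seed = cfg$seed + 1)
  qpcr <- generate_qpcr_plate(min(n, 50), seed = cfg$seed + 2)

  structure(list(
    gene_abundance = as_abundance(gene_ab),
    species_abundance = as_abundance(species_ab),
    species_truth = species_truth,
    metabolites = mets,
    subjects = subjects,
    hits = hits,
    qpcr = qpcr,
    truth = truth,
    config = cfg), class = "synthetic_cohort")
}

# Draw (x, m) of the linear chain x -> m -> y conditional on observed
# standardized y. Only the chain's second moments matter to the linear
# mediation models, and those are reproduced exactly.
chain_conditional_xm <- function(z_y, a, b, c_prime, noise_m, noise_y) {
  var_m <- a^2 + noise_m^2
  cov_xm <- a
  cov_xy <- c_prime + a * b
  cov_my <- a * c_prime + b * var_m
  var_y <- b^2 * var_m + c_prime^2 + 2 * a * b * c_prime + noise_y^2
  sigma11 <- matrix(c(1, cov_xm, cov_xm, var_m), 2, 2)
  sigma12 <- c(cov_xy, cov_my)
  cond_cov <- sigma11 - tcrossprod(sigma12) / var_y
  ch <- tryCatch(chol(cond_cov),
                 error = function(e) chol(cond_cov + diag(1e-12, 2)))
  y_obs <- z_y * sqrt(var_y)
  mean_xm <- tcrossprod(sigma12 / var_y, y_obs)  # 2 x n
  eps <- t(ch) %*% matrix(rnorm(2 * length(z_y)), 2)
  xm <- mean_xm + eps
  list(x = xm[1, ], m = xm[2, ])
}

#' Age-group labels
#'
#' Bins ages into the four groups used for cohort comparisons:
#' 20-59 (young/middle-aged), 60-89 (elderly), 90-99 (nonagenarian),
#' 100+ (centenarian).
#'
#' @param age Ages in years.
#' @return Factor with levels `<60`, `60-89`, `90-99`, `100+`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 60, 90, 100, Inf),
      labels = c("<60", "60-89", "90-99", "100+"), right = FALSE)
}

#' Generate one mediation-chain triplet
#'
#' Standalone test bed for the mediation machinery: `x ~ N(0,1)`,
#' `m = a*x + e_m`, `y = b*m + c'*x + e_y`. The population average causal
#' mediation effect (per unit of x) in this linear no-interaction model is
#' `a * b`.
#'
#' @param n Sample size (>= 10).
#' @param a,b,c_prime Chain coefficients.
#' @param noise_m,noise_y Noise SDs (>= 0).
#' @param seed Integer seed.
#' @return List with `data` (tibble `x`, `m`, `y`) and `truth` (tibble with
#'   the coefficients and the population `acme = a * b`).
#' @export
generate_mediation_chain <- function(n, a = 0.5, b = 0.5, c_prime = 0,
                                     noise_m = 1, noise_y = 1, seed = 1) {
  if (n < 10) abort("need n >= 10")
  if (noise_m < 0 || noise_y < 0) abort("noise SDs must be nonnegative")
  dat <- with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + rnorm(n, 0, noise_m)
    y <- b * m + c_prime * x + rnorm(n, 0, noise_y)
    tibble(x = x, m = m, y = y)
  })
  list(data = dat,
       truth = tibble(a = a, b = b, c_prime = c_prime, acme = a * b))
}

#' Generate an alignment best-hit table for planted genes
#'
#' Every gene receives a best hit to its true species at
#' `identity ~ N(mean_identity, identity_noise)` (clamped to \[50, 100\])
#' with the top bit score, plus optionally a lower-identity decoy hit to a
#' different species. Genes listed in `tie_genes` additionally get
#' equal-bit-score hits — two to the true species and one to a decoy species
#' — so downstream tie resolution by majority is exercised.
#'
#' @param species_truth Feature map (`feature_id` gene, `group_id` species).
#' @param mean_identity Mean percent identity of the true-species hit.
#' @param identity_noise SD of the identity noise.
#' @param coverage_range Uniform query-coverage range (percent).
#' @param decoy_prob Probability a gene also gets a decoy hit.
#' @param tie_genes Genes for which tied best hits are injected.
#' @param seed Integer seed.
#' @return Hit tibble as consumed by [assign_gene_taxonomy()].
#' @export
generate_hit_table <- function(species_truth, mean_identity = 97,
                               identity_noise = 1,
                               coverage_range = c(75, 100),
                               decoy_prob = 0.3, tie_genes = character(0),
                               seed = 1) {
  species_truth <- validate_feature_map(species_truth)
  if (nrow(species_truth) == 0) abort("species_truth is empty")
  with_seed(seed, {
    g <- nrow(species_truth)
    all_sp <- unique(species_truth$group_id)
    clamp <- function(x) pmin(100, pmax(50, x))
    best <- tibble(
      gene_id = species_truth$feature_id,
      subject_species = species_truth$group_id,
      identity = clamp(rnorm(g, mean_identity, identity_noise)),
      coverage = runif(g, coverage_range[1], coverage_range[2]),
      bitscore = 900 + round(runif(g, 0, 50)))
    rows <- list(best)
    if (decoy_prob > 0 && length(all_sp) > 1) {
      has_decoy <- rbinom(g, 1, decoy_prob) == 1
      if (any(has_decoy)) {
        other <- vapply(species_truth$group_id[has_decoy], function(s) {
          sample(setdiff(all_sp, s), 1)
        }, character(1))
        rows[[2]] <- tibble(
          gene_id = species_truth$feature_id[has_decoy],
          subject_species = unname(other),
          identity = clamp(rnorm(sum(has_decoy), 78, 3)),
          coverage = runif(sum(has_decoy), coverage_range[1], coverage_range[2]),
          bitscore = 400 + round(runif(sum(has_decoy), 0, 50)))
      }
    }
    hits <- list_rbind(rows)
    if (length(tie_genes) > 0) {
      if (!all(tie_genes %in% species_truth$feature_id)) {
        abort("tie_genes must be planted genes")
      }
      ties <- purrr::map(tie_genes, function(gid) {
        true_sp <- species_truth$group_id[species_truth$feature_id == gid]
        decoy_sp <- if (length(all_sp) > 1) sample(setdiff(all_sp, true_sp), 1)
                    else true_sp
        bs <- hits$bitscore[hits$gene_id == gid][1]
        tibble(gene_id = gid,
               subject_species = c(true_sp, decoy_sp),
               identity = clamp(rnorm(2, mean_identity, identity_noise)),
               coverage = runif(2, coverage_range[1], coverage_range[2]),
               bitscore = bs)
      }) |> list_rbind()
      hits <- bind_rows(hits, ties)
    }
    lineage <- species_lineage(unique(hits$subject_species))
    hits |>
      left_join(lineage, by = "subject_species") |>
      select("gene_id", "subject_species", "subject_genus",
             "subject_phylum", "identity", "coverage", "bitscore") |>
      arrange(.data$gene_id, desc(.data$bitscore))
  })
}

#' Generate a telomere qPCR plate with known T/S ratios
#'
#' Simulates Ct values for the telomere (T) and single-copy gene (S) assays,
#' three replicates each, plus the inter-plate standard. The per-sample
#' `dCt = Ct(T) - Ct(S)` is offset from the standard's by `-log2(true_ts)`,
#' so noise-free plates recover `true_ts` exactly.
#'
#' @param n_samples Number of samples.
#' @param true_ts True T/S ratios (recycled; default log-normal around 1).
#' @param replicate_sd Replicate noise SD in Ct units.
#' @param seed Integer seed.
#' @return List with `plate` (long tibble: `sample_id`, `target`,
#'   `replicate`, `ct`; standard included as sample `"standard"`) and
#'   `truth` (tibble `sample_id`, `true_ts`).
#' @export
generate_qpcr_plate <- function(n_samples, true_ts = NULL,
                                replicate_sd = 0.1, seed = 1) {
  if (n_samples < 1) abort("need at least one sample")
  with_seed(seed, {
    if (is.null(true_ts)) true_ts <- rlnorm(n_samples, 0, 0.25)
    true_ts <- rep_len(true_ts, n_samples)
    if (any(true_ts <= 0)) abort("true T/S ratios must be positive")
    ids <- sprintf("q%03d", seq_len(n_samples))
    std_ct_s <- 19
    std_dct <- 3
    base_s <- runif(n_samples, 17, 20)
    dct <- std_dct - log2(true_ts)
    one <- function(id, ct_t_mean, ct_s_mean) {
      tibble(sample_id = id,
             target = rep(c("T", "S"), each = 3),
             replicate = rep(1:3, 2),
             ct = c(ct_t_mean + rnorm(3, 0, replicate_sd),
                    ct_s_mean + rnorm(3, 0, replicate_sd)))
    }
    plate <- purrr::map(seq_len(n_samples), function(i) {
      one(ids[i], base_s[i] + dct[i], base_s[i])
    }) |> list_rbind()
    plate <- bind_rows(plate, one("standard", std_ct_s + std_dct, std_ct_s))
    list(plate = plate, truth = tibble(sample_id = ids, true_ts = true_ts))
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d species, %d genes, %d metabolites\n",
              nrow(x$subjects), nrow(x$species_abundance),
              nrow(x$gene_abundance),
              if (is.null(x$metabolites)) 0 else nrow(x$metabolites)))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `gene_abundance.tsv`, `species_abundance.tsv`, `species_truth.tsv`,
#' `metabolites.tsv`, `subjects.tsv`, `hits.tsv`, `qpcr.tsv` and a
#' `manifest.json` recording the generator configuration and seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance(cohort$gene_abundance, file.path(dir, "gene_abundance.tsv"))
  write_abundance(cohort$species_abundance,
                  file.path(dir, "species_abundance.tsv"))
  readr::write_tsv(cohort$species_truth, file.path(dir, "species_truth.tsv"))
  if (!is.null(cohort$metabolites)) {
    write_abundance(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  }
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  readr::write_tsv(cohort$hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(cohort$qpcr$plate, file.path(dir, "qpcr.tsv"))
  cfg <- cohort$config
  cfg$producer_map <- NULL; cfg$mediation_chains <- NULL
  jsonlite::write_json(
    list(config = unclass(cfg),
         producer_map = cohort$config$producer_map,
         mediation_chains = cohort$config$mediation_chains),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
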