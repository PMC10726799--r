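#' Pipeline configuration
#'
#' Configures an end-to-end run: either a [cohort_config()] generator (the
#' synthetic route) or a directory of input TSVs written by
#' [write_cohort()], plus per-stage parameters. All seeds are explicit so a
#' run can be reproduced from its manifest alone.
#'
#' @param generator A [cohort_config()], or `NULL` when `input_dir` is
#'   given.
#' @param input_dir Directory holding `gene_abundance.tsv`,
#'   `metabolites.tsv`, `subjects.tsv`, `hits.tsv` (mutually exclusive with
#'   `generator`).
#' @param out_dir Output directory.
#' @param canopy A [canopy_params()] list.
#' @param taxonomy A [taxonomy_params()] list.
#' @param rf_target Metabolite to model with [forward_select_rf()]; `NULL`
#'   picks the first metabolite.
#' @param n_trees Trees for the forward-selection forests.
#' @param n_perm Permutations for the effect-size stage.
#' @param n_sims Draws for the mediation stage.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(), input_dir = NULL,
                            out_dir = tempfile("gutage_run_"),
                            canopy = canopy_params(),
                            taxonomy = taxonomy_params(),
                            rf_target = NULL, n_trees = 100,
                            n_perm = 199, n_sims = 500, seed = 1) {
  if (is.null(generator) == is.null(input_dir)) {
    abort("exactly one of generator or input_dir must be given")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage_digest <- function(...) rlang::hash(list(...))

run_stage <- function(name, manifest, digest, outputs, out_dir, fn) {
  paths <- file.path(out_dir, outputs)
  cached <- !is.null(manifest$stages[[name]]) &&
    identical(manifest$stages[[name]]$digest, digest) &&
    all(file.exists(paths))
  if (cached) {
    message(sprintf("[%s] cached (digest %s)", name, substr(digest, 1, 8)))
    return(list(manifest = manifest, ran = FALSE))
  }
  fn(paths)
  manifest$stages[[name]] <- list(
    digest = digest,
    outputs = outputs,
    output_hash = vapply(paths, function(p) {
      rlang::hash(readChar(p, file.info(p)$size, useBytes = TRUE))
    }, character(1), USE.NAMES = FALSE))
  message(sprintf("[%s] done (digest %s)", name, substr(digest, 1, 8)))
  list(manifest = manifest, ran = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a synthetic or user-supplied
#' cohort: cohort generation/loading, canopy clustering into CAGs/MGSs, MGS
#' abundance and taxonomy, diversity and PERMANOVA effect-size
#' decomposition of the metabolome, age-adjusted associations,
#' forward-selection random forest for one metabolite, and the bidirectional
#' mediation screen. Every stage logs a parameter digest and output hashes
#' to `manifest.json`; re-running with an unchanged configuration reuses
#' cached stage outputs, and deleting an intermediate file recomputes only
#' that stage and its dependents.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; stage outputs are TSV/JSON files
#'   (`cags.tsv`, `mgs_abundance.tsv`, `taxonomy.tsv`, `shannon.tsv`,
#'   `effects.tsv`, `assoc.tsv`, `selection.json`, `linkages.tsv`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path)
  } else list(stages = list())

  # --- cohort ---------------------------------------------------------
  cohort_files <- c("gene_abundance.tsv", "metabolites.tsv", "subjects.tsv",
                    "hits.tsv", "species_truth.tsv")
  if (!is.null(config$generator)) {
    dg <- stage_digest("cohort", config$generator)
    st <- run_stage("cohort", manifest, dg, cohort_files, out_dir, function(paths) {
      write_cohort(generate_cohort(config$generator), out_dir)
    })
    manifest <- st$manifest
  } else {
    for (f in cohort_files[1:4]) {
      src <- file.path(config$input_dir, f)
      if (!file.exists(src)) abort(paste0("cohort stage: missing input ", src))
      file.copy(src, file.path(out_dir, f), overwrite = TRUE)
    }
  }
  genes <- read_abundance(file.path(out_dir, "gene_abundance.tsv"))
  mets <- read_abundance(file.path(out_dir, "metabolites.tsv"))
  subjects <- readr::read_tsv(file.path(out_dir, "subjects.tsv"),
                              show_col_types = FALSE)
  hits <- readr::read_tsv(file.path(out_dir, "hits.tsv"),
                          show_col_types = FALSE)
  if (!all(c("age", "sex", "scr") %in% names(subjects))) {
    abort("cohort stage produced a subjects table without age/sex/scr")
  }

  # --- clustering -----------------------------------------------------
  dg <- stage_digest("cags", config$canopy, genes)
  st <- run_stage("cags", manifest, dg, "cags.tsv", out_dir, function(paths) {
    cl <- canopy_cluster(genes, config$canopy)
    readr::write_tsv(cl$membership, paths[1])
  })
  manifest <- st$manifest
  membership <- readr::read_tsv(file.path(out_dir, "cags.tsv"),
                                show_col_types = FALSE)

  # --- MGS abundance + taxonomy --------------------------------------
  dg <- stage_digest("mgs", membership, genes)
  st <- run_stage("mgs", manifest, dg, "mgs_abundance.tsv", out_dir,
                  function(paths) {
    write_abundance(mgs_abundance(genes, membership), paths[1])
  })
  manifest <- st$manifest
  mgs <- read_abundance(file.path(out_dir, "mgs_abundance.tsv"))

  dg <- stage_digest("taxonomy", membership, hits, config$taxonomy)
  st <- run_stage("taxonomy", manifest, dg, "taxonomy.tsv", out_dir,
                  function(paths) {
    readr::write_tsv(assign_mgs_taxonomy(membership, hits, config$taxonomy),
                     paths[1])
  })
  manifest <- st$manifest

  # --- ecology --------------------------------------------------------
  dg <- stage_digest("ecology", mgs, mets, subjects, config$n_perm,
                     config$seed)
  st <- run_stage("ecology", manifest, dg, c("shannon.tsv", "effects.tsv"),
                  out_dir, function(paths) {
    readr::write_tsv(shannon_table(mgs), paths[1])
    covs <- as.data.frame(subjects[, c("age", "sex", "scr")])
    es <- effect_size_decomposition(
      bray_curtis(normalize_relative(mets)), covs,
      n_perm = config$n_perm, seed = config$seed)
    tab <- es$table
    tab$combined_r2 <- es$combined_r2
    readr::write_tsv(tab, paths[2])
  })
  manifest <- st$manifest

  # --- associations ---------------------------------------------------
  dg <- stage_digest("assoc", mgs, mets, subjects$age)
  st <- run_stage("assoc", manifest, dg, "assoc.tsv", out_dir,
                  function(paths) {
    readr::write_tsv(correlate_features(mgs, mets, adjust = subjects$age),
                     paths[1])
  })
  manifest <- st$manifest

  # --- random-forest selection ---------------------------------------
  target <- config$rf_target %||% mets$feature_id[1]
  dg <- stage_digest("rfselect", mgs, mets, target, config$n_trees,
                     config$seed)
  st <- run_stage("rfselect", manifest, dg, "selection.json", out_dir,
                  function(paths) {
    x <- t(abundance_matrix(mgs))
    y <- as.numeric(abundance_matrix(mets)[target, rownames(x)])
    sel <- forward_select_rf(x, y, n_trees = config$n_trees,
                             seed = config$seed)
    jsonlite::write_json(
      list(target = target, selected = sel$selected,
           q2_trajectory = sel$q2_trajectory, final_q2 = sel$final_q2,
           importances = sel$importances),
      paths[1], auto_unbox = TRUE, digits = NA)
  })
  manifest <- st$manifest

  # --- mediation screen ----------------------------------------------
  dg <- stage_digest("mediation", mgs, mets, subjects$age, config$n_sims,
                     config$seed)
  st <- run_stage("mediation", manifest, dg, "linkages.tsv", out_dir,
                  function(paths) {
    age <- setNames(subjects$age, subjects$sample_id)
    readr::write_tsv(bidirectional_screen(mgs, mets, age,
                                          n_sims = config$n_sims,
                                          seed = config$seed), paths[1])
  })
  manifest <- st$manifest

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
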