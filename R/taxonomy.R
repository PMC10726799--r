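#' Taxonomy assignment thresholds
#'
#' Identity cutoffs (percent, inclusive) for rank assignment from nucleotide
#' best hits: >= 95 species, >= 85 genus, >= 65 phylum; alignments below 70%
#' query coverage are discarded before any assignment. MGS-level rules:
#' species requires >= 90% of member genes hitting one species at the
#' species-rank thresholds; genus requires >= 80% of member genes hitting one
#' genus at >= 85% identity.
#'
#' @param species_identity,genus_identity,phylum_identity Rank cutoffs.
#' @param min_coverage Minimal query coverage.
#' @param mgs_species_frac,mgs_genus_frac Member-gene fractions for MGS
#'   assignment (computed over all member genes, annotated or not).
#' @return A list of class `taxonomy_params`.
#' @export
taxonomy_params <- function(species_identity = 95, genus_identity = 85,
                            phylum_identity = 65, min_coverage = 70,
                            mgs_species_frac = 0.9, mgs_genus_frac = 0.8) {
  structure(as.list(environment()), class = "taxonomy_params")
}

validate_hits <- function(hits) {
  need <- c("gene_id", "subject_species", "subject_genus", "subject_phylum",
            "identity", "coverage", "bitscore")
  if (!all(need %in% names(hits))) {
    abort(paste0("hit table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(hits$identity < 0 | hits$identity > 100) ||
      any(hits$coverage < 0 | hits$coverage > 100)) {
    abort("identity and coverage are percentages in [0, 100]")
  }
  if (any(hits$bitscore < 0)) abort("bit scores must be nonnegative")
  as_tibble(hits)
}

#' Resolve equal-bit-score best hits to a single species
#'
#' When a gene's best hits (maximal bit score) span several species, the
#' winning species is the one with the highest frequency among the tied
#' hits; remaining ties are broken by highest mean identity, then
#' lexicographically by species name.
#'
#' @param tied_hits Hit-table rows for one gene, all sharing the maximal
#'   bit score.
#' @return The winning species name (character scalar).
#' @export
resolve_best_hit_ties <- function(tied_hits) {
  if (nrow(tied_hits) == 0) abort("no tied hits to resolve")
  stats <- as_tibble(tied_hits) |>
    group_by(.data$subject_species) |>
    summarise(freq = n(), mean_identity = mean(.data$identity),
              .groups = "drop") |>
    arrange(desc(.data$freq), desc(.data$mean_identity),
            .data$subject_species)
  stats$subject_species[1]
}

#' Rule-based gene taxonomy from alignment best hits
#'
#' Per gene: hits below `min_coverage` query coverage are removed; the best
#' hit is the one with maximal bit score (ties across species resolved by
#' [resolve_best_hit_ties()]); the assigned rank follows the best-hit
#' identity (>= 95 species, >= 85 genus, >= 65 phylum, else unassigned) and
#' the taxon name is taken at that rank. A gene with no surviving hit is
#' unassigned, not an error.
#'
#' @param hits Hit table: `gene_id`, `subject_species`, `subject_genus`,
#'   `subject_phylum`, `identity`, `coverage`, `bitscore` (BLAST
#'   outfmt-6-like, one row per alignment).
#' @param params A [taxonomy_params()] list.
#' @return Tibble with `gene_id`, `assigned_rank` (`species`/`genus`/
#'   `phylum`/`unassigned`), `taxon` (NA when unassigned), `best_identity`.
#' @export
assign_gene_taxonomy <- function(hits, params = taxonomy_params()) {
  hits <- validate_hits(hits)
  all_genes <- unique(hits$gene_id)
  hits <- hits[hits$coverage >= params$min_coverage, ]
  assigned <- hits |>
    group_by(.data$gene_id) |>
    group_map(function(h, key) {
      best <- h[h$bitscore == max(h$bitscore), ]
      species <- if (length(unique(best$subject_species)) > 1) {
        resolve_best_hit_ties(best)
      } else {
        best$subject_species[1]
      }
      sp_hits <- h[h$subject_species == species, ]
      best_id <- max(sp_hits$identity)
      top <- sp_hits[which.max(sp_hits$identity), ]
      rank <- if (best_id >= params$species_identity) "species"
              else if (best_id >= params$genus_identity) "genus"
              else if (best_id >= params$phylum_identity) "phylum"
              else "unassigned"
      taxon <- switch(rank,
                      species = species,
                      genus = top$subject_genus[1],
                      phylum = top$subject_phylum[1],
                      unassigned = NA_character_)
      tibble(gene_id = key$gene_id, assigned_rank = rank, taxon = taxon,
             best_identity = best_id)
    }) |> list_rbind()
  missing <- setdiff(all_genes, assigned$gene_id)
  if (length(missing) > 0) {
    assigned <- bind_rows(assigned,
                          tibble(gene_id = missing,
                                 assigned_rank = "unassigned",
                                 taxon = NA_character_,
                                 best_identity = NA_real_))
  }
  assigned[order(assigned$gene_id), ]
}

#' MGS taxonomy from member-gene hits
#'
#' An MGS (or CAG) is assigned to a species when at least
#' `mgs_species_frac` (default 90%) of its member genes align to that
#' species at species-rank identity (>= 95%) and coverage (>= 70%);
#' otherwise to a genus when at least `mgs_genus_frac` (default 80%) of the
#' genes align to that genus at >= 85% identity; otherwise it is
#' unclassified. Fractions are computed over all member genes, including
#' unannotated ones, so sparse annotation cannot inflate support.
#'
#' @param membership Feature map with columns `feature_id` (gene) and
#'   `group_id` (CAG/MGS id).
#' @param hits Gene-level hit table (see [assign_gene_taxonomy()]).
#' @param params A [taxonomy_params()] list.
#' @return Tibble with `group_id`, `assigned_rank`, `taxon`, `support`
#'   (fraction of member genes backing the call), `n_genes`.
#' @export
assign_mgs_taxonomy <- function(membership, hits, params = taxonomy_params()) {
  membership <- validate_feature_map(membership)
  hits <- validate_hits(hits)
  hits <- hits[hits$coverage >= params$min_coverage, ]
  purrr::map(split(membership$feature_id, membership$group_id), function(genes) {
    n <- length(genes)
    h <- hits[hits$gene_id %in% genes, ]
    sp <- h[h$identity >= params$species_identity, ] |>
      distinct(.data$gene_id, .data$subject_species) |>
      count(.data$subject_species, name = "hits") |>
      arrange(desc(.data$hits), .data$subject_species)
    if (nrow(sp) > 0 && sp$hits[1] / n >= params$mgs_species_frac) {
      return(tibble(assigned_rank = "species", taxon = sp$subject_species[1],
                    support = sp$hits[1] / n, n_genes = n))
    }
    ge <- h[h$identity >= params$genus_identity, ] |>
      distinct(.data$gene_id, .data$subject_genus) |>
      count(.data$subject_genus, name = "hits") |>
      arrange(desc(.data$hits), .data$subject_genus)
    if (nrow(ge) > 0 && ge$hits[1] / n >= params$mgs_genus_frac) {
      return(tibble(assigned_rank = "genus", taxon = ge$subject_genus[1],
                    support = ge$hits[1] / n, n_genes = n))
    }
    tibble(assigned_rank = "unclassified", taxon = NA_character_,
           support = if (nrow(sp) > 0) sp$hits[1] / n else 0, n_genes = n)
  }) |> list_rbind(names_to = "group_id")
}
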