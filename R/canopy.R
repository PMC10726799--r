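#' Canopy clustering parameters
#'
#' Thresholds for co-abundance clustering of gene profiles into CAGs/MGSs.
#' The defaults are the standard canopy settings for metagenomic gene
#' catalogs: a gene joins a canopy when both Pearson > 0.9 and Spearman >
#' 0.6 against the canopy profile; canopies whose median profiles correlate
#' at Pearson >= 0.97 are merged; canopies with <= 2 genes, with their signal
#' concentrated in <= 3 samples (>= 90% of the total), detected in < 4
#' samples, or with one sample holding >= 90% of the signal are discarded;
#' surviving canopies are CAGs and CAGs with more than 700 genes are MGSs.
#'
#' @param capture_pearson,capture_spearman Strict capture thresholds.
#' @param merge_pearson Merge threshold on median profiles (inclusive).
#' @param min_genes_cag Minimal retained canopy size (default 3; smaller
#'   canopies are discarded).
#' @param mgs_min_genes Minimal MGS size (default 701, i.e. > 700 genes).
#' @param top3_signal_frac Discard when the top three samples hold at least
#'   this fraction of the canopy's summed signal.
#' @param single_sample_frac Discard when one sample holds at least this
#'   fraction of the summed signal.
#' @param min_detected_samples Median profile must be nonzero in at least
#'   this many samples.
#' @param recenter_iters Recapture iterations against the recomputed median
#'   profile after the initial seed capture.
#' @return A list of class `canopy_params`.
#' @export
canopy_params <- function(capture_pearson = 0.9, capture_spearman = 0.6,
                          merge_pearson = 0.97, min_genes_cag = 3,
                          mgs_min_genes = 701, top3_signal_frac = 0.9,
                          single_sample_frac = 0.9,
                          min_detected_samples = 4, recenter_iters = 1) {
  stopifnot(capture_pearson > 0, capture_pearson <= 1,
            capture_spearman > 0, capture_spearman <= 1,
            merge_pearson > 0, merge_pearson <= 1,
            min_genes_cag >= 1, mgs_min_genes >= 1,
            min_detected_samples >= 1, recenter_iters >= 0)
  structure(as.list(environment()), class = "canopy_params")
}

# Pearson correlation of every row of a centered matrix against a vector;
# rows or vectors with zero variance yield NA (non-capturable).
cor_rows_centered <- function(mc, ss, v) {
  vc <- v - mean(v)
  den_v <- sum(vc^2)
  if (den_v == 0) return(rep(NA_real_, nrow(mc)))
  r <- as.numeric(mc %*% vc) / sqrt(ss * den_v)
  r[ss == 0] <- NA_real_
  r
}

row_ranks <- function(m) {
  t(apply(m, 1, rank))
}

#' Build canopies from gene abundance profiles
#'
#' Deterministic greedy canopy clustering. Seeds are drawn from the not yet
#' clustered genes in descending order of total abundance (ties broken by
#' gene id); a gene joins the current canopy iff its Pearson correlation with
#' the canopy profile exceeds `capture_pearson` and its Spearman correlation
#' exceeds `capture_spearman` (average ranks; zero-variance profiles are
#' non-capturable). After the initial capture against the seed profile the
#' canopy's median profile is recomputed and membership re-captured against
#' it for `recenter_iters` iterations (the seed always stays in). Captured
#' genes leave the pool, so finalized canopies never overlap.
#'
#' @param genes Gene abundance tibble (>= 4 samples).
#' @param params A [canopy_params()] list.
#' @return List of canopies, each a list with `seed_gene`, `members`
#'   (character) and `profile` (median abundance per sample).
#' @export
build_canopies <- function(genes, params = canopy_params()) {
  m <- abundance_matrix(genes)
  if (ncol(m) < 4) abort("canopy clustering needs at least 4 samples")
  ranks <- row_ranks(m)
  mc <- m - rowMeans(m)
  rc <- ranks - rowMeans(ranks)
  ss_m <- rowSums(mc^2)
  ss_r <- rowSums(rc^2)
  total <- rowSums(m)
  seed_order <- rownames(m)[order(-total, rownames(m))]
  in_pool <- setNames(rep(TRUE, nrow(m)), rownames(m))
  variable <- ss_m > 0
  canopies <- list()
  capture <- function(profile, candidate_idx) {
    pe <- cor_rows_centered(mc[candidate_idx, , drop = FALSE],
                            ss_m[candidate_idx], profile)
    sp <- cor_rows_centered(rc[candidate_idx, , drop = FALSE],
                            ss_r[candidate_idx], rank(profile))
    hit <- !is.na(pe) & !is.na(sp) &
      pe > params$capture_pearson & sp > params$capture_spearman
    rownames(m)[candidate_idx][hit]
  }
  for (seed in seed_order) {
    if (!in_pool[seed]) next
    if (!variable[seed]) next  # zero-variance genes cannot seed
    pool_idx <- which(in_pool)
    members <- capture(m[seed, ], pool_idx)
    members <- union(seed, members)
    iter <- 0
    while (iter < params$recenter_iters) {
      profile <- apply(m[members, , drop = FALSE], 2, median)
      cand_idx <- which(in_pool | rownames(m) %in% members)
      members <- union(seed, capture(profile, cand_idx))
      iter <- iter + 1
    }
    in_pool[members] <- FALSE
    canopies[[length(canopies) + 1]] <- list(
      seed_gene = seed,
      members = sort(members),
      profile = apply(m[members, , drop = FALSE], 2, median))
  }
  # remaining genes (zero variance, never captured) become singletons
  for (g in rownames(m)[in_pool]) {
    canopies[[length(canopies) + 1]] <- list(
      seed_gene = g, members = g, profile = m[g, ])
  }
  canopies
}

#' Merge canopies with near-identical median profiles
#'
#' Canopies whose median profiles correlate at Pearson >= `merge_pearson`
#' are merged transitively (union-find, so the result is independent of
#' pair order); merged median profiles are recomputed from the pooled member
#' genes.
#'
#' @param canopies Output of [build_canopies()].
#' @param genes The gene abundance tibble the canopies were built from.
#' @param params A [canopy_params()] list.
#' @return List of canopies after merging.
#' @export
merge_canopies <- function(canopies, genes, params = canopy_params()) {
  k <- length(canopies)
  if (k <= 1) return(canopies)
  m <- abundance_matrix(genes)
  profiles <- t(vapply(canopies, function(cp) cp$profile, numeric(ncol(m))))
  pc <- suppressWarnings(cor(t(profiles)))
  pc[!is.finite(pc)] <- 0
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (pc[i, j] >= params$merge_pearson) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  purrr::map(unique(roots), function(r) {
    grp <- canopies[roots == r]
    members <- sort(unique(unlist(purrr::map(grp, "members"))))
    # the merged seed is the seed of the largest constituent canopy
    sizes <- purrr::map_dbl(grp, ~ length(.x$members))
    list(seed_gene = grp[[which.max(sizes)]]$seed_gene,
         members = members,
         profile = apply(m[members, , drop = FALSE], 2, median))
  })
}

#' Filter canopies into CAGs
#'
#' Discards canopies with insufficient supporting evidence: fewer than
#' `min_genes_cag` genes (<= 2 by default); top-three samples holding
#' >= `top3_signal_frac` of the canopy's total summed member-gene signal;
#' median profile detected (nonzero) in fewer than `min_detected_samples`
#' samples; or a single sample holding >= `single_sample_frac` of the summed
#' signal. Survivors are co-abundance gene groups (CAGs).
#'
#' @inheritParams merge_canopies
#' @return List of surviving canopies (CAGs).
#' @export
filter_canopies <- function(canopies, genes, params = canopy_params()) {
  m <- abundance_matrix(genes)
  keep <- purrr::map_lgl(canopies, function(cp) {
    if (length(cp$members) < params$min_genes_cag) return(FALSE)
    signal <- colSums(m[cp$members, , drop = FALSE])
    tot <- sum(signal)
    if (tot <= 0) return(FALSE)
    top3 <- sum(sort(signal, decreasing = TRUE)[seq_len(min(3, length(signal)))])
    if (top3 / tot >= params$top3_signal_frac) return(FALSE)
    if (max(signal) / tot >= params$single_sample_frac) return(FALSE)
    if (sum(cp$profile > 0) < params$min_detected_samples) return(FALSE)
    TRUE
  })
  canopies[keep]
}

#' Label CAGs as metagenomic species
#'
#' CAGs with more than 700 member genes (strictly greater; configurable via
#' `mgs_min_genes`) are labeled MGSs — clusters large enough to represent the
#' core genome of a bacterial species.
#'
#' @param cags List of CAGs from [filter_canopies()].
#' @param params A [canopy_params()] list.
#' @return The CAG list with an `is_mgs` flag added to each element.
#' @export
call_mgs <- function(cags, params = canopy_params()) {
  purrr::map(cags, function(cp) {
    cp$is_mgs <- length(cp$members) >= params$mgs_min_genes
    cp
  })
}

#' Full canopy pipeline: build, merge, filter, label
#'
#' Runs [build_canopies()], [merge_canopies()], [filter_canopies()] and
#' [call_mgs()] and returns a tidy result. CAG ids are assigned in
#' descending size order (`CAG0001`, ...).
#'
#' @inheritParams build_canopies
#' @return An object of class `gutage_cags` with `membership` (tibble:
#'   `feature_id`, `group_id`, `is_mgs`, `seed_gene`), `cags` (the canopy
#'   list) and `params`.
#' @export
canopy_cluster <- function(genes, params = canopy_params()) {
  canopies <- build_canopies(genes, params)
  merged <- merge_canopies(canopies, genes, params)
  cags <- call_mgs(filter_canopies(merged, genes, params), params)
  cags <- cags[order(-purrr::map_dbl(cags, ~ length(.x$members)),
                     purrr::map_chr(cags, "seed_gene"))]
  ids <- sprintf("CAG%04d", seq_along(cags))
  membership <- imap(cags, function(cp, i) {
    tibble(feature_id = cp$members, group_id = ids[[i]],
           is_mgs = cp$is_mgs, seed_gene = cp$seed_gene)
  }) |> list_rbind()
  structure(list(membership = membership, cags = setNames(cags, ids),
                 params = params),
            class = "gutage_cags")
}

#' @export
print.gutage_cags <- function(x, ...) {
  sizes <- purrr::map_int(x$cags, ~ length(.x$members))
  cat(sprintf("%d CAG(s), of which %d MGS(s); %d genes clustered\n",
              length(x$cags),
              sum(purrr::map_lgl(x$cags, "is_mgs")),
              nrow(x$membership)))
  if (length(sizes) > 0) {
    cat("size range:", min(sizes), "-", max(sizes), "genes\n")
  }
  invisible(x)
}
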