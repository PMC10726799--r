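#' Tidy a forward-selection random-forest result
#'
#' @param x An `rf_selection` object.
#' @param ... Unused.
#' @return One row per selected variable with its selection step, the LOOCV
#'   Q^2 after its addition, and its full-model importance.
#' @method tidy rf_selection
#' @export
tidy.rf_selection <- function(x, ...) {
  tibble(variable = x$selected,
         step = seq_along(x$selected),
         q2_after = x$q2_trajectory) |>
    left_join(x$importances, by = "variable")
}

#' @rdname tidy.rf_selection
#' @method glance rf_selection
#' @export
glance.rf_selection <- function(x, ...) {
  tibble(final_q2 = x$final_q2,
         variance_explained_pct = 100 * x$final_q2,
         n_selected = length(x$selected),
         n = x$n, n_trees = x$n_trees)
}

#' Tidy a mediation result
#'
#' @param x A `mediation_result` object.
#' @param ... Unused.
#' @return One row per effect (acme, ade, total) with estimate, percentile
#'   confidence bounds and simulation p-value.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(term = c("acme", "ade", "total"),
         estimate = c(x$acme, x$ade, x$total),
         conf.low = x$ci[, 1],
         conf.high = x$ci[, 2],
         p.value = c(x$p_mediation, x$p_direct, x$p_total))
}

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(prop_mediated = x$prop_mediated, direction = x$direction,
         n = x$n, n_sims = x$n_sims,
         treat_value = x$treat_value, control_value = x$control_value)
}

#' Tidy a PERMANOVA effect-size decomposition
#'
#' @param x A `gutage_effectsize` object.
#' @param ... Unused.
#' @return The per-covariate table (`variable`, `r2`, `p`, `kept`,
#'   `redundant_with`).
#' @method tidy gutage_effectsize
#' @export
tidy.gutage_effectsize <- function(x, ...) x$table

#' @rdname tidy.gutage_effectsize
#' @method glance gutage_effectsize
#' @export
glance.gutage_effectsize <- function(x, ...) {
  tibble(combined_r2 = x$combined_r2, n_retained = length(x$retained),
         n_tested = nrow(x$table))
}

#' Tidy an enterotype clustering
#'
#' @param x A `gutage_enterotype` object.
#' @param ... Unused.
#' @return Sample labels joined with each cluster's driver taxon.
#' @method tidy gutage_enterotype
#' @export
tidy.gutage_enterotype <- function(x, ...) {
  left_join(x$labels, x$drivers, by = "cluster")
}

#' @rdname tidy.gutage_enterotype
#' @method glance gutage_enterotype
#' @export
glance.gutage_enterotype <- function(x, ...) {
  tibble(k_opt = x$k_opt, n = nrow(x$labels),
         ch_max = if (all(is.na(x$ch))) NA_real_ else max(x$ch, na.rm = TRUE))
}

#' Tidy a canopy clustering
#'
#' @param x A `gutage_cags` object.
#' @param ... Unused.
#' @return The gene membership table (`feature_id`, `group_id`, `is_mgs`,
#'   `seed_gene`).
#' @method tidy gutage_cags
#' @export
tidy.gutage_cags <- function(x, ...) x$membership

#' @rdname tidy.gutage_cags
#' @method glance gutage_cags
#' @export
glance.gutage_cags <- function(x, ...) {
  tibble(n_cags = length(x$cags),
         n_mgs = sum(purrr::map_lgl(x$cags, "is_mgs")),
         n_genes_clustered = nrow(x$membership),
         largest = if (length(x$cags) == 0) 0L else
           max(purrr::map_int(x$cags, ~ length(.x$members))))
}
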