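#' Plot the Q-squared trajectory of a forward selection
#'
#' Line-and-point plot of the LOOCV Q^2 after each variable addition; the
#' trajectory is strictly increasing by the stopping rule.
#'
#' @param object An `rf_selection` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rf_selection
#' @export
autoplot.rf_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$step, y = .data$q2_after)) +
    geom_line(color = "grey40") +
    geom_point(size = 2) +
    geom_text(aes(label = .data$variable), vjust = -0.8, size = 3) +
    scale_x_continuous(breaks = d$step) +
    labs(x = "Variables selected", y = expression(LOOCV ~ Q^2),
         title = "Forward-selection random forest") +
    theme_minimal()
}

#' Plot a PERMANOVA effect-size decomposition
#'
#' Bar chart of single-covariate R^2 values; retained (significant,
#' non-redundant) covariates are highlighted and the combined model R^2 is
#' drawn as a dashed line.
#'
#' @param object A `gutage_effectsize` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gutage_effectsize
#' @export
autoplot.gutage_effectsize <- function(object, ...) {
  d <- object$table
  d$variable <- factor(d$variable, levels = rev(d$variable))
  ggplot(d, aes(x = .data$r2, y = .data$variable, fill = .data$kept)) +
    geom_col() +
    geom_vline(xintercept = object$combined_r2, linetype = "dashed") +
    scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                      name = "retained") +
    labs(x = expression(R^2), y = NULL,
         title = "PERMANOVA effect sizes",
         subtitle = sprintf("combined R2 of retained covariates = %.3f",
                            object$combined_r2)) +
    theme_minimal()
}

#' Plot within-group beta diversity
#'
#' Boxplots of the within-group pairwise dissimilarities per group.
#'
#' @param object A `gutage_beta` object from [intragroup_beta()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gutage_beta
#' @export
autoplot.gutage_beta <- function(object, ...) {
  ggplot(object$distances, aes(x = .data$group, y = .data$distance)) +
    geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    labs(x = NULL, y = "Within-group dissimilarity",
         title = "Intragroup beta diversity") +
    theme_minimal()
}

#' Plot an enterotype clustering
#'
#' Calinski-Harabasz index over the candidate cluster numbers, with the
#' chosen k marked.
#'
#' @param object A `gutage_enterotype` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gutage_enterotype
#' @export
autoplot.gutage_enterotype <- function(object, ...) {
  d <- tibble(k = as.integer(names(object$ch)), ch = unname(object$ch))
  ggplot(d, aes(x = .data$k, y = .data$ch)) +
    geom_line(color = "grey40") +
    geom_point(size = 2) +
    geom_point(data = d[d$k == object$k_opt, ], color = "#d95f02", size = 3) +
    scale_x_continuous(breaks = d$k) +
    labs(x = "Number of clusters k", y = "Calinski-Harabasz index",
         title = sprintf("Enterotype model selection (k_opt = %d)",
                         object$k_opt)) +
    theme_minimal()
}

#' Plot the simulation distribution of a mediation analysis
#'
#' Density of the quasi-Bayesian ACME draws with the point estimate and
#' percentile interval.
#'
#' @param object A `mediation_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  ggplot(object$draws, aes(x = .data$acme)) +
    geom_density(fill = "grey85") +
    geom_vline(xintercept = object$acme, color = "#d95f02") +
    geom_vline(xintercept = object$ci["acme", ], linetype = "dashed") +
    geom_vline(xintercept = 0, color = "grey40") +
    labs(x = "ACME", y = "Density",
         title = sprintf("ACME = %.3f, p = %.3f (%s)",
                         object$acme, object$p_mediation, object$direction)) +
    theme_minimal()
}
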