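#' Causal mediation analysis with treatment-mediator interaction
#'
#' Estimates how much of an exposure's effect on an outcome is transmitted
#' through a mediator, using the linear structural models
#' `m ~ x` (mediator model) and `y ~ x + m + x:m` (outcome model with
#' interaction). Effects are estimated by quasi-Bayesian simulation: `n_sims`
#' parameter vectors are drawn from the fitted models' asymptotic normal
#' distributions, potential outcomes are evaluated in closed form at
#' `treat_value` versus `control_value`, and the average causal mediation
#' effect (ACME), average direct effect (ADE) and total effect are averaged
#' over draws. With interaction the ACME and ADE are each averaged over the
#' two treatment arms, so ACME + ADE = total exactly. The mediation p-value
#' is the two-sided simulation p of the ACME; confidence intervals are
#' percentile intervals of the draws. Results are reproducible under a fixed
#' seed.
#'
#' For relative abundances a 0/1 treatment contrast is meaningless, so the
#' default contrast is one standard deviation of the exposure:
#' `control_value = mean(x)`, `treat_value = mean(x) + sd(x)`.
#'
#' @param x Exposure (e.g. MGS relative abundance).
#' @param m Mediator (e.g. serum metabolite).
#' @param y Outcome (e.g. age in years).
#' @param n_sims Number of quasi-Bayesian parameter draws.
#' @param seed Integer seed.
#' @param treat_value,control_value Exposure contrast; defaults to
#'   mean + 1 SD versus mean.
#' @param direction Label stored in the result (`"forward"` or
#'   `"inverse"`).
#' @param conf_level Confidence level of the percentile intervals.
#' @return Object of class `mediation_result` with point estimates `acme`,
#'   `ade`, `total`, `prop_mediated`, simulation p-values (`p_mediation`,
#'   `p_direct`, `p_total`), percentile `ci` (rows acme/ade/total), the
#'   draws, and metadata (`n`, `n_sims`, `direction`).
#' @export
mediate_interaction <- function(x, m, y, n_sims = 1000, seed = 1,
                                treat_value = NULL, control_value = NULL,
                                direction = "forward", conf_level = 0.95) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20) abort("mediation needs at least 20 complete cases")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0) {
    abort("constant exposure, mediator or outcome")
  }
  if (abs(cor(x, m)) > 0.999) {
    abort("exposure and mediator are collinear (|r| > 0.999)")
  }
  if (is.null(control_value)) control_value <- mean(x)
  if (is.null(treat_value)) treat_value <- mean(x) + sd(x)
  t1 <- treat_value; t0 <- control_value
  med_fit <- lm(m ~ x)
  out_fit <- lm(y ~ x * m)
  draws <- with_seed(seed, {
    md <- MASS::mvrnorm(n_sims, coef(med_fit), vcov(med_fit))
    od <- MASS::mvrnorm(n_sims, coef(out_fit), vcov(out_fit))
    list(md = md, od = od)
  })
  alpha_m <- draws$md[, 1]; a <- draws$md[, 2]
  cp <- draws$od[, "x"]; b <- draws$od[, "m"]; d <- draws$od[, "x:m"]
  delta <- t1 - t0
  # E[Y(t, M(t1)) - Y(t, M(t0))] = a * (b + d t) * delta, averaged over arms
  acme_draws <- a * (b + d * (t1 + t0) / 2) * delta
  # E[Y(t1, M(t)) - Y(t0, M(t))] = (c' + d (alpha_m + a t)) * delta
  ade_draws <- (cp + d * (alpha_m + a * (t1 + t0) / 2)) * delta
  total_draws <- acme_draws + ade_draws
  est <- function(v) mean(v)
  pval <- function(v) min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  ci <- function(v) quantile(v, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), names = FALSE)
  acme <- est(acme_draws); ade <- est(ade_draws); total <- est(total_draws)
  structure(list(
    acme = acme, ade = ade, total = total,
    prop_mediated = if (abs(total) < 1e-12) NA_real_ else acme / total,
    p_mediation = pval(acme_draws), p_direct = pval(ade_draws),
    p_total = pval(total_draws),
    ci = rbind(acme = ci(acme_draws), ade = ci(ade_draws),
               total = ci(total_draws)),
    draws = tibble(acme = acme_draws, ade = ade_draws, total = total_draws),
    treat_value = t1, control_value = t0,
    n = n, n_sims = n_sims, seed = seed, direction = direction,
    conf_level = conf_level), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation analysis (%s), n = %d, %d sims\n",
              x$direction, x$n, x$n_sims))
  cat(sprintf("  ACME  %8.4f [%.4f, %.4f]  p = %.4f\n",
              x$acme, x$ci["acme", 1], x$ci["acme", 2], x$p_mediation))
  cat(sprintf("  ADE   %8.4f [%.4f, %.4f]  p = %.4f\n",
              x$ade, x$ci["ade", 1], x$ci["ade", 2], x$p_direct))
  cat(sprintf("  Total %8.4f   prop. mediated = %.3f\n",
              x$total, x$prop_mediated))
  invisible(x)
}

#' Bidirectional mediation screen
#'
#' For every (microbe, metabolite) pair whose Spearman association passes
#' the prefilter, runs the mediation analysis in both causal orientations:
#'
#' * forward: microbe -> metabolite -> age
#'   (`mediate_interaction(x = microbe, m = metabolite, y = age)`);
#' * inverse: microbe -> age -> metabolite (mediator and outcome swapped).
#'
#' A linkage passes when the forward mediation is significant and the
#' inverse is not (`p_forward < alpha` and `p_inverse > alpha`), the pattern
#' expected when the microbe influences age through the metabolite rather
#' than the metabolite merely tracking age.
#'
#' @param microbes Abundance tibble of microbial features (MGSs).
#' @param metabolites Abundance tibble of metabolite intensities sharing the
#'   sample columns of `microbes`.
#' @param age Numeric vector of ages, aligned with the shared samples (or
#'   named by sample id).
#' @param prefilter_alpha Spearman screening threshold.
#' @param prefilter_on `"p"` (per-pair p-value, default) or `"q"` (BH
#'   q-value over all pairs).
#' @param alpha Significance threshold of the mediation filter.
#' @param n_sims,seed Passed to [mediate_interaction()].
#' @return Tibble of class `gutage_linkages` with one row per screened pair:
#'   `microbe`, `metabolite`, `rho`, `p_spearman`, `acme_forward`,
#'   `p_forward`, `acme_inverse`, `p_inverse`, `passes`.
#' @export
bidirectional_screen <- function(microbes, metabolites, age,
                                 prefilter_alpha = 0.05,
                                 prefilter_on = c("p", "q"),
                                 alpha = 0.05, n_sims = 1000, seed = 1) {
  prefilter_on <- match.arg(prefilter_on)
  mm <- abundance_matrix(microbes)
  mt <- abundance_matrix(metabolites)
  shared <- intersect(colnames(mm), colnames(mt))
  if (length(shared) < 20) abort("need at least 20 shared samples")
  mm <- mm[, shared, drop = FALSE]
  mt <- mt[, shared, drop = FALSE]
  if (!is.null(names(age))) {
    if (!all(shared %in% names(age))) abort("age missing some sample ids")
    age <- age[shared]
  }
  if (length(age) != length(shared)) abort("age must match the shared samples")
  assoc <- correlate_features(microbes, metabolites)
  crit <- if (prefilter_on == "p") assoc$p else assoc$q
  survivors <- assoc[crit < prefilter_alpha, ]
  out <- purrr::map(seq_len(nrow(survivors)), function(i) {
    mb <- survivors$feature_a[i]; met <- survivors$feature_b[i]
    fwd <- mediate_interaction(mm[mb, ], mt[met, ], age,
                               n_sims = n_sims, seed = seed,
                               direction = "forward")
    inv <- mediate_interaction(mm[mb, ], age, mt[met, ],
                               n_sims = n_sims, seed = seed,
                               direction = "inverse")
    tibble(microbe = mb, metabolite = met,
           rho = survivors$rho[i], p_spearman = survivors$p[i],
           acme_forward = fwd$acme, p_forward = fwd$p_mediation,
           acme_inverse = inv$acme, p_inverse = inv$p_mediation,
           passes = fwd$p_mediation < alpha & inv$p_mediation > alpha)
  }) |> list_rbind()
  if (nrow(out) == 0) {
    out <- tibble(microbe = character(), metabolite = character(),
                  rho = numeric(), p_spearman = numeric(),
                  acme_forward = numeric(), p_forward = numeric(),
                  acme_inverse = numeric(), p_inverse = numeric(),
                  passes = logical())
  }
  class(out) <- c("gutage_linkages", class(out))
  out
}
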