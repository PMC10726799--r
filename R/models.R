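#' Cross-validated predictive Q-squared
#'
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: the fraction of the
#' response variance (about its mean) captured by held-out predictions.
#' Unlike an in-sample R^2 it can be negative — a model predicting worse than
#' the response mean.
#'
#' @param y Observed values (non-constant, length >= 2).
#' @param yhat Predictions of the same length.
#' @return Q^2 (<= 1, possibly negative).
#' @examples
#' q2_score(1:10, 1:10)            # 1
#' q2_score(1:10, rep(5.5, 10))    # 0
#' @export
q2_score <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("y and yhat must have equal length")
  if (length(y) < 2) abort("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("constant response has no variance to explain")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Leave-one-out random-forest predictions
#'
#' For each sample, a regression forest is trained on all other samples
#' (features restricted to `variables`) and predicts the held-out response.
#' Fold seeds are derived deterministically as `seed + fold index`, so
#' repeated calls are bit-identical.
#'
#' @param x Feature matrix or data frame (samples x features, named
#'   columns).
#' @param y Numeric response aligned with the rows of `x`.
#' @param variables Character vector of feature names to use.
#' @param n_trees Trees per forest (default 500).
#' @param seed Base integer seed.
#' @param mtry Variables tried at each split; default `max(1, floor(p/3))`
#'   (regression-forest convention).
#' @return Numeric vector of held-out predictions, one per sample.
#' @export
loocv_predict <- function(x, y, variables, n_trees = 500, seed = 1,
                          mtry = NULL) {
  x <- as.data.frame(x)
  if (!all(variables %in% names(x))) {
    abort(paste0("variable(s) not in x: ",
                 paste(setdiff(variables, names(x)), collapse = ", ")))
  }
  if (length(variables) < 1) abort("need at least one variable")
  n <- nrow(x)
  if (n < 10) abort("leave-one-out needs at least 10 samples")
  xv <- x[, variables, drop = FALSE]
  if (is.null(mtry)) mtry <- max(1, floor(length(variables) / 3))
  vapply(seq_len(n), function(i) {
    with_seed(seed + i, {
      fit <- randomForest::randomForest(
        x = xv[-i, , drop = FALSE], y = y[-i],
        ntree = n_trees, mtry = mtry)
      unname(predict(fit, xv[i, , drop = FALSE]))
    })
  }, numeric(1))
}

#' Forward-selection random forest driven by Q-squared
#'
#' Iterative variable selection for predicting a metabolite from MGS
#' abundances:
#'
#' 1. fit one forest on all candidates; the first selected variable is the
#'    one with maximal permutation importance (increase in MSE);
#' 2. at each later step, every unselected variable is tried in combination
#'    with the current set, scored by leave-one-out Q^2
#'    ([loocv_predict()] + [q2_score()]); the best addition is kept if it
#'    improves Q^2 by more than `tol`;
#' 3. selection stops when Q^2 no longer increases.
#'
#' The returned trajectory is strictly increasing by construction; the final
#' LOOCV Q^2 times 100 is the "variance explained" reported for a
#' metabolite.
#'
#' @param x Feature matrix or data frame (samples x candidates, >= 2
#'   candidates).
#' @param y Numeric response.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (forests and folds derive their seeds from it).
#' @param tol Minimal Q^2 improvement counted as an increase.
#' @param first One of `"importance"` (default: highest %IncMSE of a forest
#'   on all candidates) or `"q2"` (best single-variable LOOCV Q^2).
#' @param max_vars Stop after this many selected variables (default
#'   unlimited).
#' @param mtry Passed to [loocv_predict()].
#' @return An object of class `rf_selection` with elements `selected`,
#'   `q2_trajectory`, `importances` (tibble), `final_q2`, `n`, and
#'   `predictions` (LOOCV predictions of the final model).
#' @export
forward_select_rf <- function(x, y, n_trees = 500, seed = 1, tol = 1e-6,
                              first = c("importance", "q2"), mtry = NULL,
                              max_vars = Inf) {
  first <- match.arg(first)
  x <- as.data.frame(x)
  p <- ncol(x)
  if (p < 2) abort("need at least 2 candidate variables")
  imp_fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(imp_fit, type = 1, scale = TRUE)[, 1]
  importances <- tibble(variable = names(imp), inc_mse = unname(imp)) |>
    arrange(desc(.data$inc_mse))
  start <- if (first == "importance") {
    importances$variable[1]
  } else {
    scores <- vapply(names(x), function(v) {
      q2_score(y, loocv_predict(x, y, v, n_trees, seed, mtry))
    }, numeric(1))
    names(which.max(scores))
  }
  selected <- start
  best_q2 <- q2_score(y, loocv_predict(x, y, selected, n_trees, seed, mtry))
  trajectory <- best_q2
  preds <- loocv_predict(x, y, selected, n_trees, seed, mtry)
  repeat {
    rest <- setdiff(names(x), selected)
    if (length(rest) == 0 || length(selected) >= max_vars) break
    trial <- purrr::map(rest, function(v) {
      ph <- loocv_predict(x, y, c(selected, v), n_trees, seed, mtry)
      list(variable = v, q2 = q2_score(y, ph), predictions = ph)
    })
    q2s <- map_dbl(trial, "q2")
    j <- which.max(q2s)
    if (q2s[j] <= best_q2 + tol) break
    selected <- c(selected, trial[[j]]$variable)
    best_q2 <- q2s[j]
    trajectory <- c(trajectory, best_q2)
    preds <- trial[[j]]$predictions
  }
  structure(list(selected = selected, q2_trajectory = trajectory,
                 importances = importances, final_q2 = best_q2,
                 n = length(y), n_trees = n_trees, seed = seed,
                 predictions = preds),
            class = "rf_selection")
}

#' @export
print.rf_selection <- function(x, ...) {
  cat("Forward-selection random forest\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  final LOOCV Q2 = %.4f (variance explained %.2f%%)\n",
              x$final_q2, 100 * x$final_q2))
  invisible(x)
}

#' Power of a two-sided correlation test
#'
#' Power to reject rho = 0 at effect size `r` and sample size `n`, via the
#' Fisher z approximation: with `z = atanh(|r|)` and critical value
#' `z_crit = qnorm(1 - alpha/2)`,
#' `power = pnorm(sqrt(n-3) * z - z_crit) + pnorm(-sqrt(n-3) * z - z_crit)`.
#' At `r = 0` this reduces to `alpha` exactly.
#'
#' @param r Population correlation, |r| < 1.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @return Power in \[alpha, 1\].
#' @examples
#' correlation_power(0.3, 85)
#' @export
correlation_power <- function(r, n, alpha = 0.05) {
  if (any(abs(r) >= 1)) abort("|r| must be below 1")
  if (any(n < 4)) abort("need n >= 4")
  z <- atanh(abs(r)) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  power <- pnorm(z - zc) + pnorm(-z - zc)
  # at r = 0 the rejection probability is the size of the test by definition
  power[r == 0] <- alpha
  power
}
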