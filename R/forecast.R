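#' SARIMA order search grids
#'
#' Candidate `(p,d,q)(P,D,Q)` orders for AIC selection. `"full"` covers
#' p,q,P,Q in 0..2 and d,D in 0..1 (324 models); `"small"` restricts every
#' order to 0..1 (64 models), which is the default search space of the
#' bundled pipeline and of the multi-seed simulation studies — the selected
#' models on series of this length almost always fall inside it, at a
#' fraction of the cost.
#'
#' @param preset `"full"` or `"small"`.
#' @return Data frame with columns p, d, q, P, D, Q.
#' @export
sarima_order_grid <- function(preset = c("full", "small")) {
  preset <- match.arg(preset)
  r <- if (preset == "full") 0:2 else 0:1
  expand.grid(p = r, d = 0:1, q = r, P = if (preset == "full") 0:2 else 0:1,
              D = 0:1, Q = if (preset == "full") 0:2 else 0:1)
}

arima_try <- function(y, order, seasonal, xreg) {
  fit <- suppressWarnings(tryCatch(
    stats::arima(y, order = order,
                 seasonal = list(order = seasonal, period = 12),
                 xreg = xreg, method = "ML",
                 optim.control = list(maxit = 200)),
    error = function(e) e))
  # predict.Arima re-evaluates the call's xreg symbol in the caller's frame;
  # store the value itself so prediction works anywhere
  if (!inherits(fit, "error")) fit$call$xreg <- xreg
  fit
}

#' Fit a seasonal ARIMA model with AIC order selection
#'
#' Fits every candidate in `grid` by maximum likelihood with seasonal period
#' 12 (and optional exogenous covariates) and keeps the lowest-AIC fit.
#' Selection is deterministic given the data and grid: ties and grid order
#' are resolved by first occurrence.
#'
#' @param y Training series: a `monthly_series`, `ts`, or numeric vector
#'   (>= 24 months).
#' @param xreg Optional numeric matrix of exogenous covariates aligned with
#'   `y` (e.g. monthly symptom-expression prevalences).
#' @param grid Order grid, see [sarima_order_grid()].
#' @return A `sarima_fit`: the `arima` fit plus `order`, `seasonal`, `aic`.
#' @export
fit_sarima <- function(y, xreg = NULL, grid = sarima_order_grid("full")) {
  if (inherits(y, "monthly_series")) y <- as.ts(y)
  if (!stats::is.ts(y)) y <- stats::ts(y, frequency = 12)
  if (length(y) < 24L) stop("training series must cover at least 24 months")
  if (stats::sd(y) == 0) {
    # degenerate constant process: the likelihood is singular for every
    # candidate, and the only sensible forecast is the constant itself
    return(structure(list(fit = NULL, order = c(p = 0, d = 0, q = 0),
                          seasonal = c(P = 0, D = 0, Q = 0), aic = NA_real_,
                          has_xreg = FALSE, constant = y[1L]),
                     class = "sarima_fit"))
  }
  if (!is.null(xreg)) {
    xreg <- as.matrix(xreg)
    if (nrow(xreg) != length(y)) stop("xreg must align with the series")
  }
  best <- NULL; best_aic <- Inf; best_row <- NULL
  errs <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- arima_try(y, c(g$p, g$d, g$q), c(g$P, g$D, g$Q), xreg)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    if (is.finite(fit$aic) && fit$aic < best_aic) {
      best <- fit; best_aic <- fit$aic; best_row <- g
    }
  }
  if (is.null(best))
    stop(sprintf("no SARIMA candidate converged; last errors: %s",
                 paste(utils::tail(unique(errs), 3L), collapse = " | ")))
  structure(list(fit = best, order = unlist(best_row[c("p", "d", "q")]),
                 seasonal = unlist(best_row[c("P", "D", "Q")]),
                 aic = best_aic, has_xreg = !is.null(xreg)),
            class = "sarima_fit")
}

#' @exportS3Method base::print
print.sarima_fit <- function(x, ...) {
  cat(sprintf("<sarima_fit> (%d,%d,%d)(%d,%d,%d)[12]%s, AIC %.2f\n",
              x$order[1], x$order[2], x$order[3], x$seasonal[1],
              x$seasonal[2], x$seasonal[3],
              if (x$has_xreg) " + xreg" else "", x$aic))
  invisible(x)
}

#' Forecast from a fitted SARIMA model
#'
#' @param object A `sarima_fit`.
#' @param n_ahead Months ahead.
#' @param newxreg Covariate values for the forecast months (required when
#'   the model was fit with covariates).
#' @param ... Unused.
#' @return Numeric vector of point forecasts.
#' @export
predict.sarima_fit <- function(object, n_ahead = 1L, newxreg = NULL, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, n_ahead))
  p <- stats::predict(object$fit, n.ahead = n_ahead, newxreg = newxreg)
  as.numeric(p$pred)
}

# forecast fallback chain for short or ill-conditioned training windows:
# simpler and simpler SARIMA orders, then a seasonal-naive forecast
fallback_forecast <- function(y, h, xreg, newxreg) {
  chain <- list(list(c(0, 1, 1), c(0, 1, 1)),
                list(c(1, 0, 0), c(1, 0, 0)),
                list(c(0, 1, 0), c(0, 0, 0)))
  for (cand in chain) {
    fit <- arima_try(y, cand[[1]], cand[[2]], xreg)
    if (!inherits(fit, "error")) {
      p <- tryCatch(stats::predict(fit, n.ahead = h, newxreg = newxreg),
                    error = function(e) NULL)
      if (!is.null(p) && all(is.finite(p$pred))) return(as.numeric(p$pred))
    }
  }
  n <- length(y)
  vapply(seq_len(h), function(j) {
    k <- n + j - 12L
    if (k >= 1L) y[k] else y[n]
  }, 0)
}

#' Anchored k-fold cross-validated SARIMA predictions
#'
#' Splits the non-anchor months into `k` contiguous blocks; each block is
#' predicted exactly once by a model trained on every month that precedes it
#' (which always includes the anchor year), and the predictions are pooled.
#' Orders are AIC-selected either once on the full series
#' (`order_search = "once"`, the default: selection is then shared by all
#' folds and cheap) or independently on each fold's training window
#' (`"per_fold"`). If a fold's refit does not converge, a chain of simpler
#' seasonal models (and finally a seasonal-naive rule) supplies the
#' forecast, so every month is always predicted.
#'
#' Exogenous covariates follow a nowcasting contract: the observed covariate
#' values of the test months are supplied to the forecast. `exog_lag` shifts
#' the covariates forward in time by that many months (covariate value at
#' `t - exog_lag` predicts month `t`), the natural choice when the lag scan
#' shows social-media language leading consultations. Because symptom
#' prevalence series measure overlapping constructs and are strongly
#' correlated, `exog_combine = "pc1"` replaces several covariates by the
#' first principal component of their standardized (shifted) values, which
#' stabilizes the regression part of the model; `"none"` keeps the raw
#' columns.
#'
#' @param consult Consultation `monthly_series` (the forecast target).
#' @param exog Optional covariate matrix or named list of `monthly_series`
#'   aligned with `consult`.
#' @param k Number of folds (default 10).
#' @param anchor Months always kept in training (default 12, the first
#'   year).
#' @param grid Order grid (see [sarima_order_grid()]).
#' @param order_search `"once"` or `"per_fold"`.
#' @param exog_lag Nonnegative months by which covariates lead the target;
#'   scalar or one value per covariate column.
#' @param exog_combine `"none"` (raw covariate columns) or `"pc1"` (first
#'   principal component of the standardized, shifted covariates).
#' @return A `prediction_set`: data frame `month`, `actual`, `predicted`
#'   with attributes `model_id` and `folds`.
#' @export
cv_predict <- function(consult, exog = NULL, k = 10L, anchor = 12L,
                       grid = sarima_order_grid("full"),
                       order_search = c("once", "per_fold"), exog_lag = 0L,
                       exog_combine = c("none", "pc1")) {
  order_search <- match.arg(order_search)
  exog_combine <- match.arg(exog_combine)
  stopifnot(inherits(consult, "monthly_series"))
  n <- nrow(consult)
  if (k < 2L) stop("k must be >= 2")
  if (n < anchor + k) stop("series too short: need at least anchor + k months")
  y <- as.ts(consult)
  X <- NULL
  if (!is.null(exog)) {
    if (is.list(exog) && !is.data.frame(exog)) {
      X <- do.call(cbind, lapply(exog, function(s) {
        stopifnot(identical(s$month, consult$month))
        s$value
      }))
      colnames(X) <- names(exog)
    } else X <- as.matrix(exog)
    if (nrow(X) != n) stop("exog must align with the consultation series")
    if (anyNA(X)) stop("exog contains missing values; fill before forecasting")
    exog_lag <- rep_len(as.integer(exog_lag), ncol(X))
    for (j in seq_len(ncol(X))) {
      l <- exog_lag[j]
      if (l > 0L) X[, j] <- c(rep(X[1L, j], l), X[seq_len(n - l), j])
    }
    if (exog_combine == "pc1" && ncol(X) > 1L) {
      X <- matrix(stats::prcomp(X, center = TRUE, scale. = TRUE)$x[, 1L],
                  ncol = 1L, dimnames = list(NULL, "exog_pc1"))
    }
  }
  m <- n - anchor
  bounds <- floor(seq(0L, m, length.out = k + 1L))
  sel_grid <- grid
  if (order_search == "once") {
    sel <- fit_sarima(y, xreg = X, grid = grid)
    sel_grid <- data.frame(p = sel$order[1], d = sel$order[2],
                           q = sel$order[3], P = sel$seasonal[1],
                           D = sel$seasonal[2], Q = sel$seasonal[3])
  }
  months <- consult$month
  out <- vector("list", k)
  for (f in seq_len(k)) {
    test <- anchor + seq.int(bounds[f] + 1L, bounds[f + 1L])
    train <- seq_len(min(test) - 1L)
    ytr <- stats::ts(y[train], frequency = 12)
    xtr <- if (is.null(X)) NULL else X[train, , drop = FALSE]
    xte <- if (is.null(X)) NULL else X[test, , drop = FALSE]
    pred <- tryCatch({
      fit <- fit_sarima(ytr, xreg = xtr, grid = sel_grid)
      p <- predict(fit, n_ahead = length(test), newxreg = xte)
      if (!all(is.finite(p))) stop("non-finite forecast")
      p
    }, error = function(e) fallback_forecast(y[train], length(test), xtr, xte))
    out[[f]] <- data.frame(month = months[test], actual = y[test],
                           predicted = pred, fold = f,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, anchor = anchor, k = k,
            class = c("prediction_set", "data.frame"))
}

#' Forecast evaluation metrics
#'
#' Pearson's r between pooled predictions and actuals, mean absolute error
#' (MAE), and symmetric mean absolute percentage error
#' `SMAPE = 100 * mean(|y - x| / ((|y| + |x|) / 2))`, bounded in `[0, 100]`,
#' with a term defined as 0 when both actual and prediction are 0.
#'
#' @param pred A `prediction_set`, or a data frame with `actual` and
#'   `predicted` columns.
#' @return A `metrics_report`: `pearson_r`, `mae`, `smape`, `n`,
#'   `r_defined` (FALSE when either side has zero variance).
#' @export
prediction_metrics <- function(pred) {
  x <- pred$actual; y <- pred$predicted
  if (length(x) < 3L) stop("need at least 3 months of predictions")
  r_defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  r <- if (r_defined) stats::cor(x, y) else NA_real_
  ae <- abs(y - x)
  denom <- (abs(x) + abs(y)) / 2
  term <- ifelse(denom == 0, 0, ae / denom)
  structure(list(pearson_r = r, mae = mean(ae), smape = 100 * mean(term),
                 n = length(x), r_defined = r_defined),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("Pearson's r = %.3f | MAE = %.3f | SMAPE = %.2f (n = %d)\n",
              x$pearson_r, x$mae, x$smape, x$n))
  invisible(x)
}

#' Permutation null for pooled predictions
#'
#' Shuffles the predictions over months `n_perm` times, recomputing r and
#' SMAPE each time; reports the null means and the fraction of permutations
#' that beat the unpermuted predictions (strictly higher r AND strictly
#' lower SMAPE).
#'
#' @param pred A `prediction_set` or data frame with `actual`/`predicted`.
#' @param n_perm Number of permutations (default 1000; below 100 warns).
#' @param seed Seed for the shuffles.
#' @return A `permutation_summary`: `mean_r`, `mean_smape`, `prob_better`,
#'   plus the null vectors `null_r`, `null_smape`.
#' @export
permutation_test <- function(pred, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  x <- pred$actual; y <- pred$predicted
  n <- length(x)
  obs <- prediction_metrics(pred)
  denom0 <- function(a, b) { d <- (abs(a) + abs(b)) / 2
    ifelse(d == 0, 0, abs(b - a) / d) }
  withr::with_seed(seed, {
    null_r <- numeric(n_perm); null_s <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      yp <- y[sample.int(n)]
      null_r[i] <- if (obs$r_defined) stats::cor(x, yp) else NA_real_
      null_s[i] <- 100 * mean(denom0(x, yp))
    }
  })
  prob_better <- mean(null_r > obs$pearson_r & null_s < obs$smape)
  structure(list(mean_r = mean(null_r), mean_smape = mean(null_s),
                 prob_better = prob_better, n_perm = n_perm,
                 null_r = null_r, null_smape = null_s, observed = obs),
            class = "permutation_summary")
}

#' @exportS3Method base::print
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    "%d permutations: mean r = %.3f, mean SMAPE = %.2f, P(better) = %.4f\n",
    x$n_perm, x$mean_r, x$mean_smape, x$prob_better))
  invisible(x)
}

#' Test for the difference of two dependent overlapping correlations
#'
#' Williams/Steiger t test of whether `cor(actual, pred0)` differs from
#' `cor(actual, pred1)`, accounting for `cor(pred0, pred1)` — the standard
#' comparison of two correlations that share a common variable. Positive t
#' means the first prediction series correlates more strongly with the
#' actuals.
#'
#' @param actual,pred0,pred1 Aligned numeric vectors (n >= 10).
#' @return A `dependent_correlation_test`: `t`, `p_value`, `df`, and the
#'   three correlations.
#' @export
dependent_overlap_test <- function(actual, pred0, pred1) {
  n <- length(actual)
  if (length(pred0) != n || length(pred1) != n) stop("inputs must align")
  if (n < 10L) stop("need at least 10 months")
  if (stats::sd(actual) == 0 || stats::sd(pred0) == 0 || stats::sd(pred1) == 0)
    stop("zero-variance input")
  r01 <- stats::cor(actual, pred0)
  r02 <- stats::cor(actual, pred1)
  r12 <- stats::cor(pred0, pred1)
  if (isTRUE(all.equal(pred0, pred1)) || r01 == r02) {
    t <- 0; p <- 1
  } else {
    detR <- 1 - r01^2 - r02^2 - r12^2 + 2 * r01 * r02 * r12
    rbar <- (r01 + r02) / 2
    t <- (r01 - r02) *
      sqrt(((n - 1) * (1 + r12)) /
             (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
    p <- 2 * stats::pt(-abs(t), n - 3)
  }
  structure(list(t = t, p_value = p, df = n - 3L,
                 r_actual_pred0 = r01, r_actual_pred1 = r02,
                 r_pred0_pred1 = r12),
            class = "dependent_correlation_test")
}

#' @exportS3Method base::print
print.dependent_correlation_test <- function(x, ...) {
  cat(sprintf(
    "Dependent overlapping correlation: t = %.2f, df = %d, p = %.4g\n",
    x$t, x$df, x$p_value))
  invisible(x)
}

#' Relative improvement between two metric reports
#'
#' The comparison arithmetic used to contrast a baseline and an augmented
#' model: percentage gain in Pearson's r and percentage reduction in SMAPE.
#'
#' @param m0,m1 `metrics_report`s (or lists with `pearson_r` and `smape`)
#'   for the baseline and augmented model.
#' @return List with `delta_r_percent` (`100 * (r1 - r0) / r0`) and
#'   `delta_error_percent` (`100 * (smape0 - smape1) / smape0`).
#' @examples
#' compare_metrics(list(pearson_r = 0.76, smape = 22.64),
#'                 list(pearson_r = 0.86, smape = 13.30))
#' @export
compare_metrics <- function(m0, m1) {
  list(delta_r_percent = 100 * (m1$pearson_r - m0$pearson_r) / m0$pearson_r,
       delta_error_percent = 100 * (m0$smape - m1$smape) / m0$smape)
}

#' Full comparison of baseline and covariate-augmented predictions
#'
#' Bundles the metrics of both models, the relative-improvement arithmetic,
#' the dependent-overlapping-correlation test (signed so that negative t
#' favors the augmented model, matching the baseline-minus-augmented
#' convention), and the permutation null of each model.
#'
#' @param pred0,pred1 `prediction_set`s over the same months (baseline,
#'   augmented).
#' @param n_perm Permutations for the null (default 1000).
#' @param seed Seed for the permutations.
#' @return A `model_comparison`.
#' @export
compare_models <- function(pred0, pred1, n_perm = 1000L, seed = 1L) {
  if (!identical(pred0$month, pred1$month))
    stop("prediction sets must cover the same months")
  m0 <- prediction_metrics(pred0)
  m1 <- prediction_metrics(pred1)
  deltas <- compare_metrics(m0, m1)
  steiger <- dependent_overlap_test(pred0$actual, pred0$predicted,
                                    pred1$predicted)
  structure(list(metrics_m0 = m0, metrics_m1 = m1,
                 delta_r_percent = deltas$delta_r_percent,
                 delta_error_percent = deltas$delta_error_percent,
                 steiger = steiger,
                 permutation_m0 = permutation_test(pred0, n_perm, seed),
                 permutation_m1 = permutation_test(pred1, n_perm, seed)),
            class = "model_comparison")
}

#' @exportS3Method base::print
print.model_comparison <- function(x, ...) {
  cat("Model M0 (baseline):   "); print(x$metrics_m0)
  cat("Model M1 (+ social):   "); print(x$metrics_m1)
  cat(sprintf("Relative improvement:  r +%.2f%%, SMAPE -%.2f%%\n",
              x$delta_r_percent, x$delta_error_percent))
  print(x$steiger)
  cat("Permutation null (M1): "); print(x$permutation_m1)
  invisible(x)
}

#' @export
plot.prediction_set <- function(x, ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$actual, type = "l", lwd = 2, xaxt = "n",
                 xlab = "month", ylab = "consultation rate (% enrolled)", ...)
  graphics::lines(idx, x$predicted, col = 2, lty = 2)
  at <- idx[seq(1, length(idx), by = max(1L, length(idx) %/% 8L))]
  graphics::axis(1, at = at, labels = x$month[at], las = 2, cex.axis = 0.7)
  graphics::legend("topleft", c("actual", "predicted"), col = c(1, 2),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
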