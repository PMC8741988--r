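#' Train a per-outcome n-gram symptom classifier
#'
#' Fits a linear (max-margin) support vector machine on n-gram counts
#' (n = 1..`max_n`) to separate symptomatic from control documents — the
#' transfer-classifier design in which the positive class comes from an
#' outcome-specific community and the negative class from a general control
#' sample. Held-out accuracy is estimated on a stratified split before the
#' final model is refit on all documents. The decision threshold is the
#' SVM's natural zero margin; no calibration is applied.
#'
#' @param positives,negatives Character vectors of raw documents.
#' @param outcome Outcome name carried by the classifier.
#' @param max_n Largest n-gram order (default 3).
#' @param min_df Drop n-grams seen in fewer documents than this (default 2).
#' @param cost SVM cost parameter `C`.
#' @param sublinear Use `1 + log(count)` term weighting.
#' @param holdout Fraction held out per class for the accuracy estimate.
#' @param seed Seed for the stratified split (training itself is
#'   deterministic given the data).
#' @return An `outcome_classifier` with fields `outcome`, `vocabulary`,
#'   `heldout_accuracy`, and the linear weights used by [predict] and
#'   [label_posts()].
#' @export
train_classifier <- function(positives, negatives, outcome = "outcome",
                             max_n = 3L, min_df = 2L, cost = 1,
                             sublinear = FALSE, holdout = 0.2, seed = 1L) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must be non-empty")
  docs <- c(positives, negatives)
  y <- factor(rep(c(1L, 0L), c(length(positives), length(negatives))),
              levels = c(0L, 1L))
  test_idx <- withr::with_seed(seed, c(
    sample(seq_along(positives), round(holdout * length(positives))),
    length(positives) + sample(seq_along(negatives),
                               round(holdout * length(negatives)))))
  fit_svm <- function(idx) {
    d <- build_dtm(docs[idx], max_n = max_n, min_df = min_df,
                   sublinear = sublinear)
    ysub <- y[idx]
    if (length(unique(ysub)) < 2L) stop("single-class input")
    fit <- e1071::svm(d$matrix, ysub, kernel = "linear", cost = cost,
                      scale = FALSE)
    # flatten to an explicit linear decision function and orient it so that
    # a positive margin means the symptomatic class
    sv <- fit$SV
    if (inherits(sv, "matrix.csr")) {
      # e1071 hands support vectors back in compressed-row form
      dims <- attr(sv, "dimension")
      ia <- attr(sv, "ia")
      sv <- Matrix::sparseMatrix(i = rep.int(seq_len(dims[1L]), diff(ia)),
                                 j = attr(sv, "ja"), x = attr(sv, "ra"),
                                 dims = dims)
    }
    w <- as.numeric(Matrix::crossprod(fit$coefs, sv))
    b <- -fit$rho
    dec <- as.numeric(d$matrix %*% w) + b
    if (mean(dec[ysub == "1"]) < mean(dec[ysub == "0"])) { w <- -w; b <- -b }
    list(w = w, b = b, vocabulary = d$vocabulary)
  }
  acc <- NA_real_
  if (length(test_idx) > 0L) {
    m <- fit_svm(setdiff(seq_along(docs), test_idx))
    dtest <- build_dtm(docs[test_idx], max_n = max_n,
                       vocabulary = m$vocabulary, sublinear = sublinear)
    lab <- as.integer((as.numeric(dtest$matrix %*% m$w) + m$b) > 0)
    acc <- mean(lab == as.integer(as.character(y[test_idx])))
  }
  final <- fit_svm(seq_along(docs))
  structure(list(outcome = outcome, vocabulary = final$vocabulary,
                 w = final$w, b = final$b, max_n = max_n,
                 sublinear = sublinear, cost = cost,
                 heldout_accuracy = acc,
                 n_pos = length(positives), n_neg = length(negatives)),
            class = "outcome_classifier")
}

#' @exportS3Method base::print
print.outcome_classifier <- function(x, ...) {
  cat(sprintf(
    "<outcome_classifier: %s> %d n-gram features (n<=%d), held-out accuracy %.3f\n",
    x$outcome, length(x$vocabulary), x$max_n, x$heldout_accuracy))
  invisible(x)
}

#' Predict symptomatic labels or margins for documents
#'
#' @param object An `outcome_classifier`.
#' @param newdata Character vector of raw documents.
#' @param type `"class"` for 0/1 labels (zero-margin threshold) or
#'   `"decision"` for signed margins.
#' @param chunk Documents processed per block (memory control).
#' @param ... Unused.
#' @return Integer labels or numeric decision values.
#' @export
predict.outcome_classifier <- function(object, newdata,
                                       type = c("class", "decision"),
                                       chunk = 5000L, ...) {
  type <- match.arg(type)
  n <- length(newdata)
  dec <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d <- build_dtm(newdata[idx], max_n = object$max_n,
                   vocabulary = object$vocabulary,
                   sublinear = object$sublinear)
    dec[idx] <- as.numeric(d$matrix %*% object$w) + object$b
  }
  if (type == "decision") dec else as.integer(dec > 0)
}

#' Label a post stream with one or more outcome classifiers
#'
#' Adds an integer column `label_<outcome>` per classifier. Deterministic and
#' idempotent: relabeling overwrites with identical values.
#'
#' @param classifiers An `outcome_classifier` or (named) list of them.
#' @param posts A `post_stream`.
#' @return The stream with label columns added.
#' @export
label_posts <- function(classifiers, posts) {
  if (inherits(classifiers, "outcome_classifier"))
    classifiers <- list(classifiers)
  for (clf in classifiers)
    posts[[paste0("label_", clf$outcome)]] <- predict(clf, posts$text)
  posts
}

#' Monthly prevalence of a labeled outcome
#'
#' Share of each month's posts labeled 1 for `outcome`. Months inside the
#' stream's configured range with zero posts yield `NA` with a warning
#' (interpolation is deferred to the series-building stage).
#'
#' @param posts A labeled `post_stream` (see [label_posts()]).
#' @param outcome Outcome name whose `label_<outcome>` column is used.
#' @param months Optional month range; defaults to the stream's.
#' @return A `monthly_series` of kind `prevalence` with values in `[0, 1]`.
#' @export
monthly_prevalence <- function(posts, outcome, months = NULL) {
  col <- paste0("label_", outcome)
  if (is.null(posts[[col]]))
    stop(sprintf("posts carry no '%s' labels; run label_posts() first", outcome))
  if (is.null(months)) months <- attr(posts, "months")
  mlab <- format(posts$timestamp, "%Y-%m")
  if (is.null(months)) months <- sort(unique(mlab))
  agg <- tapply(posts[[col]], mlab, mean)
  v <- as.numeric(agg[months])
  if (anyNA(v))
    warning(sprintf("%d month(s) with zero posts; prevalence set missing",
                    sum(is.na(v))))
  monthly_series(months, v, "prevalence")
}
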