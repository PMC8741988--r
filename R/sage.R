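#' Fit a Sparse Additive Generative Model (SAGE) contrast
#'
#' Models the target corpus's n-gram distribution as a sparse deviation from
#' a background corpus: `p(w) = exp(m_w + eta_w) / Z` where `m` is the log
#' of the (smoothed) background relative frequencies and `eta` is a
#' regularized per-term deviation. Positive `eta` marks terms saliently
#' over-used in the target corpus, negative `eta` terms under-used.
#'
#' The penalized log-likelihood
#' `sum_w c_w eta_w - C log sum_w exp(m_w + eta_w) - penalty(eta)`
#' (with `c` the target counts and `C` their total) is maximized by a damped
#' diagonal proximal-Newton scheme; convergence requires the largest
#' coordinate change to fall below `tol` (default 1e-6) within `max_iter`
#' iterations, otherwise an error carries the last iterate.
#'
#' Regularization:
#' * `reg = NULL` (default): self-tuned sparsity. Each term carries its own
#'   quadratic penalty `0.5 * eta_w^2 / tau_w` whose variance `tau_w` is
#'   re-estimated from the current deviation (`tau_w = eta_w^2 + eps^2`, a
#'   majorization-minimization scheme for a log penalty). Strong deviations
#'   end up nearly unpenalized while weak ones are driven to zero, so the
#'   tradeoff between frequent and rare terms tunes itself.
#' * `reg > 0`: fixed L1 penalty `reg * sum |eta_w|`.
#' * `reg = 0`: unpenalized maximum likelihood; `eta` then equals the
#'   difference in smoothed log relative frequencies between target and
#'   background (the natural normalization `Z = 1` fixes the additive
#'   gauge).
#'
#' @param target,background Character vectors of documents, or named numeric
#'   count vectors over a shared vocabulary.
#' @param max_n Largest n-gram order when the inputs are raw documents.
#' @param reg `NULL` (self-tuned), or a nonnegative L1 strength.
#' @param smoothing Additive count smoothing (default 0.5).
#' @param min_count Drop terms whose combined count is below this.
#' @param zero_sum Re-center `eta` each iteration so its background-weighted
#'   sum is zero (an alternative gauge; the likelihood is invariant).
#' @param max_iter,tol Convergence controls.
#' @return A `sage_model`: `vocabulary`, `m`, `eta`, `reg`, `converged`,
#'   `iterations`, plus the count vectors.
#' @export
fit_sage <- function(target, background, max_n = 3L, reg = NULL,
                     smoothing = 0.5, min_count = 1L, zero_sum = FALSE,
                     max_iter = 500L, tol = 1e-6) {
  as_counts <- function(x) {
    if (is.numeric(x)) {
      if (is.null(names(x))) stop("count vectors must be named")
      return(x)
    }
    if (length(x) == 0L) stop("corpus must be non-empty")
    corpus_ngram_counts(x, max_n = max_n)
  }
  ct_raw <- as_counts(target)
  cb_raw <- as_counts(background)
  vocab <- sort(union(names(ct_raw), names(cb_raw)))
  ct <- stats::setNames(numeric(length(vocab)), vocab)
  cb <- ct
  ct[names(ct_raw)] <- ct_raw
  cb[names(cb_raw)] <- cb_raw
  keep <- (ct + cb) >= min_count
  ct <- ct[keep]; cb <- cb[keep]; vocab <- vocab[keep]
  if (length(vocab) == 0L) stop("shared vocabulary is empty")
  m <- log(cb + smoothing) - log(sum(cb + smoothing))
  C <- sum(ct)
  V <- length(vocab)
  if (!is.null(reg) && reg == 0) {
    eta <- log(ct + smoothing) - log(sum(ct + smoothing)) - m
    return(new_sage(vocab, m, eta, "mle", TRUE, 0L, ct, cb))
  }
  objective <- function(eta, lam) {
    sum(ct * eta) - C * log(sum(exp(m + eta))) - sum(lam * abs(eta))
  }
  prox_newton <- function(eta, lam, iters) {
    # one pass of damped diagonal proximal Newton on the L1-penalized
    # likelihood with per-term weights lam
    delta_max <- Inf; it <- 0L
    while (it < iters && delta_max >= tol) {
      it <- it + 1L
      p <- exp(m + eta); p <- p / sum(p)
      g <- ct - C * p
      h <- pmax(C * p * (1 - p), 1e-8)
      z <- eta + g / h
      eta_new <- sign(z) * pmax(abs(z) - lam / h, 0)
      f0 <- objective(eta, lam)
      step <- 1
      repeat {
        cand <- eta + step * (eta_new - eta)
        if (objective(cand, lam) >= f0 - 1e-12 || step < 1e-6) break
        step <- step / 2
      }
      cand <- eta + step * (eta_new - eta)
      if (zero_sum) {
        wts <- exp(m)
        cand <- cand - sum(wts * cand) / sum(wts)
      }
      delta_max <- max(abs(cand - eta))
      eta <- cand
    }
    list(eta = eta, iters = it, converged = delta_max < tol)
  }
  eta <- numeric(V)
  if (is.null(reg)) {
    # self-tuned adaptive variances: damped Newton steps on the smooth
    # objective sum(ct*eta) - C log Z - 0.5 sum(eta^2 / tau), with
    # tau = eta^2 + eps^2 refreshed each iteration (MM for a log penalty).
    # Warm start at the unpenalized estimate: zero is a local attractor of
    # the log penalty, so starting there would crush genuine contrasts.
    eta <- log(ct + smoothing) - log(sum(ct + smoothing)) - m
    eps <- 1e-3
    smooth_obj <- function(e, itau)
      sum(ct * e) - C * log(sum(exp(m + e))) - 0.5 * sum(itau * e^2)
    delta_max <- Inf; it <- 0L
    while (it < max_iter && delta_max >= tol) {
      it <- it + 1L
      itau <- 1 / (eta^2 + eps^2)
      p <- exp(m + eta); p <- p / sum(p)
      g <- ct - C * p - itau * eta
      h <- pmax(C * p * (1 - p), 1e-8) + itau
      dir <- g / h
      f0 <- smooth_obj(eta, itau)
      step <- 1
      while (smooth_obj(eta + step * dir, itau) < f0 - 1e-12 && step > 1e-6)
        step <- step / 2
      cand <- eta + step * dir
      if (zero_sum) {
        wts <- exp(m)
        cand <- cand - sum(wts * cand) / sum(wts)
      }
      delta_max <- max(abs(cand - eta))
      eta <- cand
    }
    if (delta_max >= tol)
      stop(structure(class = c("sage_convergence_error", "error", "condition"),
                     list(message = sprintf(
                       "SAGE failed to converge in %d iterations (self-tuned)",
                       it), call = sys.call(-1), eta = eta)))
    return(new_sage(vocab, m, eta, "self-tuned", TRUE, it, ct, cb))
  }
  lam <- rep(reg, V)
  st <- prox_newton(eta, lam, iters = max_iter)
  if (!st$converged)
    stop(structure(class = c("sage_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "SAGE failed to converge in %d iterations (reg = %g)",
                     st$iters, reg), call = sys.call(-1), eta = st$eta)))
  new_sage(vocab, m, st$eta, reg, TRUE, st$iters, ct, cb)
}

new_sage <- function(vocab, m, eta, reg, converged, iterations, ct, cb) {
  structure(list(vocabulary = vocab, m = stats::setNames(m, vocab),
                 eta = stats::setNames(eta, vocab), reg = reg,
                 converged = converged, iterations = iterations,
                 counts_target = ct, counts_background = cb),
            class = "sage_model")
}

#' @exportS3Method base::print
print.sage_model <- function(x, ...) {
  cat(sprintf(
    "<sage_model> %d terms, reg = %s, %d iterations; %d non-zero deviations\n",
    length(x$vocabulary), as.character(x$reg), x$iterations,
    sum(abs(x$eta) > 1e-8)))
  invisible(x)
}

#' @export
coef.sage_model <- function(object, ...) object$eta

#' Top salient terms of a SAGE contrast
#'
#' The `k` terms with the largest positive (or most negative) deviation.
#' Ties are broken by higher background frequency, then lexicographically.
#'
#' @param model A `sage_model`.
#' @param k Number of terms (0 gives an empty result; larger than the
#'   vocabulary warns and returns everything).
#' @param direction `"positive"` (salient in the target corpus) or
#'   `"negative"` (salient in the background).
#' @return Data frame `term`, `eta`, `count_target`, `count_background`,
#'   ranked.
#' @export
top_salient <- function(model, k = 25L, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "sage_model"))
  if (k > length(model$vocabulary)) {
    warning("k exceeds vocabulary size; returning all terms")
    k <- length(model$vocabulary)
  }
  key <- if (direction == "positive") -model$eta else model$eta
  ord <- order(key, -model$counts_background, model$vocabulary)
  idx <- ord[seq_len(k)]
  data.frame(term = model$vocabulary[idx], eta = unname(model$eta[idx]),
             count_target = unname(model$counts_target[idx]),
             count_background = unname(model$counts_background[idx]),
             stringsAsFactors = FALSE)
}
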