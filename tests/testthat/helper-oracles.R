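# Independent oracles used across the suite. These deliberately avoid the
# package's own optimization/adjustment code paths.

# Brute-force maximizer of the SAGE penalized likelihood
#   f(eta) = sum(ct * eta) - C * log(sum(exp(m + eta))) - lambda * sum(|eta|)
# by cyclic coordinate grid search with shrinking ranges. Tractable only for
# tiny vocabularies; resolution well below the comparison tolerance.
sage_bruteforce <- function(ct, cb, lambda, smoothing = 0.5,
                            span = 8, rounds = 7L, grid_n = 81L,
                            sweeps = 60L) {
  m <- log(cb + smoothing) - log(sum(cb + smoothing))
  C <- sum(ct)
  V <- length(ct)
  eta <- numeric(V)
  obj_term <- function(w, g) {
    # objective as a function of eta[w] = g with the others fixed
    s_other <- sum(exp(m[-w] + eta[-w]))
    ct[w] * g - C * log(s_other + exp(m[w] + g)) - lambda * abs(g) -
      lambda * sum(abs(eta[-w]))
  }
  width <- span
  for (r in seq_len(rounds)) {
    for (s in seq_len(sweeps)) {
      moved <- 0
      for (w in seq_len(V)) {
        grid <- seq(eta[w] - width, eta[w] + width, length.out = grid_n)
        grid <- sort(c(grid, 0))  # the penalty kink is always a candidate
        vals <- vapply(grid, function(g) obj_term(w, g), 0)
        new <- grid[which.max(vals)]
        moved <- max(moved, abs(new - eta[w]))
        eta[w] <- new
      }
      if (moved < width / (grid_n - 1) / 2) break
    }
    width <- width / 6
  }
  eta
}

# Step-up FDR adjustment computed by direct enumeration:
# adjusted_(i) = min over j >= i of min(1, p_(j) * m * c_m / j), with
# c_m = 1 for plain step-up and the harmonic number H(m) for the
# arbitrary-dependence variant.
fdr_stepup_reference <- function(p, harmonic = TRUE) {
  m <- length(p)
  cm <- if (harmonic) sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, ps * m * cm / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Bootstrap oracle for comparing two overlapping dependent correlations:
# resample months with replacement, recompute r(a,p0) - r(a,p1), and use the
# percentile interval for sign/significance classification.
bootstrap_overlap_oracle <- function(a, p0, p1, B = 400L, level = 0.95) {
  n <- length(a)
  d <- replicate(B, {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(a[idx], p0[idx]) - stats::cor(a[idx], p1[idx]))
  })
  d <- d[is.finite(d)]
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(significant = qs[1] > 0 || qs[2] < 0,
       sign = sign(stats::median(d)))
}

# shared small simulation configs for fast tests
quick_sim <- function(seed, n_months = 40L, coupling = 0, lag = 0L,
                      posts_per_day = 5, ...) {
  sim_config(seed = seed, n_months = n_months, coupling = coupling,
             lag = lag, posts_per_day = posts_per_day, ...)
}
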