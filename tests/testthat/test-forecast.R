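pred_frame <- function(x, y) data.frame(month = month_seq("2012-01",
                                                          length(x)),
                                        actual = x, predicted = y)

test_that("metrics satisfy their closed-form identities", {
  x <- c(1, 2, 3, 5, 4)
  perfect <- prediction_metrics(pred_frame(x, x))
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$smape, 0)
  m <- prediction_metrics(pred_frame(c(1, 1, 1, 2), c(2, 1, 1, 2)))
  # the single discordant month contributes |2-1|/1.5
  expect_equal(m$mae, 0.25)
  expect_equal(m$smape, 100 * (1 / 1.5) / 4, tolerance = 1e-12)
  expect_error(prediction_metrics(pred_frame(1, 2)), "at least 3")
  flat <- prediction_metrics(pred_frame(rep(2, 5), c(1, 2, 3, 2, 1)))
  expect_false(flat$r_defined)
  expect_true(is.na(flat$pearson_r))
})

test_that("SMAPE and MAE are symmetric, bounded, and zero-safe on fuzzed input", {
  # the per-term ratio |y-x| / ((|x|+|y|)/2) is bounded by 2, so SMAPE lies
  # in [0, 200] for arbitrary input; each term is below 1 exactly when the
  # pair agrees within a factor of 3, so forecasts of that quality stay in
  # the familiar [0, 100] range
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(3:12, 1)
      x <- round(stats::rnorm(n, 0, 5), 2)
      y <- round(stats::rnorm(n, 0, 5), 2)
      x[sample(n, 1)] <- 0
      if (i %% 7 == 0) { y[1] <- 0; x[1] <- 0 }
      a <- prediction_metrics(pred_frame(x, y))
      b <- prediction_metrics(pred_frame(y, x))
      expect_true(a$smape >= 0 && a$smape <= 200)
      expect_true(a$mae >= 0)
      expect_equal(a$smape, b$smape)
      expect_equal(a$mae, b$mae)
      xp <- pmax(abs(x), 0.01); yp <- xp * stats::runif(n, 1 / 3, 3)
      expect_lte(prediction_metrics(pred_frame(xp, yp))$smape, 100)
    }
  })
})

test_that("relative-improvement arithmetic is exact", {
  d <- compare_metrics(list(pearson_r = 0.76, smape = 22.64),
                       list(pearson_r = 0.86, smape = 13.30))
  expect_equal(round(d$delta_r_percent, 2), 13.16)
  expect_equal(round(d$delta_error_percent, 2), 41.25)
})

test_that("anchored CV partitions the non-anchor months exactly once", {
  for (n in c(40L, 64L)) {
    for (k in c(4L, 10L)) {
      con <- gen_consultations(make_calendar(n, seed = 1),
                               sim_config(seed = 1, n_months = n))
      p <- cv_predict(con, k = k,
                      grid = data.frame(p = 1, d = 0, q = 0, P = 1, D = 1,
                                        Q = 0))
      expect_setequal(p$month, con$month[-(1:12)])
      expect_equal(anyDuplicated(p$month), 0L)
      expect_equal(sort(unique(p$fold)), seq_len(k))
    }
  }
  con <- gen_consultations(make_calendar(24, seed = 1),
                           sim_config(seed = 1, n_months = 24))
  expect_error(cv_predict(con, k = 20), "too short")
})

test_that("a constant series forecasts its own constant", {
  con <- monthly_series(month_seq("2011-01", 40), rep(5, 40), "rate_percent")
  fit <- fit_sarima(con)
  expect_lt(max(abs(predict(fit, 12) - 5)), 1e-6)
  p <- cv_predict(con, k = 4, grid = sarima_order_grid("small"))
  expect_lt(max(abs(p$predicted - 5)), 1e-6)
})

test_that("SARIMA recovers a seasonal AR process well enough to forecast", {
  y <- withr::with_seed(4, {
    n <- 96
    e <- stats::rnorm(n, 0, 0.4)
    x <- numeric(n)
    for (t in 13:n) x[t] <- 0.8 * x[t - 12] + 0.3 * x[t - 1] + e[t]
    8 + x
  })
  train <- stats::ts(y[1:84], frequency = 12)
  fit <- fit_sarima(train, grid = sarima_order_grid("small"))
  pred <- predict(fit, 12)
  sm <- prediction_metrics(pred_frame(y[85:96], pred))$smape
  expect_lt(sm, 20)
  # refitting the same data selects the same orders
  fit2 <- fit_sarima(train, grid = sarima_order_grid("small"))
  expect_identical(fit$order, fit2$order)
  expect_identical(fit$seasonal, fit2$seasonal)
})

test_that("permutation null behaves like exchangeable noise", {
  con <- gen_consultations(make_calendar(64, seed = 12),
                           sim_config(seed = 12, n_months = 64))
  p <- cv_predict(con, k = 10, grid = sarima_order_grid("small"))
  ps <- permutation_test(p, n_perm = 1000, seed = 5)
  expect_lt(abs(ps$mean_r), 0.05)
  ps2 <- permutation_test(p, n_perm = 1000, seed = 5)
  expect_identical(ps$null_r, ps2$null_r)
  perfect <- permutation_test(pred_frame(con$value, con$value),
                              n_perm = 500, seed = 1)
  expect_equal(perfect$prob_better, 0)
  expect_warning(permutation_test(p, n_perm = 50, seed = 1), "100")
})

test_that("dependent overlapping correlation test matches expectations", {
  a <- withr::with_seed(8, stats::rnorm(60, 8))
  noise <- withr::with_seed(9, stats::rnorm(60, 8))
  expect_equal(dependent_overlap_test(a, noise, noise)$t, 0)
  good <- a + withr::with_seed(10, stats::rnorm(60, 0, 0.3))
  strong <- dependent_overlap_test(a, noise, good)
  expect_lt(strong$t, 0)  # second series is the better predictor
  expect_lt(strong$p_value, 0.01)
  expect_error(dependent_overlap_test(a, rep(1, 60), good), "zero-variance")
  expect_error(dependent_overlap_test(a[1:5], noise[1:5], good[1:5]),
               "at least 10")
})

test_that("the t test agrees with a bootstrap oracle on clear-cut triples", {
  withr::with_seed(77, {
    agree <- vapply(1:200, function(i) {
      n <- 60
      a <- stats::rnorm(n)
      if (i %% 2 == 0) {
        p0 <- stats::rnorm(n)               # useless baseline
        p1 <- a + stats::rnorm(n, 0, 0.5)   # strong predictor
      } else {
        p0 <- a + stats::rnorm(n, 0, 1)     # equally mediocre predictors
        p1 <- a + stats::rnorm(n, 0, 1)
      }
      tst <- dependent_overlap_test(a, p0, p1)
      orc <- bootstrap_overlap_oracle(a, p0, p1, B = 300)
      sig_t <- tst$p_value < 0.05
      if (sig_t && orc$significant) sign(tst$t) == orc$sign
      else sig_t == orc$significant
    }, TRUE)
    expect_gte(mean(agree), 0.95)
  })
})

test_that("coupled covariates improve cross-validated forecasts", {
  smapes <- t(vapply(1:10, function(sd) {
    cfg <- quick_sim(seed = sd, n_months = 60, coupling = 2, lag = 2,
                     posts_per_day = 8)
    cal <- make_calendar(60, seed = sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    prev <- lapply(cfg$lexicons[c("depression", "anxiety", "stress",
                                  "suicidal_ideation")],
                   function(lex) monthly_term_frequency(posts, lex))
    g <- sarima_order_grid("small")
    m0 <- prediction_metrics(cv_predict(con, NULL, k = 10, grid = g))
    m1 <- prediction_metrics(cv_predict(con, prev, k = 10, grid = g,
                                        exog_lag = 2,
                                        exog_combine = "pc1"))
    c(m0$smape, m1$smape)
  }, c(0, 0)))
  expect_gte(sum(smapes[, 2] < smapes[, 1]), 8)
})

test_that("uncoupled covariates give no systematic advantage", {
  smapes <- t(vapply(1:20, function(sd) {
    cfg <- quick_sim(seed = 300 + sd, n_months = 48, coupling = 0,
                     posts_per_day = 5)
    cal <- make_calendar(48, seed = 300 + sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    prev <- lapply(cfg$lexicons[c("depression", "anxiety", "stress",
                                  "suicidal_ideation")],
                   function(lex) monthly_term_frequency(posts, lex))
    g <- sarima_order_grid("small")
    m0 <- prediction_metrics(cv_predict(con, NULL, k = 5, grid = g))
    m1 <- prediction_metrics(cv_predict(con, prev, k = 5, grid = g,
                                        exog_combine = "pc1"))
    c(m0$smape, m1$smape)
  }, c(0, 0)))
  wins <- sum(smapes[, 2] < smapes[, 1])
  # one-sided sign test for a systematic M1 advantage
  p <- stats::binom.test(wins, 20, alternative = "greater")$p.value
  expect_gt(p, 0.05)
})

test_that("comparing M1 against M0 favors M1 under strong coupling", {
  ts_sign <- vapply(1:20, function(sd) {
    cfg <- quick_sim(seed = sd, n_months = 48, coupling = 2, lag = 0,
                     posts_per_day = 5)
    cal <- make_calendar(48, seed = sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    prev <- lapply(cfg$lexicons[c("depression", "anxiety", "stress",
                                  "suicidal_ideation")],
                   function(lex) monthly_term_frequency(posts, lex))
    g <- sarima_order_grid("small")
    p0 <- cv_predict(con, NULL, k = 5, grid = g)
    p1 <- cv_predict(con, prev, k = 5, grid = g, exog_combine = "pc1")
    dependent_overlap_test(p0$actual, p0$predicted, p1$predicted)$t
  }, 0)
  expect_gte(mean(ts_sign < 0), 0.8)
})
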