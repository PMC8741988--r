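test_that("normalization converts visits to percent of enrolled", {
  s <- normalize_consultations(c(500, 0, 50000), 50000,
                               c("2011-05", "2011-06", "2011-07"))
  expect_equal(s$value, c(1, 0, 100))
  expect_error(normalize_consultations(5, 0, "2011-05"), "enrollment")
  expect_error(normalize_consultations(-1, 10, "2011-05"), "visits")
})

test_that("monthly series container validates its index", {
  expect_error(monthly_series(c("2011-05", "2011-07"), c(1, 2)), "gaps")
  expect_error(monthly_series(c("2011-06", "2011-05"), c(1, 2)), "increasing")
  expect_error(monthly_series("2011/05", 1), "YYYY-MM")
  expect_warning(
    filled <- fill_month_gaps(data.frame(month = c("2011-05", "2011-08"),
                                         value = c(1, 4))),
    "imputing")
  expect_equal(filled$value, c(1, 2, 3, 4))
  expect_equal(filled$month, month_seq("2011-05", 4))
})

test_that("ADF test separates stationary noise from a random walk", {
  wn <- withr::with_seed(42, stats::rnorm(120))
  rep_wn <- adf_test(wn)
  expect_lt(rep_wn$p_value, 0.05)
  expect_true(rep_wn$stationary)
  rw <- withr::with_seed(43, cumsum(stats::rnorm(120)))
  rep_rw <- adf_test(rw)
  expect_gt(rep_rw$p_value, 0.05)
  expect_false(rep_rw$stationary)
  expect_error(adf_test(stats::rnorm(10)), "too short")
  deg <- adf_test(rep(3, 30))
  expect_true(deg$degenerate)
  expect_false(deg$stationary)
})

test_that("decomposition removes pure seasonality and pure trend exactly", {
  months <- month_seq("2011-01", 48)
  sinus <- monthly_series(months, sin(2 * pi * seq_len(48) / 12), "other")
  d <- decompose_series(sinus, 12)
  expect_lt(max(abs(d$residual[d$interior])), 1e-6)
  ramp <- monthly_series(months, 0.3 * seq_len(48), "other")
  d2 <- decompose_series(ramp, 12)
  expect_lt(max(abs(d2$seasonal)), 1e-6)
  expect_error(decompose_series(sinus, 1), "window")
  expect_error(decompose_series(monthly_series(months[1:20],
                                               stats::rnorm(20)), 12),
               "twice the window")
})

test_that("decomposition is additive everywhere", {
  withr::with_seed(5, {
    s <- monthly_series(month_seq("2011-05", 40), stats::rnorm(40, 8))
    d <- decompose_series(s, 12)
    expect_lt(max(abs(d$trend + d$seasonal + d$residual - s$value)), 1e-9)
  })
})

test_that("residualize reports stationarity and is stable under repetition", {
  # slope-free seasonal input: the edge fill is exact, so a second pass
  # changes nothing (with a sloped trend the mandated edge fill leaves
  # nonzero edge residuals that a second pass smooths into the interior)
  months <- month_seq("2011-01", 48)
  det <- monthly_series(months,
                        8 + 2 * sin(2 * pi * seq_len(48) / 12),
                        "rate_percent")
  r1 <- suppressWarnings(residualize(det, 12))
  expect_s3_class(attr(r1, "adf"), "adf_report")
  r2 <- suppressWarnings(residualize(r1, 12))
  expect_lt(max(abs(r2$value - r1$value)), 1e-6)
  # on noisy input the second pass only nibbles at the smoothed noise the
  # moving average leaves behind; the residual is already dominant
  noisy <- gen_consultations(make_calendar(60, seed = 8),
                             sim_config(seed = 8, n_months = 60))
  n1 <- suppressWarnings(residualize(noisy, 12))
  n2 <- suppressWarnings(residualize(n1, 12))
  expect_gt(stats::cor(n1$value, n2$value), 0.95)
})

test_that("default generator output residualizes to stationarity", {
  ok <- vapply(1:10, function(sd) {
    con <- gen_consultations(make_calendar(64, seed = sd),
                             sim_config(seed = sd, n_months = 64))
    attr(suppressWarnings(residualize(con, 12)), "adf")$p_value < 0.05
  }, TRUE)
  expect_gte(sum(ok), 9)
})

test_that("self-association is exact and null association is flat", {
  con <- gen_consultations(make_calendar(40, seed = 2),
                           sim_config(seed = 2, n_months = 40))
  vres <- suppressWarnings(residualize(con))
  self_plain <- lagged_association(vres, vres, lag = 0, controls = FALSE)
  expect_equal(self_plain$e, 1, tolerance = 1e-9)
  self_ctl <- lagged_association(vres, vres, lag = 0)
  expect_gt(self_ctl$e, 0)
  expect_lt(self_ctl$p_value, 0.05)
  # independent noise: small e, non-significant on the median seed
  stats <- t(vapply(1:20, function(sd) {
    noise <- monthly_series(con$month,
                            withr::with_seed(100 + sd, stats::rnorm(40)),
                            "residual")
    a <- lagged_association(vres, noise, lag = 0)
    c(a$e, a$p_value)
  }, c(0, 0)))
  expect_lt(stats::median(abs(stats[, 1])), 0.3)
  expect_gt(stats::median(stats[, 2]), 0.05)
})

test_that("association errors on short overlap and zero variance", {
  con <- gen_consultations(make_calendar(24, seed = 3),
                           sim_config(seed = 3, n_months = 24))
  vres <- suppressWarnings(residualize(con))
  expect_error(lagged_association(vres, vres, lag = 15), "overlap")
  flat <- monthly_series(con$month, rep(1, 24), "residual")
  expect_error(lagged_association(vres, flat, lag = 0), "zero-variance")
})

test_that("standardized coefficients are scale invariant", {
  cfg <- quick_sim(seed = 6, n_months = 48, coupling = 1.5)
  cal <- make_calendar(48, seed = 6)
  con <- gen_consultations(cal, cfg)
  posts <- gen_posts(cal, con, cfg)
  pv <- monthly_term_frequency(posts, cfg$lexicons$stress)
  vres <- suppressWarnings(residualize(con))
  eres <- suppressWarnings(residualize(pv))
  e1 <- lagged_association(vres, eres, lag = 0)$e
  scaled <- monthly_series(eres$month, 137.5 * eres$value, "residual")
  e2 <- lagged_association(vres, scaled, lag = 0)$e
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("the lag scan recovers the generator's planted lag", {
  hits <- vapply(1:10, function(sd) {
    cfg <- quick_sim(seed = sd, n_months = 60, coupling = 2, lag = 2)
    cal <- make_calendar(60, seed = sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    pv <- monthly_term_frequency(posts,
                                 unlist(cfg$lexicons, use.names = FALSE))
    vres <- suppressWarnings(residualize(con))
    eres <- suppressWarnings(residualize(pv))
    sc <- lag_scan(vres, eres, 6)
    sc$lag[which.max(sc$e)] == 2L
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("positive coupling yields positive significant e at the true lag", {
  res <- t(vapply(1:20, function(sd) {
    cfg <- quick_sim(seed = sd, n_months = 60, coupling = 2, lag = 0)
    cal <- make_calendar(60, seed = sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    pv <- monthly_term_frequency(posts,
                                 unlist(cfg$lexicons, use.names = FALSE))
    vres <- suppressWarnings(residualize(con))
    eres <- suppressWarnings(residualize(pv))
    a <- lagged_association(vres, eres, lag = 0)
    c(a$e, a$p_value)
  }, c(0, 0)))
  expect_gte(mean(res[, 1] > 0 & res[, 2] < 0.05), 0.8)
})
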