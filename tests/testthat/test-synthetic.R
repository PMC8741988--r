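test_that("calendar profile is deterministic, centered, and peaks in April", {
  cal1 <- make_calendar(36, seed = 7)
  cal2 <- make_calendar(36, seed = 7)
  expect_identical(cal1, cal2)
  expect_lt(abs(mean(cal1$seasonal_load[1:12])), 1e-9)
  # any 12 consecutive months average to ~0 (period-12, centered)
  for (s in c(5, 13, 20))
    expect_lt(abs(mean(cal1$seasonal_load[s:(s + 11)])), 1e-9)
  # argmax within each calendar year is the first configured peak (April)
  moy <- cal1$month_of_year
  for (yr in split(seq_len(36), cumsum(moy == 1))) {
    if (length(yr) < 12) next
    expect_equal(moy[yr][which.max(cal1$seasonal_load[yr])], 4L)
  }
  expect_error(make_calendar(12), "insufficient history")
})

test_that("consultation generator obeys its noise-free and clipping limits", {
  cfg0 <- sim_config(seed = 1, n_months = 36, noise_sd = 0, trend_slope = 0)
  cal <- make_calendar(36, seed = 1, trend_slope = 0)
  con <- gen_consultations(cal, cfg0)
  expect_equal(con$value, cfg0$base_rate + cal$seasonal_load, tolerance = 1e-12)
  # heavy noise never produces negative rates
  cfgN <- sim_config(seed = 2, n_months = 36, base_rate = 0.5, noise_sd = 5)
  conN <- gen_consultations(make_calendar(36, seed = 2), cfgN)
  expect_true(all(conN$value >= 0))
  expect_error(sim_config(base_rate = -1), "base_rate")
})

test_that("consultation generator mean matches the Monte-Carlo oracle", {
  n_rep <- 1000L
  cal <- make_calendar(24, seed = 5)
  t_check <- c(3L, 11L, 17L)
  draws <- sapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(seed = 1000L + i, n_months = 24, noise_sd = 0.8)
    gen_consultations(cal, cfg)$value[t_check]
  })
  expected <- sim_config(seed = 1, n_months = 24)$base_rate +
    cal$trend[t_check] + cal$seasonal_load[t_check]
  tol <- 3 * 0.8 / sqrt(n_rep)
  expect_true(all(abs(rowMeans(draws) - expected) < tol))
})

test_that("post stream generation is deterministic and well-formed", {
  cfg <- quick_sim(seed = 11, coupling = 1)
  cal <- make_calendar(cfg$n_months, seed = 11)
  con <- gen_consultations(cal, cfg)
  p1 <- gen_posts(cal, con, cfg)
  p2 <- gen_posts(cal, con, cfg)
  expect_identical(p1, p2)
  expect_true(!is.unsorted(p1$timestamp))
  expect_true(all(format(p1$timestamp, "%Y-%m") %in% cal$months))
  expect_error(gen_posts(cal, con, quick_sim(seed = 1, lag = 40L)),
               "lag")
})

test_that("uncoupled post streams are independent of the consultation series", {
  rs <- vapply(1:20, function(sd) {
    cfg <- quick_sim(seed = sd, n_months = 60, coupling = 0)
    cal <- make_calendar(60, seed = sd)
    con <- gen_consultations(cal, cfg)
    posts <- gen_posts(cal, con, cfg)
    pv <- monthly_term_frequency(posts,
                                 unlist(cfg$lexicons, use.names = FALSE))
    stats::cor(pv$value, con$value)
  }, 0)
  expect_lt(abs(stats::median(rs)), 0.2)
})

test_that("coupling raises the language-consultation coupling monotonically", {
  # the logistic link is linear on the log-odds scale, so monotonicity in
  # the coupling is measured there; the raw-scale correlation saturates by
  # construction but must be plainly visible under strong coupling
  cors_at <- function(coupling) {
    t(vapply(1:10, function(sd) {
      cfg <- quick_sim(seed = sd, n_months = 60, coupling = coupling)
      cal <- make_calendar(60, seed = sd)
      con <- gen_consultations(cal, cfg)
      posts <- gen_posts(cal, con, cfg)
      pv <- monthly_term_frequency(posts,
                                   unlist(cfg$lexicons, use.names = FALSE))
      lo <- stats::qlogis(pmin(pmax(pv$value, 1e-6), 1 - 1e-6))
      c(raw = stats::cor(pv$value, con$value),
        link = stats::cor(lo, con$value))
    }, c(0, 0)))
  }
  med <- vapply(c(0, 0.5, 1, 2),
                function(cp) apply(cors_at(cp), 2, stats::median), c(0, 0))
  expect_true(all(diff(med["link", ]) >= 0))
  expect_gt(med["raw", 2], med["raw", 1])
  expect_gt(med["raw", 4], 0.5)  # strong coupling at lag 0 is plainly visible
})

test_that("training corpora are separable as configured and validated", {
  cfg <- sim_config(seed = 3, n_pos = 60, n_neg = 60, p_pos = 0.3,
                    p_neg = 0.01)
  corp <- gen_training_corpora(cfg)
  all_terms <- unlist(cfg$lexicons, use.names = FALSE)
  rate <- function(docs) {
    tok <- unlist(strsplit(docs, " ", fixed = TRUE))
    mean(tok %in% all_terms)
  }
  for (o in names(corp$positives))
    expect_gt(rate(corp$positives[[o]]), rate(corp$negatives))
  expect_error(gen_training_corpora(sim_config(p_pos = 0.01, p_neg = 0.3)),
               "not separable")
  expect_error(gen_training_corpora(sim_config(n_pos = 0)), "n_pos")
  # document lengths track the configured mean
  cfgL <- sim_config(seed = 4, n_pos = 1000, n_neg = 2, mean_doc_len = 40)
  lens <- lengths(strsplit(gen_training_corpora(cfgL)$positives[[1]], " "))
  expect_lt(abs(mean(lens) - 40) / 40, 0.05)
})

test_that("serialized outputs round-trip byte-identically under a fixed seed", {
  cfg <- quick_sim(seed = 9, n_months = 25, posts_per_day = 2, coupling = 1)
  cal <- make_calendar(25, seed = 9)
  con <- gen_consultations(cal, cfg)
  posts <- gen_posts(cal, con, cfg)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.jsonl"); f2 <- file.path(d, "b.jsonl")
  write_posts_jsonl(posts, f1)
  write_posts_jsonl(gen_posts(cal, con, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_posts_jsonl(f1)
  expect_equal(back$text, posts$text)
  expect_equal(back$timestamp, posts$timestamp, tolerance = 1e-3)
  tab <- consultation_table(con, cfg)
  fc <- file.path(d, "visits.csv")
  write_consultations_csv(tab, fc)
  expect_equal(read_consultations_csv(fc)$visits, tab$visits)
  dd <- file.path(d, "corpora")
  corp <- gen_training_corpora(quick_sim(seed = 2, n_pos = 5, n_neg = 4))
  write_corpora(corp, dd)
  back2 <- read_corpora(dd)
  expect_equal(back2$negatives, corp$negatives)
  expect_equal(back2$positives$stress, corp$positives$stress)
})
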