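#' Default per-outcome symptom lexicons
#'
#' Small disjoint word lists, one per symptomatic outcome, used by the
#' synthetic generators: positive training documents and coupled post streams
#' are enriched in these terms. They are generator configuration, not a
#' clinical instrument.
#'
#' @return Named list of character vectors for depression, anxiety, stress,
#'   suicidal_ideation, psychosis.
#' @export
default_outcome_lexicons <- function() {
  list(
    depression = c("depressed", "depression", "hopeless", "worthless",
                   "empty", "numb", "crying", "lonely", "miserable",
                   "despair", "gloomy", "drained"),
    anxiety = c("anxious", "anxiety", "panic", "worry", "nervous",
                "restless", "dread", "uneasy", "tense", "jittery",
                "apprehensive", "racing"),
    stress = c("stress", "stressed", "overwhelmed", "deadline", "deadlines",
               "workload", "pressure", "burnout", "cramming", "exhausted",
               "frazzled", "swamped"),
    suicidal_ideation = c("suicidal", "suicide", "selfharm", "hotline",
                          "lifeline", "overdose", "goodbye", "endless",
                          "unbearable", "burden", "vanish", "disappear"),
    psychosis = c("psychosis", "hallucination", "hallucinations", "voices",
                  "delusion", "paranoid", "unreal", "derealization",
                  "episode", "antipsychotic", "visions", "shadows"))
}

#' Default background vocabulary with Zipf weights
#'
#' A base of everyday campus-forum words followed by synthetic filler tokens,
#' with sampling probabilities proportional to 1/rank (Zipf's law), which is
#' the canonical size-frequency profile of natural text.
#'
#' @param size Total vocabulary size.
#' @return List with `words` and sampling `prob`.
#' @export
default_background_vocab <- function(size = 2000L) {
  common <- c("the", "to", "and", "of", "in", "is", "it", "you", "that",
              "for", "on", "with", "as", "at", "this", "but", "my", "have",
              "be", "not", "are", "was", "we", "they", "so", "all", "just",
              "campus", "class", "classes", "professor", "semester", "dorm",
              "parking", "football", "game", "party", "friends", "weekend",
              "food", "dining", "library", "study", "course", "credit",
              "advisor", "major", "housing", "roommate", "club", "tickets",
              "bus", "coffee", "music", "movie", "gym", "break", "summer",
              "spring", "fall", "winter", "freshman", "senior", "tuition",
              "email", "online", "lecture", "lab", "quiz", "grade", "grades",
              "gpa", "schedule", "register", "application", "internship",
              "job", "resume", "career", "graduation", "commencement",
              "happy", "great", "love", "fun", "awesome", "nice", "cool",
              "thanks", "help", "question", "anyone", "know", "time", "year",
              "people", "good", "best", "new", "really", "think", "going")
  n_extra <- max(0L, size - length(common))
  words <- c(common, sprintf("word%04d", seq_len(n_extra)))[seq_len(size)]
  prob <- 1 / seq_along(words)
  list(words = words, prob = prob / sum(prob))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. Defaults emulate the
#' study conditions: a 64-month window starting May 2011, about 33 posts per
#' day from a pool of ~18,400 authors, consultation rates expressed as a
#' percentage of ~50,000 enrolled students, academic-calendar seasonality,
#' and a configurable coupling by which the standardized consultation signal
#' at month `t + lag` raises the symptom-lexicon share of posts written in
#' month `t` (posts lead consultations by `lag` months).
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_months Number of months simulated.
#' @param start First month, `"YYYY-MM"`.
#' @param enrollment Enrolled students per month (scalar or vector).
#' @param base_rate Baseline consultation rate, percent of enrolled.
#' @param coupling Nonnegative strength linking latent load to post language.
#' @param lag Months by which post language leads consultations.
#' @param posts_per_day Mean posts per day (Poisson).
#' @param noise_sd SD of the Gaussian month-level rate noise.
#' @param trend_slope Linear trend of the rate, percentage points per month.
#' @param mean_doc_len Mean post length in tokens (Poisson, min 3).
#' @param n_authors Size of the author pool.
#' @param base_mix Baseline probability that a token comes from one given
#'   outcome lexicon (at zero standardized load).
#' @param background_vocab As from [default_background_vocab()].
#' @param lexicons Named list of outcome word lists.
#' @param n_pos,n_neg Documents per class in the training corpora.
#' @param p_pos,p_neg Lexicon-term token rate in positive / negative
#'   training documents (`p_pos > p_neg`).
#' @param seasonal_amplitude,peak_months,trough_months Passed to
#'   [make_calendar()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_months = 64L, start = "2011-05",
                       enrollment = 50000L, base_rate = 8,
                       coupling = 1, lag = 0L, posts_per_day = 33,
                       noise_sd = 0.8, trend_slope = 0.02,
                       mean_doc_len = 40, n_authors = 18401L,
                       base_mix = 0.03,
                       background_vocab = default_background_vocab(),
                       lexicons = default_outcome_lexicons(),
                       n_pos = 500L, n_neg = 500L,
                       p_pos = 0.3, p_neg = 0.01,
                       seasonal_amplitude = 2,
                       peak_months = c(4L, 7L, 11L),
                       trough_months = c(12L, 2L, 10L)) {
  if (base_rate < 0) stop("base_rate must be nonnegative")
  if (coupling < 0) stop("coupling must be nonnegative")
  if (lag < 0) stop("lag must be nonnegative")
  if (posts_per_day < 0) stop("posts_per_day must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(lexicons) == 0L || any(lengths(lexicons) == 0L))
    stop("each outcome lexicon must be non-empty")
  if (base_mix * length(lexicons) >= 0.9)
    stop("base_mix too large for the number of outcomes")
  structure(list(seed = as.integer(seed), n_months = as.integer(n_months),
                 start = start, enrollment = enrollment,
                 base_rate = base_rate, coupling = coupling,
                 lag = as.integer(lag), posts_per_day = posts_per_day,
                 noise_sd = noise_sd, trend_slope = trend_slope,
                 mean_doc_len = mean_doc_len, n_authors = as.integer(n_authors),
                 base_mix = base_mix, background_vocab = background_vocab,
                 lexicons = lexicons, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), p_pos = p_pos, p_neg = p_neg,
                 seasonal_amplitude = seasonal_amplitude,
                 peak_months = peak_months, trough_months = trough_months),
            class = "sim_config")
}

#' Simulate the monthly consultation series
#'
#' Monthly rate (percent of enrolled) = base rate + trend + seasonal load +
#' Gaussian noise, clipped at zero.
#'
#' @param profile A [make_calendar()] profile of length `cfg$n_months`.
#' @param cfg A [sim_config()].
#' @return A `monthly_series` of kind `rate_percent`.
#' @export
gen_consultations <- function(profile, cfg) {
  stopifnot(inherits(profile, "calendar_profile"))
  if (profile$n_months != cfg$n_months)
    stop("profile length must equal cfg$n_months")
  eps <- withr::with_seed(cfg$seed + 1L,
                          stats::rnorm(cfg$n_months, 0, cfg$noise_sd))
  rate <- pmax(cfg$base_rate + profile$trend + profile$seasonal_load + eps, 0)
  monthly_series(profile$months, rate, "rate_percent")
}

#' Consultation series as a visits/enrollment table
#'
#' @param series Rate series from [gen_consultations()].
#' @param cfg A [sim_config()] (for enrollment).
#' @return Data frame `month,visits,enrollment` as written to CSV.
#' @export
consultation_table <- function(series, cfg) {
  enrollment <- rep_len(cfg$enrollment, nrow(series))
  data.frame(month = series$month,
             visits = round(series$value / 100 * enrollment),
             enrollment = enrollment, stringsAsFactors = FALSE)
}

#' Simulate a coupled post stream
#'
#' Draws per-day post counts from a Poisson law, post lengths from a Poisson
#' law (minimum 3 tokens), and tokens from a mixture of the background
#' vocabulary and the outcome lexicons. The mixture follows a multinomial
#' logit: in month `t` outcome `o`'s token share is
#' `b*exp(coupling*z[t+lag]) / (1 + K*b*exp(coupling*z[t+lag]))` with `z` the
#' standardized consultation series, `K` the number of outcomes and `b`
#' calibrated so the share equals `base_mix` at `z = 0`. Posts therefore lead
#' consultations by `lag` months, and `coupling = 0` makes the stream
#' independent of the consultation series.
#'
#' @param profile A [make_calendar()] profile.
#' @param consult Consultation series from [gen_consultations()].
#' @param cfg A [sim_config()].
#' @return A `post_stream` data frame: id, timestamp (POSIXct UTC), author,
#'   text (space-joined tokens).
#' @export
gen_posts <- function(profile, consult, cfg) {
  stopifnot(inherits(profile, "calendar_profile"))
  if (cfg$lag >= cfg$n_months) stop("lag must be smaller than n_months")
  n <- cfg$n_months
  z <- if (stats::sd(consult$value) > 0)
    as.numeric(scale(consult$value)) else numeric(n)
  # z at month t + lag drives the language of month t; beyond the simulated
  # window the load is taken at its mean (0)
  zlead <- c(z[seq.int(1L + cfg$lag, n)], rep(0, cfg$lag))
  K <- length(cfg$lexicons)
  b <- cfg$base_mix / (1 - K * cfg$base_mix)
  w <- b * exp(cfg$coupling * zlead)
  p_out <- w / (1 + K * w)          # per-outcome token share, per month
  p_bg <- 1 - K * p_out
  vocab <- cfg$background_vocab
  month_starts <- as.Date(paste0(profile$months, "-01"))
  month_days <- as.integer(diff(c(month_starts,
                                  seq(month_starts[n], by = "1 month",
                                      length.out = 2L)[2L])))
  withr::with_seed(cfg$seed + 2L, {
    out <- vector("list", n)
    post_offset <- 0L
    for (t in seq_len(n)) {
      counts <- stats::rpois(month_days[t], cfg$posts_per_day)
      n_posts <- sum(counts)
      if (n_posts == 0L) { out[[t]] <- NULL; next }
      lens <- pmax(stats::rpois(n_posts, cfg$mean_doc_len), 3L)
      total <- sum(lens)
      src <- sample.int(K + 1L, total, replace = TRUE,
                        prob = c(p_bg[t], rep(p_out[t], K)))
      toks <- character(total)
      bg <- src == 1L
      if (any(bg))
        toks[bg] <- sample(vocab$words, sum(bg), replace = TRUE,
                           prob = vocab$prob)
      for (o in seq_len(K)) {
        sel <- src == o + 1L
        if (any(sel))
          toks[sel] <- sample(cfg$lexicons[[o]], sum(sel), replace = TRUE)
      }
      texts <- vapply(split(toks, rep.int(seq_len(n_posts), lens)),
                      paste, "", collapse = " ")
      day_of_post <- rep.int(seq_len(month_days[t]), counts)
      secs <- sort(stats::runif(n_posts, 0, 86400)) # within-day order
      ts_post <- as.POSIXct(month_starts[t], tz = "UTC") +
        (day_of_post - 1L) * 86400 + secs
      out[[t]] <- data.frame(
        id = sprintf("p%07d", post_offset + seq_len(n_posts)),
        timestamp = ts_post,
        author = sprintf("u%05d", sample.int(cfg$n_authors, n_posts,
                                             replace = TRUE)),
        text = unname(texts), stringsAsFactors = FALSE)
      post_offset <- post_offset + n_posts
    }
  })
  posts <- do.call(rbind, out)
  rownames(posts) <- NULL
  structure(posts, months = profile$months,
            class = c("post_stream", "data.frame"))
}

#' @exportS3Method base::print
print.post_stream <- function(x, ...) {
  cat(sprintf("<post_stream> %d posts, %d authors, %s .. %s\n", nrow(x),
              length(unique(x$author)), format(min(x$timestamp), "%Y-%m-%d"),
              format(max(x$timestamp), "%Y-%m-%d")))
  invisible(x)
}

#' Monthly frequency of a term set in a post stream
#'
#' Fraction of tokens per month that belong to `terms` — the direct,
#' classifier-free measure of lexicon prevalence used to validate the
#' generator's coupling.
#'
#' @param posts A `post_stream`.
#' @param terms Character vector of terms.
#' @param months Optional full month range (defaults to the stream's).
#' @return A `monthly_series` of kind `prevalence`.
#' @export
monthly_term_frequency <- function(posts, terms, months = NULL) {
  if (is.null(months)) months <- attr(posts, "months")
  mlab <- format(posts$timestamp, "%Y-%m")
  toks <- strsplit(posts$text, " ", fixed = TRUE)
  ntok <- lengths(toks)
  nhit <- vapply(toks, function(t) sum(t %in% terms), 0L)
  tot <- tapply(ntok, mlab, sum)
  hit <- tapply(nhit, mlab, sum)
  if (is.null(months)) months <- sort(names(tot))
  v <- as.numeric(hit[months] / tot[months])
  monthly_series(months, v, "prevalence")
}

#' Simulate per-outcome classifier training corpora
#'
#' For each outcome, `n_pos` positive documents whose tokens come from the
#' outcome lexicon with probability `p_pos` (background otherwise), plus one
#' shared negative corpus in which any lexicon term appears at rate `p_neg`.
#'
#' @param cfg A [sim_config()].
#' @return List with `positives` (named list of character-vector corpora,
#'   one per outcome) and `negatives` (character vector).
#' @export
gen_training_corpora <- function(cfg) {
  if (cfg$n_pos <= 0L || cfg$n_neg <= 0L)
    stop("n_pos and n_neg must be positive")
  if (cfg$p_pos <= cfg$p_neg) stop("corpora not separable as configured")
  vocab <- cfg$background_vocab
  all_terms <- unlist(cfg$lexicons, use.names = FALSE)
  gen_docs <- function(n_docs, rate, terms) {
    lens <- pmax(stats::rpois(n_docs, cfg$mean_doc_len), 3L)
    total <- sum(lens)
    use_lex <- stats::runif(total) < rate
    toks <- character(total)
    toks[!use_lex] <- sample(vocab$words, sum(!use_lex), replace = TRUE,
                             prob = vocab$prob)
    if (any(use_lex))
      toks[use_lex] <- sample(terms, sum(use_lex), replace = TRUE)
    unname(vapply(split(toks, rep.int(seq_len(n_docs), lens)),
                  paste, "", collapse = " "))
  }
  withr::with_seed(cfg$seed + 3L, {
    positives <- lapply(cfg$lexicons,
                        function(lex) gen_docs(cfg$n_pos, cfg$p_pos, lex))
    negatives <- gen_docs(cfg$n_neg, cfg$p_neg, all_terms)
  })
  list(positives = positives, negatives = negatives)
}
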