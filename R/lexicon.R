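#' Read a category lexicon in `.dic` dialect
#'
#' Parses the dictionary format used by psycholinguistic word-count tools:
#' a `%`-delimited header block mapping numeric category IDs to names,
#' followed by `word<TAB>id...` lines. A terminal `*` marks a prefix
#' wildcard (`friend*` matches "friends", "friendly", not "befriend");
#' wildcards anywhere else are rejected.
#'
#' @param path Path to a `.dic` file.
#' @return A `category_lexicon`: named list mapping category name to a
#'   character vector of patterns.
#' @export
read_dic <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  pct <- which(lines == "%")
  if (length(pct) < 2L) stop("not a .dic file: missing %-delimited header")
  header <- lines[(pct[1L] + 1L):(pct[2L] - 1L)]
  body <- lines[-seq_len(pct[2L])]
  hp <- strsplit(header, "[\t ]+")
  ids <- vapply(hp, function(x) x[1L], "")
  nms <- vapply(hp, function(x) x[2L], "")
  cats <- stats::setNames(vector("list", length(ids)), nms)
  for (ln in strsplit(body, "[\t ]+")) {
    w <- ln[1L]
    for (id in ln[-1L]) {
      nm <- nms[match(id, ids)]
      if (is.na(nm)) stop(sprintf("unknown category id '%s' for word '%s'",
                                  id, w))
      cats[[nm]] <- c(cats[[nm]], w)
    }
  }
  as_category_lexicon(cats)
}

#' Build a category lexicon from a named list
#'
#' @param categories Named list of pattern vectors (exact words or
#'   `stem*` prefix wildcards; `*` is only allowed terminally).
#' @return A `category_lexicon`.
#' @export
as_category_lexicon <- function(categories) {
  if (length(categories) == 0L || is.null(names(categories)))
    stop("categories must be a non-empty named list")
  if (any(lengths(categories) == 0L))
    stop("every category needs at least one pattern")
  bad <- unlist(lapply(categories, function(p)
    p[grepl("\\*", sub("\\*$", "", p))]))
  if (length(bad))
    stop(sprintf("wildcard '*' is only allowed terminally: %s",
                 paste(bad, collapse = ", ")))
  structure(categories, class = "category_lexicon")
}

#' @exportS3Method base::print
print.category_lexicon <- function(x, ...) {
  cat(sprintf("<category_lexicon> %d categories: %s\n", length(x),
              paste(utils::head(names(x), 8L), collapse = ", ")))
  invisible(x)
}

#' Per-document normalized category occurrence
#'
#' For every document, the percentage of tokens matching each category:
#' `100 * matching tokens / total tokens`. A token matches a category if it
#' equals an exact pattern or starts with a wildcard stem (it is counted
#' once per category however many patterns it matches). Empty documents get
#' 0 in every category, with a warning.
#'
#' @param docs Character vector of documents.
#' @param lexicon A `category_lexicon`.
#' @return Numeric matrix, documents x categories, of percentages.
#' @export
lexicon_profile <- function(docs, lexicon) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  toks <- tokenize(docs)
  if (any(lengths(toks) == 0L))
    warning(sprintf("%d empty document(s); all categories set to 0",
                    sum(lengths(toks) == 0L)))
  exact <- lapply(lexicon, function(p) p[!grepl("\\*$", p)])
  stems <- lapply(lexicon, function(p) sub("\\*$", "", p[grepl("\\*$", p)]))
  out <- matrix(0, nrow = length(docs), ncol = length(lexicon),
                dimnames = list(NULL, names(lexicon)))
  for (d in seq_along(toks)) {
    t <- toks[[d]]
    if (length(t) == 0L) next
    for (j in seq_along(lexicon)) {
      hit <- t %in% exact[[j]]
      for (s in stems[[j]]) hit <- hit | startsWith(t, s)
      out[d, j] <- 100 * sum(hit) / length(t)
    }
  }
  out
}

#' Split months into high and low consultation groups
#'
#' Median split on the normalized monthly consultation rate: months above
#' the median go to the Hi group, months below to Lo, and months exactly at
#' the median are assigned alternately to whichever group is currently
#' smaller so the sizes differ by at most one. If posts are supplied, each
#' group also collects the documents of its months.
#'
#' @param rate A `monthly_series` of kind `rate_percent` (>= 4 months).
#' @param posts Optional `post_stream` whose texts are grouped by month.
#' @return A `median_split`: `hi_months`, `lo_months`, `threshold`, and
#'   (with posts) `hi_docs`, `lo_docs`.
#' @export
median_split <- function(rate, posts = NULL) {
  stopifnot(inherits(rate, "monthly_series"))
  if (nrow(rate) < 4L) stop("need at least 4 months for a median split")
  v <- rate$value
  if (stats::sd(v) == 0) stop("degenerate split: all months have equal rate")
  med <- stats::median(v)
  hi <- rate$month[v > med]
  lo <- rate$month[v < med]
  for (m in rate$month[v == med]) {
    if (length(hi) < length(lo)) hi <- c(hi, m)
    else if (length(lo) < length(hi)) lo <- c(lo, m)
    else lo <- c(lo, m)  # balanced: start filling from Lo (<= median)
  }
  out <- list(hi_months = sort(hi), lo_months = sort(lo), threshold = med)
  if (!is.null(posts)) {
    mlab <- format(posts$timestamp, "%Y-%m")
    out$hi_docs <- posts$text[mlab %in% out$hi_months]
    out$lo_docs <- posts$text[mlab %in% out$lo_months]
  }
  structure(out, class = "median_split")
}

#' @exportS3Method base::print
print.median_split <- function(x, ...) {
  cat(sprintf("<median_split> threshold %.3f: %d Hi months, %d Lo months\n",
              x$threshold, length(x$hi_months), length(x$lo_months)))
  invisible(x)
}

#' Compare category profiles between Hi and Lo groups
#'
#' Welch two-sample t test per category of the per-document normalized
#' percentages, signed Hi minus Lo, followed by false-discovery-rate
#' adjustment across categories — by default the Benjamini-Yekutieli
#' step-up variant valid under arbitrary dependence (with its harmonic
#' correction factor), with plain Benjamini-Hochberg available. Categories
#' with zero variance in both groups are flagged and excluded from testing.
#'
#' @param hi_profiles,lo_profiles Matrices from [lexicon_profile()] with the
#'   same categories (>= 2 documents each).
#' @param method `"BY"` (default) or `"BH"`.
#' @param alpha Significance level on the adjusted p-values.
#' @return A `category_comparison` data frame: `category`, `mean_hi`,
#'   `mean_lo`, `t`, `p_value`, `p_adjusted`, `significant`, `degenerate`.
#' @export
compare_categories <- function(hi_profiles, lo_profiles,
                               method = c("BY", "BH"), alpha = 0.05) {
  method <- match.arg(method)
  if (!identical(colnames(hi_profiles), colnames(lo_profiles)))
    stop("profiles must share the same categories")
  if (nrow(hi_profiles) < 2L || nrow(lo_profiles) < 2L)
    stop("need at least 2 documents per group")
  cats <- colnames(hi_profiles)
  t_stat <- p_raw <- rep(NA_real_, length(cats))
  degenerate <- logical(length(cats))
  for (j in seq_along(cats)) {
    a <- hi_profiles[, j]; b <- lo_profiles[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degenerate[j] <- TRUE
      next
    }
    tt <- stats::t.test(a, b)
    t_stat[j] <- unname(tt$statistic)
    p_raw[j] <- tt$p.value
  }
  p_adj <- rep(NA_real_, length(cats))
  ok <- !degenerate
  p_adj[ok] <- stats::p.adjust(p_raw[ok], method = method)
  out <- data.frame(category = cats,
                    mean_hi = colMeans(hi_profiles),
                    mean_lo = colMeans(lo_profiles),
                    t = t_stat, p_value = p_raw, p_adjusted = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("category_comparison", "data.frame")
  out
}
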