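#' Read and write post streams as JSONL
#'
#' One post per line with fields `id`, `timestamp` (ISO-8601 UTC), `author`,
#' `text`, plus any integer label columns already attached.
#'
#' @param posts A `post_stream` data frame.
#' @param path File path.
#' @return `write_posts_jsonl` returns `path` invisibly; `read_posts_jsonl`
#'   returns a `post_stream`.
#' @export
write_posts_jsonl <- function(posts, path) {
  df <- as.data.frame(posts)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ")
  structure(df, months = sort(unique(format(df$timestamp, "%Y-%m"))),
            class = c("post_stream", "data.frame"))
}

#' Read and write the consultation CSV
#'
#' Format: header `month,visits,enrollment`, month as `YYYY-MM`.
#'
#' @param tab Data frame from [consultation_table()].
#' @param path File path.
#' @return `read_consultations_csv` returns the data frame;
#'   `write_consultations_csv` returns `path` invisibly.
#' @export
write_consultations_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_consultations_csv
#' @export
read_consultations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(month = "character"))
  need <- c("month", "visits", "enrollment")
  if (!all(need %in% names(df)))
    stop("consultation CSV must have columns month,visits,enrollment")
  df
}

#' Write/read training corpora as plain-text directories
#'
#' One subdirectory per outcome containing `pos_*.txt` files, a shared
#' `negatives` directory, and a `manifest.csv` listing every document.
#'
#' @param corpora As from [gen_training_corpora()].
#' @param dir Target directory (created if absent).
#' @return `write_corpora` returns `dir` invisibly; `read_corpora` the
#'   corpora list.
#' @export
write_corpora <- function(corpora, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (o in names(corpora$positives)) {
    d <- file.path(dir, o)
    dir.create(d, showWarnings = FALSE)
    files <- sprintf("pos_%04d.txt", seq_along(corpora$positives[[o]]))
    for (i in seq_along(files))
      writeLines(corpora$positives[[o]][i], file.path(d, files[i]))
    manifest[[o]] <- data.frame(outcome = o, class = "positive",
                                file = file.path(o, files))
  }
  d <- file.path(dir, "negatives")
  dir.create(d, showWarnings = FALSE)
  files <- sprintf("neg_%04d.txt", seq_along(corpora$negatives))
  for (i in seq_along(files))
    writeLines(corpora$negatives[i], file.path(d, files[i]))
  manifest$negatives <- data.frame(outcome = "", class = "negative",
                                   file = file.path("negatives", files))
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_corpora
#' @export
read_corpora <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  read_doc <- function(f) paste(readLines(file.path(dir, f), warn = FALSE),
                                collapse = " ")
  pos <- manifest[manifest$class == "positive", ]
  positives <- lapply(split(pos$file, pos$outcome),
                      function(fs) vapply(fs, read_doc, "", USE.NAMES = FALSE))
  neg <- manifest[manifest$class == "negative", ]
  list(positives = positives,
       negatives = vapply(neg$file, read_doc, "", USE.NAMES = FALSE))
}

#' Write a monthly series (or several) as CSV
#'
#' Single series: `month,value`. A named list of series sharing a month
#' index: `month,<name1>,<name2>,...` (the multi-outcome prevalence layout).
#'
#' @param x A `monthly_series` or named list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  if (inherits(x, "monthly_series")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  } else {
    months <- x[[1L]]$month
    df <- data.frame(month = months)
    for (nm in names(x)) df[[nm]] <- x[[nm]]$value[match(months, x[[nm]]$month)]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a monthly series CSV
#'
#' @param path File path to a `month,value` or multi-column CSV.
#' @param kind Kind tag for the resulting series.
#' @return A `monthly_series` (single value column) or named list of them.
#' @export
read_series_csv <- function(path, kind = "other") {
  df <- utils::read.csv(path, colClasses = "character")
  vals <- lapply(df[-1L], as.numeric)
  if (length(vals) == 1L) return(monthly_series(df$month, vals[[1L]], kind))
  lapply(vals, function(v) monthly_series(df$month, v, kind))
}
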