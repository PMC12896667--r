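#' Per-second behavior annotation series
#'
#' An annotation series holds one behavior label per observed second for a
#' single individual, either from manual coding or from the automated
#' classifier. Seconds must be contiguous over the observation window and
#' every label must come from the declared category set.
#'
#' @param individual Name of the observed individual.
#' @param time_s Integer vector of observed seconds (contiguous, increasing).
#' @param behavior Character vector of labels, same length as `time_s`.
#' @param categories Declared category set. Defaults to the union of labels
#'   present, in order of first appearance.
#' @return A data frame of class `annotation_series` with columns
#'   `individual`, `time_s`, `behavior` and a `categories` attribute.
#' @examples
#' annotation_series("female", 0:3,
#'                   c("Standing", "Standing", "Lying Down", "Standing"))
#' @export
annotation_series <- function(individual, time_s, behavior,
                              categories = unique(behavior)) {
  if (length(time_s) != length(behavior)) {
    stop("`time_s` and `behavior` must have the same length", call. = FALSE)
  }
  time_s <- as.integer(time_s)
  if (length(time_s) > 1L && any(diff(time_s) != 1L)) {
    stop("annotation seconds must be contiguous", call. = FALSE)
  }
  bad <- setdiff(unique(behavior), categories)
  if (length(bad)) {
    stop("labels outside the declared category set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(individual = rep_len(as.character(individual),
                                         length(time_s)),
                    time_s = time_s, behavior = as.character(behavior),
                    stringsAsFactors = FALSE)
  attr(out, "categories") <- categories
  class(out) <- c("annotation_series", "data.frame")
  out
}

#' Read and write annotation CSV files
#'
#' Annotations are exchanged as comma-separated text with a header and
#' columns `individual`, `time_s`, `behavior` (UTF-8).
#'
#' @param path File path.
#' @param categories Optional category set to declare on read; defaults to
#'   the labels present.
#' @return `read_annotation_csv()` returns a list of [annotation_series()],
#'   one per individual; `write_annotation_csv()` returns `path` invisibly.
#' @export
read_annotation_csv <- function(path, categories = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("individual", "time_s", "behavior")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$individual), function(d) {
    d <- d[order(d$time_s), ]
    annotation_series(d$individual[1L], d$time_s, d$behavior,
                      categories = categories %||% unique(d$behavior))
  })
}

#' @param series An [annotation_series()] or list of them.
#' @rdname read_annotation_csv
#' @export
write_annotation_csv <- function(series, path) {
  if (inherits(series, "annotation_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) as.data.frame(s)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
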