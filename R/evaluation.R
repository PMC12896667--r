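EVAL_CATEGORIES <- c("Standing", "Lying Down", "Foraging/Feeding",
                     "Locomotion", "Out of View/Not Labeled")

default_category_map <- function() {
  c("Out of View" = "Out of View/Not Labeled",
    "Out of Sight" = "Out of View/Not Labeled",
    "Not Labeled" = "Out of View/Not Labeled")
}

#' Build a multi-class confusion matrix (predicted vs manual)
#'
#' Counts agreement between an automated and a manual annotation series
#' over their common seconds. The manual "Out of View"/"Out of Sight"
#' category and the predicted "Not Labeled" category describe the same
#' state (no usable observation) and are paired as one axis category on
#' both sides, as is conventional when validating automated coders.
#'
#' @param manual,predicted [annotation_series()] for the same individual
#'   with overlapping seconds.
#' @param category_map Named character vector mapping raw labels to axis
#'   categories; defaults to the Out-of-View/Not-Labeled pairing.
#' @param categories Axis category order.
#' @return A `confusion_matrix`: integer matrix, rows = predicted,
#'   columns = manual, with `n` (grand total) attribute.
#' @export
build_confusion <- function(manual, predicted,
                            category_map = default_category_map(),
                            categories = EVAL_CATEGORIES) {
  common <- intersect(manual$time_s, predicted$time_s)
  if (!length(common)) {
    stop("no overlapping seconds between manual and predicted series",
         call. = FALSE)
  }
  remap <- function(lab) {
    hit <- lab %in% names(category_map)
    lab[hit] <- category_map[lab[hit]]
    lab
  }
  m <- remap(manual$behavior[match(common, manual$time_s)])
  p <- remap(predicted$behavior[match(common, predicted$time_s)])
  bad <- setdiff(unique(c(m, p)), categories)
  if (length(bad)) {
    stop("labels not covered by `categories` or `category_map`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(p, levels = categories),
              factor(m, levels = categories))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("predicted", "manual")
  confusion_matrix(cm)
}

#' @param counts Square integer matrix, rows = predicted, columns = manual.
#' @rdname build_confusion
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (any(counts < 0)) stop("invalid matrix: negative counts",
                            call. = FALSE)
  structure(counts, n = sum(counts),
            class = c("confusion_matrix", class(counts)))
}

#' Per-class performance metrics from a confusion matrix
#'
#' One-vs-rest decomposition per category: `TP` the diagonal cell, `FP`
#' the rest of the predicted row, `FN` the rest of the manual column, `TN`
#' everything else. From these, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy `(TP+TN)/total`, and
#' the True Skill Statistic `TSS = sensitivity + specificity - 1` (1 =
#' perfect, 0 = random, negative = worse than random). Ratios with a zero
#' denominator are reported as `NaN`, never silently 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per category and columns `category`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `accuracy`, `sensitivity`,
#'   `specificity`, `tss`.
#' @examples
#' cm <- confusion_matrix(diag(c(5, 7, 3)))
#' per_class_metrics(cm)  # all metrics 1
#' @export
per_class_metrics <- function(cm) {
  cm <- confusion_matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(a, b) ifelse(b == 0, NaN, a / b)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  cats <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  data.frame(category = cats, tp = tp, fp = fp, fn = fn, tn = tn,
             precision = safe_div(tp, tp + fp),
             accuracy = (tp + tn) / total,
             sensitivity = sens, specificity = spec,
             tss = sens + spec - 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative time budget of an annotation series
#'
#' Seconds spent in each category (the cumulative duration of each
#' behavior over the observation window).
#'
#' @param series An [annotation_series()].
#' @param categories Category order for the result; defaults to the
#'   series' declared categories.
#' @return Named integer vector of durations summing to the series length.
#' @export
cumulative_budget <- function(series,
                              categories = attr(series, "categories")) {
  tab <- table(factor(series$behavior, levels = categories))
  stats::setNames(as.integer(tab), categories)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement of `m` raters ranking the same `n` items, with mid-rank tie
#' handling and the tie-corrected denominator:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j}}
#' where `S` is the sum of squared deviations of the item rank-sums from
#' their mean and `T_j = sum(t^3 - t)` over rater `j`'s tie groups.
#' Significance uses the large-sample chi-squared approximation
#' `chi2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' Here the raters are typically the manual and the automated coder and
#' the items the per-category cumulative durations of a time budget.
#'
#' @param durations Numeric `m x n` matrix: one row per rater, one column
#'   per item.
#' @return A list of class `concordance_result`: `W`, `chi2`, `df`, `p`,
#'   `m`, `n`. When every rater ties all items the denominator is zero and
#'   `W` is reported as `NA` with a warning.
#' @examples
#' kendalls_w(rbind(c(10, 20, 30, 40, 50), c(12, 18, 33, 38, 55)))
#' @export
kendalls_w <- function(durations) {
  x <- as.matrix(durations)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L || n < 2L) {
    stop("need at least 2 raters and 2 items", call. = FALSE)
  }
  r <- t(apply(x, 1L, rank))          # mid-rank ties within each rater
  rank_sums <- colSums(r)
  s <- sum((rank_sums - mean(rank_sums))^2)
  ties <- sum(apply(r, 1L, function(ri) {
    t <- table(ri); sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * ties
  if (denom <= 0) {
    warning("W undefined: every rater ties all items (zero denominator)",
            call. = FALSE)
    w <- NA_real_; chi2 <- NA_real_; p <- NA_real_
  } else {
    w <- 12 * s / denom
    chi2 <- m * (n - 1) * w
    p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
  }
  structure(list(W = w, chi2 = chi2, df = n - 1L, p = p, m = m, n = n),
            class = "concordance_result")
}

#' Significance of a reported concordance value
#'
#' Maps a Kendall's W value straight to its chi-squared statistic and
#' p-value (`chi2 = m (n - 1) W` on `n - 1` df), without access to the
#' underlying rankings — useful for checking published W values.
#'
#' @param W Concordance coefficient in `[0, 1]`.
#' @param m Number of raters.
#' @param n Number of ranked items.
#' @return A `concordance_result` list.
#' @examples
#' concordance_significance(0.95, m = 2, n = 5)$p  # ~0.107
#' @export
concordance_significance <- function(W, m, n) {
  stopifnot_scalar_number(W, "W", 0, 1)
  chi2 <- m * (n - 1) * W
  structure(list(W = W, chi2 = chi2, df = as.integer(n - 1),
                 p = stats::pchisq(chi2, df = n - 1, lower.tail = FALSE),
                 m = as.integer(m), n = as.integer(n)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall's W = %.3f (m = %d raters, n = %d items)\n",
              x$W, x$m, x$n))
  cat(sprintf("chi-squared = %.3f, df = %d, p = %.3f\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
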