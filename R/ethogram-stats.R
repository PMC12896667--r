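#' Time budget of an annotation series
#'
#' Proportion of observed time spent in each behavior category, after
#' removing excluded categories (by default the out-of-sight/not-labeled
#' seconds, which carry no behavioral information) and renormalizing over
#' what remains.
#'
#' @param series An [annotation_series()].
#' @param exclude Categories removed before normalization.
#' @param period Optional period tag (`"control"`/`"test"`) carried on the
#'   result.
#' @return A list of class `time_budget`: `individual`, `period`,
#'   `proportions` (named, summing to 1), `observed_s`.
#' @examples
#' s <- annotation_series("a", 0:9, rep(c("Standing", "Lying Down"), 5))
#' time_budget(s)$proportions
#' @export
time_budget <- function(series,
                        exclude = c("Out of Sight", "Out of View",
                                    "Not Labeled",
                                    "Out of View/Not Labeled"),
                        period = NA_character_) {
  cats <- setdiff(attr(series, "categories"), exclude)
  kept <- series$behavior[!series$behavior %in% exclude]
  if (!length(kept)) stop("no observed time: every second excluded",
                          call. = FALSE)
  tab <- table(factor(kept, levels = cats))
  props <- stats::setNames(as.vector(tab) / length(kept), cats)
  structure(list(individual = series$individual[1L], period = period,
                 proportions = props, observed_s = length(kept)),
            class = "time_budget")
}

#' Daily median proportion for one cell of a daily table
#'
#' Median across observation days of one individual's proportion of time
#' in one category during one period; daily medians reduce temporal
#' autocorrelation and unequal sampling effort before between-period
#' testing.
#'
#' @param table Daily table as produced by [simulate_study_table()]
#'   (columns `individual`, `period`, `day`, `category`, `proportion`).
#' @param individual,period,category Cell selectors.
#' @return The median proportion (mean of the central pair for an even
#'   number of days).
#' @export
daily_medians <- function(table, individual, period, category) {
  v <- table$proportion[table$individual == individual &
                          table$period == period &
                          table$category == category]
  if (!length(v)) stop("no days match the requested cell", call. = FALSE)
  stats::median(v)
}

#' Mann-Whitney U test (rank-sum, normal approximation)
#'
#' U is computed from rank sums with mid-rank ties; the p-value uses the
#' normal approximation with tie correction and continuity correction
#' (the common software default, retained even for small day counts). An
#' exact p-value is available for tie-free samples via `exact = TRUE`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to `x` relative to `y`.
#' @param exact Use the exact null distribution (tie-free data only;
#'   falls back to the approximation with a warning otherwise).
#' @return List with `U` (statistic for `x`), `p`, `alternative`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$U  # 0: complete separation
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "less", "greater"),
                         exact = FALSE) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- length(unique(c(x, y))) < n
  if (exact && !has_ties) {
    p <- switch(alternative,
                two.sided = {
                  pp <- if (u > nx * ny / 2) {
                    stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
                  } else {
                    stats::pwilcox(u, nx, ny)
                  }
                  min(1, 2 * pp)
                },
                greater = stats::pwilcox(u - 1, nx, ny,
                                         lower.tail = FALSE),
                less = stats::pwilcox(u, nx, ny))
    return(list(U = u, p = p, alternative = alternative, exact = TRUE))
  }
  if (exact && has_ties) {
    warning("ties present; using the normal approximation",
            call. = FALSE)
  }
  mu <- nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations tied: no information against the null
    return(list(U = u, p = 1, alternative = alternative, exact = FALSE))
  }
  z <- u - mu
  corr <- switch(alternative, two.sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
  z <- (z - corr) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(stats::pnorm(z),
                                         stats::pnorm(z,
                                                      lower.tail = FALSE))),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(U = u, p = p, alternative = alternative, exact = FALSE)
}

#' Pearson chi-squared test on two category-count vectors
#'
#' Tests whether two behavioral distributions (e.g., second-counts per
#' category in the control vs test period) differ, via the Pearson
#' statistic on the 2 x k contingency table. Expected counts are returned
#' so users can check the approximation's validity. No continuity
#' correction is applied.
#'
#' @param counts_a,counts_b Non-negative count vectors over the same
#'   categories.
#' @return List with `statistic`, `df` (`k - 1`), `p`, `expected` (2 x k
#'   matrix).
#' @export
chi_square_counts <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors must cover the same categories", call. = FALSE)
  }
  k <- length(counts_a)
  if (k < 2L) stop("test undefined with a single category (df = 0)",
                   call. = FALSE)
  tab <- rbind(a = as.numeric(counts_a), b = as.numeric(counts_b))
  if (any(tab < 0) || any(rowSums(tab) == 0)) {
    stop("counts must be non-negative with positive totals", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- colSums(tab) > 0
  stat <- sum((tab[, keep] - expected[, keep])^2 / expected[, keep])
  df <- k - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Fligner-Killeen test of homogeneity of variances
#'
#' Rank-based dispersion comparison across groups, robust to non-normal
#' behavioral data: absolute deviations from each group's median are
#' pooled and ranked, ranks are mapped through normal quantile scores
#' `a(r) = qnorm(1/2 + r / (2(N + 1)))`, and the statistic
#' `sum_j n_j (Abar_j - abar)^2 / V` (V the sample variance of all
#' scores) is referred to chi-squared with `k - 1` df.
#'
#' @param groups List of numeric vectors, one per group (each of length
#'   at least 2).
#' @return List with `statistic`, `df`, `p`.
#' @export
fligner_killeen <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 groups with at least 2 values each",
         call. = FALSE)
  }
  dev <- lapply(groups, function(g) abs(g - stats::median(g)))
  n_j <- lengths(dev)
  pooled <- unlist(dev, use.names = FALSE)
  n <- length(pooled)
  a <- stats::qnorm(0.5 + rank(pooled) / (2 * (n + 1)))
  grp <- rep(seq_along(dev), n_j)
  abar_j <- tapply(a, grp, mean)
  abar <- mean(a)
  v <- stats::var(a)
  stat <- sum(n_j * (abar_j - abar)^2) / v
  df <- length(groups) - 1L
  list(statistic = unname(stat), df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Between-period comparisons over a daily table
#'
#' Convenience wrapper running, per individual and category, a
#' Mann-Whitney U test (on daily proportions, control vs test) or a
#' Fligner-Killeen test (dispersion across the two periods). Raw
#' p-values are reported; Benjamini-Hochberg adjustment is available but
#' off by default, matching the convention of reporting unadjusted
#' non-parametric results in small enrichment studies.
#'
#' @param daily Daily table (columns `individual`, `period`, `day`,
#'   `category`, `proportion`).
#' @param method `"mann-whitney"` or `"fligner-killeen"`.
#' @param adjust Apply Benjamini-Hochberg correction across categories
#'   within each individual.
#' @return Tidy data frame: `individual`, `category`, `statistic`, `p`
#'   (and `p_adj` when `adjust = TRUE`).
#' @export
compare_periods <- function(daily,
                            method = c("mann-whitney",
                                       "fligner-killeen"),
                            adjust = FALSE) {
  method <- match.arg(method)
  combos <- unique(daily[c("individual", "category")])
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    ind <- combos$individual[i]; cat_ <- combos$category[i]
    sel <- daily$individual == ind & daily$category == cat_
    ctl <- daily$proportion[sel & daily$period == "control"]
    tst <- daily$proportion[sel & daily$period == "test"]
    out <- if (method == "mann-whitney") {
      mw <- mann_whitney(ctl, tst)
      c(statistic = mw$U, p = mw$p)
    } else {
      fk <- fligner_killeen(list(ctl, tst))
      c(statistic = fk$statistic, p = fk$p)
    }
    data.frame(individual = ind, category = cat_,
               statistic = out[["statistic"]], p = out[["p"]],
               stringsAsFactors = FALSE)
  }))
  if (adjust) {
    res$p_adj <- stats::ave(res$p, res$individual,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  rownames(res) <- NULL
  res
}
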