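#' Two-sided variance-ratio F test
#'
#' Compares the variances of two samples with the classical F statistic
#' F = s2_a / s2_b (sample variances with n - 1 denominators). The
#' two-sided p-value is 2 min(P(F <= f), P(F >= f)) under
#' F(n_a - 1, n_b - 1), capped at 1 -- the convention of the standard
#' variance-ratio test.
#'
#' @param a,b Numeric samples, each with at least two values; at least one
#'   must have nonzero variance.
#' @return An object of class `tc_test` with `statistic`, `p_value`, the
#'   degrees of freedom, sample sizes and a method label.
#' @export
f_test_variance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least two values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("degenerate samples: both variances are zero",
                               call. = FALSE)
  f <- va / vb
  df1 <- length(a) - 1; df2 <- length(b) - 1
  p <- min(1, 2 * min(stats::pf(f, df1, df2),
                      stats::pf(f, df1, df2, lower.tail = FALSE)))
  structure(list(statistic = f, p_value = p, df = c(df1 = df1, df2 = df2),
                 n_a = length(a), n_b = length(b),
                 method = "two-sided variance-ratio F test"),
            class = "tc_test")
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum location test. With a combined sample size of at most 20 and no
#' ties, the two-sided p-value is exact: the full null distribution of U is
#' enumerated (every assignment of pooled ranks equally likely) and
#' p = min(1, 2 min(P(U <= u), P(U >= u))). Larger or tied samples use the
#' mid-rank normal approximation with tie correction and continuity
#' correction; the `method` field records which path was taken.
#'
#' @param a,b Numeric samples, each non-empty.
#' @return A `tc_test` with the U statistic of the first sample, the
#'   two-sided p-value, sample sizes and method label.
#' @export
mann_whitney_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1)
    stop("empty sample", call. = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && na + nb <= 20) {
    cnt <- u_null_counts(na, nb)            # counts of U = 0..na*nb
    tot <- sum(cnt)
    lo <- sum(cnt[1:(u + 1)]) / tot
    hi <- sum(cnt[(u + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(lo, hi))
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    n <- na + nb
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) stop("degenerate samples: all values tied", call. = FALSE)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (mid-ranks, tie and continuity correction)"
  }
  structure(list(statistic = u, p_value = p, n_a = na, n_b = nb,
                 method = method),
            class = "tc_test")
}

# null distribution of the Mann-Whitney U statistic: number of ways to pick
# na of the pooled ranks so that U = u, for u = 0..na*nb (classic DP over
# the partition count; cached per (na, nb))
u_null_counts <- local({
  cache <- new.env(parent = emptyenv())
  function(na, nb) {
    key <- paste(na, nb)
    if (!is.null(cache[[key]])) return(cache[[key]])
    # f[m + 1, u + 1] = #subsets of size m with statistic u, built by
    # adding pooled elements one at a time (each new element is either in
    # sample a, raising u by the count of b-elements before it, or in b)
    umax <- na * nb
    f <- matrix(0, nrow = na + 1, ncol = umax + 1)
    f[1, 1] <- 1
    for (i in seq_len(na + nb)) {
      g <- f
      for (m in seq_len(min(i, na))) {
        nb_before <- i - m                     # b-elements below this a
        if (nb_before <= nb) {
          shift <- min(nb_before, nb)
          g[m + 1, (shift + 1):(umax + 1)] <-
            g[m + 1, (shift + 1):(umax + 1)] +
            f[m, 1:(umax + 1 - shift)]
        }
      }
      f <- g
    }
    cache[[key]] <- f[na + 1, ]
    f[na + 1, ]
  }
})

#' @export
print.tc_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p = %.4g (n_a = %d, n_b = %d)\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Per-station variance-ratio significance profile
#'
#' Runs the two-sided variance-ratio F test on the curvature samples of two
#' station series at every station common to both, flags stations with
#' p below `alpha`, and summarises the fraction of significant stations.
#' Following the study design, no multiple-testing correction is applied by
#' default; Benjamini-Hochberg adjustment can be requested.
#'
#' @param series_a,series_b `station_series` objects (see
#'   [collect_series()]); stations are matched by arc-length position. The
#'   two series normally describe the same part under two conditions, but
#'   cross-part comparisons (head vs tail) are allowed and are matched on
#'   the common station positions.
#' @param alpha Significance level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `significance_profile`: data frame `table`
#'   with `station_um`, `f_statistic`, `p_value`, `significant`, plus
#'   `percent_significant`, `n_stations`, `alpha`, sample sizes and the
#'   comparison label.
#' @export
station_significance <- function(series_a, series_b, alpha = 0.01,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(series_a, "station_series"),
            inherits(series_b, "station_series"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  common <- intersect(series_a$stations, series_b$stations)
  if (length(common) == 0)
    stop("no stations common to the two series", call. = FALSE)
  common <- sort(common)
  ia <- match(common, series_a$stations)
  ib <- match(common, series_b$stations)
  tests <- lapply(seq_along(common), function(j)
    f_test_variance(series_a$samples[ia[j], ], series_b$samples[ib[j], ]))
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- p_use < alpha
  tab <- data.frame(station_um = common,
                    f_statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                    p_value = p, significant = sig)
  structure(list(table = tab,
                 percent_significant = percent_significant(sig),
                 n_stations = length(common), alpha = alpha,
                 adjust = adjust,
                 n_a = ncol(series_a$samples), n_b = ncol(series_b$samples),
                 comparison = paste(series_a$condition_label, "vs",
                                    series_b$condition_label)),
            class = "significance_profile")
}

#' @export
print.significance_profile <- function(x, ...) {
  cat(sprintf("Significance profile: %s\n", x$comparison))
  cat(sprintf("  %d/%d stations significant (%.1f%%) at alpha = %g (F test%s)\n",
              sum(x$table$significant), x$n_stations, x$percent_significant,
              x$alpha,
              if (x$adjust == "BH") ", BH-adjusted" else ""))
  invisible(x)
}

#' Percentage of significant positions
#'
#' 100 times the fraction of `TRUE` flags, rounded half-up to one decimal
#' place (so 36 of 59 gives 61.0 and 12 of 21 gives 57.1).
#'
#' @param flags Logical vector, at least one element.
#' @return Percentage with one decimal place.
#' @export
percent_significant <- function(flags) {
  if (length(flags) == 0) stop("no flags", call. = FALSE)
  if (any(is.na(flags))) stop("NA flags", call. = FALSE)
  round_half_up(100 * sum(flags) / length(flags), 1)
}

# round half away from zero (for non-negative input: half-up), avoiding the
# round-half-even rule of base round()
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
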