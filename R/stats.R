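#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table (rows = groups,
#' columns = categories). With the margins fixed, the count in the first
#' cell follows a hypergeometric distribution; the two-sided p-value sums
#' the probabilities of all tables whose likelihood does not exceed that
#' of the observed table (minimum-likelihood rule, the convention of the
#' standard statistical environments). Probabilities are computed in log
#' space for stability. Also returns the sample odds ratio `(a d)/(b c)`.
#'
#' @param table 2x2 numeric matrix of non-negative integer counts, or the
#'   count `a` when `b`, `c`, `d` are given separately.
#' @param b,c,d Optional individual counts.
#' @return A `"ctph_test"`: list with `statistic` (odds ratio), `df`
#'   (`NA`), `p_two_sided`, `method`, `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 25, 12, 17), 2, 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else a <- table
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (sum(cnt) == 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- sum(cnt)

  or <- (a * d) / (b * c)   # may be Inf or NaN at zero cells
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    warning("a table margin is zero; p = 1 by convention")
    p <- 1
  } else {
    k <- max(0, c1 - r2):min(r1, c1)
    logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
    logp_obs <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
    # relative tolerance guards against ties broken by rounding
    p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
    p <- min(1, p)
  }
  structure(list(statistic = or, df = NA_real_, p_two_sided = p,
                 method = "Fisher's exact test (two-sided)",
                 table = matrix(cnt, 2, 2, byrow = TRUE)),
            class = "ctph_test")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test from raw samples or from summary statistics:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch--Satterthwaite degrees of freedom and a two-sided p-value
#' from the t distribution. Degenerate inputs (both sds zero) give p = 1
#' when the means agree and p = 0 (with a warning) when they differ.
#'
#' @param x,y Raw samples (numeric vectors), or `NULL` when summary
#'   statistics are supplied.
#' @param mean1,sd1,n1,mean2,sd2,n2 Summary statistics per group.
#' @return A `"ctph_test"`: list with `statistic` (t), `df`,
#'   `p_two_sided`, `method`, and per-group `n`.
#' @examples
#' welch_t(mean1 = 4.41, sd1 = 1.7, n1 = 29, mean2 = 4.91, sd2 = 2.1, n2 = 30)
#' @export
welch_t <- function(x = NULL, y = NULL,
                    mean1 = NULL, sd1 = NULL, n1 = NULL,
                    mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]; mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
  }
  if (!is.null(y)) {
    y <- y[is.finite(y)]; mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(mean2))
    stop("supply raw samples or complete summary statistics for both groups")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  if (se1 + se2 == 0) {
    if (mean1 == mean2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warning("zero variance in both groups with differing means; p = 0")
      t <- sign(mean1 - mean2) * Inf; df <- n1 + n2 - 2; p <- 0
    }
  } else {
    t <- (mean1 - mean2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(statistic = t, df = df, p_two_sided = p,
                 method = "Welch two-sample t-test (two-sided)",
                 n = c(n1 = n1, n2 = n2)),
            class = "ctph_test")
}

#' @export
print.ctph_test <- function(x, ...) {
  cat("<ctph_test>", x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.4g\n", x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.2f", x$df),
              x$p_two_sided))
  invisible(x)
}

#' Compare two cohorts of cell summaries
#'
#' Runs the categorical and continuous group comparisons on a table of
#' per-cell summaries: Fisher's exact test on the A-type/B-type phenotype
#' counts (ambiguous and unclassified cells excluded) and on
#' bursting/non-bursting counts, and Welch's t-tests on the named
#' continuous metrics, log-transforming event frequency and event duration
#' first (zeros handled by the half-minimum offset policy of
#' [transform_features()]). Groups with fewer than 2 usable cells flag the
#' row instead of computing it.
#'
#' @param summaries data.frame of per-cell summaries with a grouping
#'   column and optionally `ab_class` (`"A"`/`"B"`/...) and `bursting`
#'   (logical) columns.
#' @param group Name of the grouping column (default `"sex"`); the first
#'   two levels encountered are compared.
#' @param metrics Continuous metrics to compare with Welch's t-test.
#' @param log_metrics Metrics log-transformed before testing.
#' @return data.frame with columns `test`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `df`, `p`.
#' @export
cohort_compare <- function(summaries, group = "sex",
                           metrics = c("capacitance_pf",
                                       "membrane_potential_mv",
                                       "event_freq_hz", "event_duration_ms",
                                       "burst_factor"),
                           log_metrics = c("event_freq_hz",
                                           "event_duration_ms")) {
  stopifnot(is.data.frame(summaries), group %in% names(summaries))
  g <- as.character(summaries[[group]])
  lev <- unique(g)
  if (length(lev) < 2) stop("need two groups to compare")
  lev <- lev[1:2]
  rows <- list()
  add <- function(test, n1, n2, stat, df, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, group1 = lev[1], group2 = lev[2], n1 = n1, n2 = n2,
      statistic = stat, df = df, p = p, stringsAsFactors = FALSE)

  if ("ab_class" %in% names(summaries)) {
    ab <- summaries$ab_class
    keep <- ab %in% c("A", "B")
    tab <- matrix(c(sum(ab == "A" & g == lev[1] & keep),
                    sum(ab == "B" & g == lev[1] & keep),
                    sum(ab == "A" & g == lev[2] & keep),
                    sum(ab == "B" & g == lev[2] & keep)), 2, 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    add("fisher_ab", sum(tab[1, ]), sum(tab[2, ]),
        ft$statistic, NA_real_, ft$p_two_sided)
  }
  if ("bursting" %in% names(summaries)) {
    bu <- as.logical(summaries$bursting)
    tab <- matrix(c(sum(bu & g == lev[1]), sum(!bu & g == lev[1]),
                    sum(bu & g == lev[2]), sum(!bu & g == lev[2])),
                  2, 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    add("fisher_bursting", sum(tab[1, ]), sum(tab[2, ]),
        ft$statistic, NA_real_, ft$p_two_sided)
  }
  for (mcol in intersect(metrics, names(summaries))) {
    x <- summaries[[mcol]][g == lev[1]]
    y <- summaries[[mcol]][g == lev[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (mcol %in% log_metrics) {
      all_v <- c(x, y)
      if (any(all_v < 0)) stop("negative values in log metric ", mcol)
      eps <- if (any(all_v == 0)) min(all_v[all_v > 0]) / 2 else 0
      x <- log(x + eps); y <- log(y + eps)
    }
    if (length(x) < 2 || length(y) < 2) {
      add(paste0("welch_", mcol), length(x), length(y),
          NA_real_, NA_real_, NA_real_)
    } else {
      wt <- welch_t(x, y)
      add(paste0("welch_", mcol), length(x), length(y),
          wt$statistic, wt$df, wt$p_two_sided)
    }
  }
  do.call(rbind, rows)
}
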