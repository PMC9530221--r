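#' Two-sided paired t-test
#'
#' Classical paired t on within-subject differences (df = n - 1). Pairs
#' with a missing value in either condition are dropped pairwise; the
#' number retained is reported.
#'
#' @param a,b numeric vectors, aligned by subject.
#' @return list with `t`, `p`, `df`, `mean_diff`, `n_pairs`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1,
                                 mean_diff = 0, n_pairs = n))
    stop("differences have zero variance")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = unname(ht$estimate), n_pairs = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied within one family of tests.
#'
#' @param pvals numeric vector in [0, 1] (NAs passed through).
#' @return adjusted p-values, same length and order.
#' @export
bh_correct <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Relative difference between two conditions
#'
#' `(a - b) / (a + b)`; lies in [-1, 1] for nonnegative inputs. Used for
#' per-subject drug-vs-placebo changes so that subjects with different
#' absolute scales are comparable.
#'
#' @param a,b numeric scalars or vectors (a = drug, b = placebo, say).
#' @return elementwise relative difference.
#' @export
relative_difference <- function(a, b) {
  s <- a + b
  if (any(s == 0, na.rm = TRUE)) stop("a + b must be nonzero")
  (a - b) / s
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' out the covariate (with intercept); two-sided p from the t
#' approximation with n - 3 degrees of freedom. With a constant covariate
#' the residuals are the demeaned data, so the result equals the plain
#' Pearson correlation.
#'
#' @param x,y,covariate numeric vectors of equal length (>= 4).
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n, n >= 4)
  keep <- stats::complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete cases")
  rx <- stats::residuals(stats::lm(x ~ covariate))
  ry <- stats::residuals(stats::lm(y ~ covariate))
  if (stats::sd(rx) <= 1e-10 * max(1, stats::sd(x)) ||
      stats::sd(ry) <= 1e-10 * max(1, stats::sd(y)))
    stop("residuals are constant; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 3
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df, n = n)
}

#' Group-level paired comparison report
#'
#' Runs a two-sided paired t-test for every metric unit (state, transition
#' pair, ...) comparing two conditions, with Benjamini-Hochberg correction
#' applied within each metric family.
#'
#' @param df long data.frame with columns `subject_id`, `condition`,
#'   `metric`, `unit`, `value`.
#' @param condition_a,condition_b condition labels to contrast
#'   (a vs. b; positive t means a > b).
#' @return data.frame: `metric`, `unit`, `mean_a`, `mean_b`, `t`, `p`,
#'   `p_adj`, `n_pairs`, one row per metric x unit.
#' @export
group_report <- function(df, condition_a, condition_b) {
  needed <- c("subject_id", "condition", "metric", "unit", "value")
  if (!all(needed %in% names(df))) stop("df lacks required columns")
  df <- df[df$condition %in% c(condition_a, condition_b), ]
  if (nrow(df) == 0) stop("no rows for the requested conditions")
  out <- NULL
  for (m in unique(df$metric)) {
    dm <- df[df$metric == m, ]
    rows <- NULL
    for (u in unique(dm$unit)) {
      du <- dm[dm$unit == u, ]
      wa <- du[du$condition == condition_a, ]
      wb <- du[du$condition == condition_b, ]
      subj <- intersect(wa$subject_id, wb$subject_id)
      a <- wa$value[match(subj, wa$subject_id)]
      b <- wb$value[match(subj, wb$subject_id)]
      tt <- tryCatch(paired_ttest(a, b), error = function(e) NULL)
      if (is.null(tt)) next
      rows <- rbind(rows, data.frame(
        metric = m, unit = u,
        mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
        t = tt$t, p = tt$p, n_pairs = tt$n_pairs))
    }
    if (!is.null(rows)) {
      rows$p_adj <- bh_correct(rows$p)
      out <- rbind(out, rows)
    }
  }
  if (is.null(out)) stop("no testable metric units")
  rownames(out) <- NULL
  out
}
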