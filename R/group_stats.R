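# Group-level inference wrappers: one-sample/paired t, Wilcoxon signed-rank
# and Spearman correlation, all two-sided, returned in one uniform shape.

group_stat <- function(test, statistic, df, p, n) {
  list(test = test, statistic = unname(statistic), df = unname(df),
       p = unname(p), n = n)
}

#' One-sample t test
#'
#' Two-sided t test of the mean of `x` against `popmean`.
#'
#' @param x Numeric vector (n >= 2, non-zero variance).
#' @param popmean Null-hypothesis mean.
#' @return A list with `test`, `statistic`, `df` (n - 1), `p`, `n`.
#' @export
one_sample_t <- function(x, popmean = 0) {
  if (length(x) < 2) stop("need n >= 2")
  if (stats::sd(x) == 0) stop("zero variance")
  r <- stats::t.test(x, mu = popmean)
  group_stat("one-sample t", r$statistic, r$parameter, r$p.value, length(x))
}

#' Paired t test
#'
#' One-sample t test of the differences `x - y` against 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return As [one_sample_t()].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  r <- one_sample_t(x - y, 0)
  r$test <- "paired t"
  r
}

# paired t that degenerates gracefully when the differences are constant
# (identical model errors across subjects give a 0/1 statistic/p rather
# than a zero-variance error)
safe_paired_t <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) {
    s <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(group_stat("paired t", s, length(d) - 1,
                      if (s == 0) 1 else 0, length(d)))
  }
  paired_t(x, y)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of `x` against `popmean`: exact null
#' distribution for n <= 25 (no ties/zeros), normal approximation above.
#' Offered as the non-parametric counterpart of the one-sample t test.
#'
#' @param x Numeric vector.
#' @param popmean Null-hypothesis center of symmetry.
#' @return A list with `test`, `statistic` (V), `df` (NA), `p`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, popmean = 0) {
  d <- x - popmean
  if (all(d == 0)) stop("all differences zero")
  exact <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  r <- stats::wilcox.test(x, mu = popmean, exact = exact, correct = !exact)
  out <- group_stat("wilcoxon signed-rank", r$statistic, NA_real_,
                    r$p.value, length(x))
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, p-value via the t approximation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  r <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(r$estimate), p = r$p.value, n = length(x))
}
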