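#' One-sample t-test
#'
#' `t = (mean - mu) / (sd / sqrt(n))`, `df = n - 1`. Decoding accuracies are
#' tested one-tailed against chance (`mu = 1/3` for three memories) because
#' only above-chance decoding is of interest; `one_tailed = FALSE` gives the
#' two-tailed p.
#'
#' @param values numeric vector (n >= 2, non-zero variance).
#' @param mu null-hypothesis mean.
#' @param one_tailed if `TRUE` (default), p for mean > mu.
#' @return list with `t`, `df`, `p`.
#' @export
t_one_sample <- function(values, mu, one_tailed = TRUE) {
  n <- length(values)
  if (n < 2L) stop("need n >= 2")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  t <- (mean(values) - mu) / (s / sqrt(n))
  df <- n - 1L
  p <- if (one_tailed) stats::pt(t, df, lower.tail = FALSE)
       else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Paired t-test
#'
#' One-sample t-test on the element-wise differences `a - b` against 0;
#' two-tailed by default (the follow-up test for significant omnibus
#' effects).
#'
#' @param a,b paired numeric vectors of equal length.
#' @param two_tailed if `TRUE` (default), two-tailed p.
#' @return list with `t`, `df`, `p`.
#' @export
t_paired <- function(a, b, two_tailed = TRUE) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero variance of differences")
  t_one_sample(d, 0, one_tailed = !two_tailed)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way F-test on a complete subjects x conditions matrix:
#' `F = MS_condition / MS_(subject x condition)` with `df1 = c - 1`,
#' `df2 = (n - 1)(c - 1)`. No sphericity correction is applied (plain F).
#'
#' @param m numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_oneway <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells")
  n <- nrow(m); c <- ncol(m)
  if (n < 2L || c < 2L) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- c * sum((subj_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- c - 1L
  df2 <- (n - 1L) * (c - 1L)
  Fv <- if (ss_err <= 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / (ss_err / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' 2x2 within-subject interaction F-test
#'
#' Interaction between two within-subject two-level factors (e.g. study x
#' memory type), computed from the per-subject difference of differences:
#' `F = t^2` of the paired contrast `(a2 - a1) - (b2 - b1)`, with
#' `df = (1, n - 1)`.
#'
#' @param a1,a2 factor-A level-1/level-2 values under factor-B level 1.
#' @param b1,b2 the same under factor-B level 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_interaction_2x2 <- function(a1, a2, b1, b2) {
  d <- (a2 - a1) - (b2 - b1)
  if (stats::sd(d) == 0) return(list(F = 0, df1 = 1L,
                                     df2 = length(d) - 1L, p = 1))
  tt <- t_one_sample(d, 0, one_tailed = FALSE)
  list(F = tt$t^2, df1 = 1L, df2 = tt$df, p = tt$p)
}
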