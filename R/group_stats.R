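#' Paired repeated-measures ANOVA (one within factor, two levels)
#'
#' Equivalent to the square of the paired t test: `F = t^2` with
#' `df = (1, n - 1)` and partial eta squared `F / (F + n - 1)`.
#'
#' @param pre,post Equal-length numeric vectors, complete cases.
#' @return List: `f_stat`, `df_num`, `df_den`, `p_value`, `partial_eta_sq`,
#'   `n`.
#' @export
paired_rm_anova <- function(pre, post) {
  if (length(pre) != length(post)) stop_input("paired_rm_anova: unequal lengths")
  ok <- complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) stop_input("paired_rm_anova: need n >= 2 complete cases")
  d <- pre - post
  if (sd(d) <= .Machine$double.eps) {
    if (all(abs(d) < .Machine$double.eps)) {
      return(list(f_stat = 0, df_num = 1L, df_den = n - 1L, p_value = 1,
                  partial_eta_sq = 0, n = n))
    }
    stop_degenerate("paired_rm_anova: zero variance of nonzero differences")
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  f_stat <- t_stat^2
  list(f_stat = f_stat, df_num = 1L, df_den = n - 1L,
       p_value = pf(f_stat, 1, n - 1, lower.tail = FALSE),
       partial_eta_sq = f_stat / (f_stat + n - 1),
       n = n)
}

manova_result <- function(wilks_lambda, hotelling_t2, f_stat, df_num, df_den, n) {
  structure(list(wilks_lambda = wilks_lambda,
                 hotelling_t2 = hotelling_t2,
                 f_stat = f_stat, df_num = df_num, df_den = df_den,
                 p_value = pf(f_stat, df_num, df_den, lower.tail = FALSE),
                 partial_eta_sq = 1 - wilks_lambda,
                 n = n),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Multivariate test: F(%d, %d) = %.2f, %s; Wilks lambda = %.2f; partial eta^2 = %.2f\n",
              x$df_num, x$df_den, x$f_stat, format_p(x$p_value),
              x$wilks_lambda, x$partial_eta_sq))
  invisible(x)
}

solve_spd <- function(S, what) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out) || rcond(S) < 1e-12)
    stop_degenerate("%s: singular covariance matrix; remove a redundant outcome", what)
  chol2inv(out)
}

#' One-sample (repeated-measures) MANOVA on difference scores
#'
#' Hotelling's one-sample T2 on the mean of the difference vector:
#' \eqn{T^2 = n\,\bar d' S^{-1} \bar d}, Wilks
#' \eqn{\Lambda = 1/(1 + T^2/(n-1))}, exact
#' \eqn{F = T^2 (n-p) / (p (n-1))} with df \eqn{(p, n-p)}, and partial
#' \eqn{\eta^2 = 1 - \Lambda} (single-df multivariate effect).
#'
#' @param diff_matrix Numeric matrix, participants x outcomes, complete
#'   cases.
#' @return A `manova_result`.
#' @export
one_sample_manova <- function(diff_matrix) {
  D <- as.matrix(diff_matrix)
  D <- D[complete.cases(D), , drop = FALSE]
  n <- nrow(D); p <- ncol(D)
  if (p < 1L) stop_input("one_sample_manova: need at least one outcome")
  if (n <= p) stop_input("one_sample_manova: need n > p (n=%d, p=%d)", n, p)
  dbar <- colMeans(D)
  if (all(abs(D) < .Machine$double.eps))
    return(manova_result(1, 0, 0, p, n - p, n))
  Sinv <- solve_spd(var(D), "one_sample_manova")
  t2 <- n * drop(t(dbar) %*% Sinv %*% dbar)
  lambda <- 1 / (1 + t2 / (n - 1))
  f_stat <- t2 * (n - p) / (p * (n - 1))
  manova_result(lambda, t2, f_stat, p, n - p, n)
}

#' Two-group MANOVA (Hotelling's two-sample T2)
#'
#' \eqn{T^2 = \frac{n_1 n_2}{n_1+n_2}(\bar x_1-\bar x_2)' S_p^{-1}(\bar
#' x_1-\bar x_2)} with pooled covariance \eqn{S_p}; Wilks
#' \eqn{\Lambda = 1/(1 + T^2/(n_1+n_2-2))}, exact
#' \eqn{F = T^2 (n_1+n_2-p-1)/(p(n_1+n_2-2))} with df
#' \eqn{(p, n_1+n_2-p-1)}.  Applied to baseline scores this is the
#' between-group baseline test; applied to difference scores it is the
#' group x time interaction test.
#'
#' @param value_matrix Numeric matrix, participants x outcomes.
#' @param groups Vector with exactly two distinct labels.
#' @return A `manova_result`.
#' @export
two_group_manova <- function(value_matrix, groups) {
  X <- as.matrix(value_matrix)
  ok <- complete.cases(X) & !is.na(groups)
  X <- X[ok, , drop = FALSE]; groups <- groups[ok]
  g <- unique(groups)
  if (length(g) != 2L) stop_input("two_group_manova: need exactly two groups")
  X1 <- X[groups == g[1], , drop = FALSE]
  X2 <- X[groups == g[2], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X)
  if (n1 < 2L || n2 < 2L) stop_input("two_group_manova: each group needs >= 2 members")
  if (n1 + n2 - 2 <= p)
    stop_input("two_group_manova: need n1 + n2 - 2 > p")
  Sp <- ((n1 - 1) * var(X1) + (n2 - 1) * var(X2)) / (n1 + n2 - 2)
  Sinv <- solve_spd(Sp, "two_group_manova")
  dm <- colMeans(X1) - colMeans(X2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(dm) %*% Sinv %*% dm)
  lambda <- 1 / (1 + t2 / (n1 + n2 - 2))
  f_stat <- t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  manova_result(lambda, t2, f_stat, p, n1 + n2 - p - 1, n1 + n2)
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta^2_p = F \cdot df_1 / (F \cdot df_1 + df_2)}.
#'
#' @param f F statistic, non-negative.
#' @param df1,df2 Degrees of freedom, at least 1.
#' @return Partial eta squared in `[0, 1)`.
#' @export
partial_eta_from_f <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Partial eta squared from Wilks lambda (single-df multivariate effect)
#'
#' For one-sample pre-post and two-group designs, \eqn{\eta^2_p = 1 -
#' \Lambda}.
#'
#' @param wilks_lambda Lambda in `(0, 1]`.
#' @return Partial eta squared.
#' @export
eta_from_lambda <- function(wilks_lambda) {
  if (any(wilks_lambda <= 0 | wilks_lambda > 1))
    stop_input("eta_from_lambda: lambda must be in (0, 1]")
  1 - wilks_lambda
}

#' Baseline-stratified test of change scores
#'
#' Compares change (post - pre) between participants with problematic vs
#' healthy baseline status on one outcome, via an independent-samples t test
#' (Welch correction by default; pooled df available).  Cohen's d uses the
#' pooled SD of the change scores, since the comparison is between mean
#' changes.
#'
#' @param pre,post Score vectors.
#' @param problematic Logical vector: baseline-problematic stratum.
#' @param outcome Outcome name for error messages / output.
#' @param welch Use Welch's unequal-variance correction (default TRUE).
#' @return List of class `stratified_test`: group sizes, pre/post means and
#'   SDs per stratum, `t_stat`, `df` (non-integer under Welch), `p_value`,
#'   `cohen_d` (positive = larger change in the problematic stratum).
#' @export
baseline_stratified_change_test <- function(pre, post, problematic,
                                            outcome = "outcome", welch = TRUE) {
  ok <- complete.cases(pre, post, problematic)
  pre <- pre[ok]; post <- post[ok]; problematic <- as.logical(problematic[ok])
  ch <- post - pre
  g1 <- ch[problematic]; g0 <- ch[!problematic]
  if (length(g1) < 2L || length(g0) < 2L)
    stop_input("baseline_stratified_change_test('%s'): each stratum needs >= 2 members", outcome)
  tt <- t.test(g1, g0, var.equal = !welch)
  n1 <- length(g1); n0 <- length(g0)
  sp <- sqrt(((n1 - 1) * var(g1) + (n0 - 1) * var(g0)) / (n1 + n0 - 2))
  d <- if (sp <= .Machine$double.eps) 0 else (mean(g1) - mean(g0)) / sp
  structure(list(
    outcome = outcome, welch = welch,
    n_problematic = n1, n_healthy = n0,
    pre_mean_problematic = mean(pre[problematic]), pre_sd_problematic = sd(pre[problematic]),
    post_mean_problematic = mean(post[problematic]), post_sd_problematic = sd(post[problematic]),
    pre_mean_healthy = mean(pre[!problematic]), pre_sd_healthy = sd(pre[!problematic]),
    post_mean_healthy = mean(post[!problematic]), post_sd_healthy = sd(post[!problematic]),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, cohen_d = d), class = "stratified_test")
}

#' Mann-Whitney U robustness check
#'
#' Rank-sum test on change scores between two strata, reported alongside the
#' t test (never replacing it).  Wraps [stats::wilcox.test()]; `W` is the U
#' statistic for the first group.
#'
#' @param values Numeric vector (e.g. change scores).
#' @param groups Two-level grouping vector.
#' @return List: `u_stat`, `p_value`, `tied` (TRUE when ties prevented an
#'   exact p).
#' @export
mann_whitney_check <- function(values, groups) {
  g <- unique(groups[!is.na(groups)])
  if (length(g) != 2L) stop_input("mann_whitney_check: need exactly two groups")
  x <- values[groups == g[1]]; y <- values[groups == g[2]]
  if (length(unique(c(x, y))) == 1L)
    stop_degenerate("mann_whitney_check: all values tied")
  tied <- anyDuplicated(c(x, y)) > 0
  # exact null distribution only when tie-free and small; the normal
  # approximation is standard beyond that
  exact <- !tied && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact))
  list(u_stat = unname(wt$statistic), p_value = wt$p.value, tied = tied)
}

#' Cross-outcome correlation matrix at one timepoint
#'
#' @param panel Outcome panel data frame (rows at a single timepoint, or pass
#'   `timepoint` to filter).
#' @param outcomes Character vector of outcome columns.
#' @param timepoint Optional `"pre"`/`"post"` filter when `panel` is long.
#' @return Symmetric correlation matrix with unit diagonal; entries for
#'   constant outcomes are `NA` with a warning.
#' @export
outcome_correlations <- function(panel, outcomes = OUTCOME_NAMES, timepoint = NULL) {
  if (!is.null(timepoint)) panel <- panel[panel$timepoint == timepoint, , drop = FALSE]
  m <- as.matrix(panel[, intersect(outcomes, names(panel)), drop = FALSE])
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop_input("outcome_correlations: need >= 3 complete cases")
  const <- apply(m, 2, sd) <= .Machine$double.eps
  r <- suppressWarnings(cor(m))
  if (any(const)) {
    warning(sprintf("constant outcome(s): %s; correlations set to NA",
                    paste(colnames(m)[const], collapse = ", ")))
    r[const, ] <- NA; r[, const] <- NA
  }
  diag(r) <- 1
  r
}

#' Flag univariate outliers by z-score
#'
#' Flags participants whose |z| exceeds `threshold` (default 3.29, the
#' two-sided .001 normal criterion) on any supplied outcome.  Flag-and-report
#' only: exclusion is an explicit user action recorded in the run log.
#'
#' @param scores Numeric vector or participants x outcomes matrix/data frame.
#' @param threshold Positive z threshold; `Inf` disables flagging.
#' @return Logical vector, one flag per participant (row).
#' @export
flag_univariate_outliers <- function(scores, threshold = 3.29) {
  m <- as.matrix(scores)
  if (nrow(m) < 3L) stop_input("flag_univariate_outliers: need n >= 3")
  flags <- rep(FALSE, nrow(m))
  for (j in seq_len(ncol(m))) {
    s <- sd(m[, j], na.rm = TRUE)
    if (is.na(s) || s <= .Machine$double.eps) {
      warning(sprintf("column %d has zero SD; no outlier flags", j))
      next
    }
    z <- (m[, j] - mean(m[, j], na.rm = TRUE)) / s
    flags <- flags | (!is.na(z) & abs(z) > threshold)
  }
  flags
}

#' Rank-based inverse-normal transform
#'
#' Blom scores, used for the optional robustness re-run mirroring the
#' transformed-vs-untransformed agreement check; untransformed analyses are
#' primary.
#'
#' @param x Numeric vector.
#' @return Transformed vector, same order.
#' @export
rank_inverse_normal <- function(x) {
  ok <- !is.na(x)
  out <- rep(NA_real_, length(x))
  n <- sum(ok)
  out[ok] <- qnorm((rank(x[ok]) - 3 / 8) / (n + 1 / 4))
  out
}

# "<.001" style display used in the printed tables.
format_p <- function(p, digits = 3) {
  ifelse(p < 10^(-digits),
         sprintf("P<.%s1", paste(rep("0", digits - 1), collapse = "")),
         sprintf("P=.%s", sub("^0\\.", "", formatC(round(p, digits), digits = digits, format = "f"))))
}
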