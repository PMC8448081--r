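# Default generator parameters: the published pre/post means and SDs of the
# six outcomes for the n = 89 analysis sample, in canonical outcome order
# (overall_wellbeing, life_satisfaction, dass_depression, dass_anxiety,
# dass_stress, resilience).
DEFAULT_PRE_MEAN  <- c(45.81, 22.01, 10.00, 6.54, 13.03, 3.27)
DEFAULT_PRE_SD    <- c(11.18,  5.93,  8.91, 6.77,  8.18, 0.76)
DEFAULT_POST_MEAN <- c(49.39, 24.46,  7.91, 5.33, 10.67, 3.45)
DEFAULT_POST_SD   <- c(12.19,  6.48,  7.37, 5.71,  7.94, 0.75)
OUTCOME_SIGN <- c(1, 1, -1, -1, -1, 1)  # +1 higher_is_better, -1 lower_is_better

#' Build a simulation configuration
#'
#' Describes the statistical world the cohort generator draws from: a
#' 12-dimensional Gaussian over the six outcomes at two timepoints.  Defaults
#' are the published pre/post means and SDs of the evaluated cohort; the
#' cross-outcome correlation magnitude (0.50) sits in the reported .40-.65
#' band with signs set by scale direction (well-being outcomes intercorrelate
#' positively, distress outcomes positively, cross-dimension negatively);
#' pre-post correlations default to 0.7 per outcome (not reported in the
#' source tables; vary in sensitivity runs).  Students receive a baseline
#' shift of half a pre SD in the unhealthy direction on every outcome,
#' applied at both timepoints (worse baselines, no group x time interaction).
#'
#' @param n_participants Cohort size (default 89).
#' @param student_fraction Fraction in the student cohort (default 32/89).
#' @param pre_mean,pre_sd,post_mean,post_sd Numeric vectors of length 6 in
#'   canonical outcome order.
#' @param true_change Mean change (post - pre) per outcome; defaults to
#'   `post_mean - pre_mean`.  Supplying it overrides `post_mean`.
#' @param pre_post_correlation Per-outcome pre-post correlation in (0, 1);
#'   scalar recycled.
#' @param cor_magnitude Magnitude of the cross-outcome correlation (default
#'   0.5, within the 0.40-0.65 band).
#' @param student_shift_sd Baseline shift for students, in pre-SD units
#'   toward the unhealthy pole (default 0.5; 0 disables).
#' @param missing_post_fraction Fraction of participants whose post scores
#'   are set missing completely at random (default 0; the analysed cohort has
#'   both timepoints).
#' @param bounds_action `"none"` (default: out-of-bounds fractions are logged
#'   but values kept, preserving the Gaussian covariance structure) or
#'   `"clamp"` (truncate to scale bounds).
#' @param seed Integer seed governing the whole cohort.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 89,
                              student_fraction = 32 / 89,
                              pre_mean = DEFAULT_PRE_MEAN,
                              pre_sd = DEFAULT_PRE_SD,
                              post_mean = DEFAULT_POST_MEAN,
                              post_sd = DEFAULT_POST_SD,
                              true_change = NULL,
                              pre_post_correlation = 0.7,
                              cor_magnitude = 0.5,
                              student_shift_sd = 0.5,
                              missing_post_fraction = 0,
                              bounds_action = c("none", "clamp"),
                              seed = 1L) {
  bounds_action <- match.arg(bounds_action)
  p <- length(OUTCOME_NAMES)
  rho <- rep_len(pre_post_correlation, p)
  for (v in c("pre_mean", "pre_sd", "post_mean", "post_sd"))
    if (length(get(v)) != p) stop_config("simulation_config: %s must have length %d", v, p)
  if (!is.null(true_change)) {
    if (length(true_change) != p) stop_config("simulation_config: true_change must have length %d", p)
    post_mean <- pre_mean + true_change
  }
  if (any(rho <= 0 | rho >= 1))
    stop_config("simulation_config: pre_post_correlation must be in (0, 1)")
  if (cor_magnitude < 0 || cor_magnitude >= 1)
    stop_config("simulation_config: cor_magnitude must be in [0, 1)")
  if (any(pre_sd <= 0) || any(post_sd <= 0))
    stop_config("simulation_config: SDs must be positive")
  if (student_fraction < 0 || student_fraction > 1)
    stop_config("simulation_config: student_fraction must be in [0, 1]")
  if (missing_post_fraction < 0 || missing_post_fraction > 1)
    stop_config("simulation_config: missing_post_fraction must be in [0, 1]")
  structure(list(
    n_participants = as.integer(n_participants),
    student_fraction = student_fraction,
    pre_mean = pre_mean, pre_sd = pre_sd,
    post_mean = post_mean, post_sd = post_sd,
    true_change = post_mean - pre_mean,
    pre_post_correlation = rho,
    cor_magnitude = cor_magnitude,
    student_shift_sd = student_shift_sd,
    missing_post_fraction = missing_post_fraction,
    bounds_action = bounds_action,
    seed = as.integer(seed)), class = "simulation_config")
}

# Six-outcome correlation matrix: |r| = cor_magnitude, signs from scale
# direction (so cross-dimension correlations are negative).
outcome_cor_matrix <- function(cor_magnitude) {
  R <- outer(OUTCOME_SIGN, OUTCOME_SIGN) * cor_magnitude
  diag(R) <- 1
  R
}

# Full 12 x 12 (pre, post) covariance.  The pre-post cross block is
# A R A with A = diag(sqrt(rho)), which puts rho_j on the own-outcome
# diagonal and sqrt(rho_i rho_j) R_ij off-diagonal; for a common rho this is
# the Kronecker product [[1, rho], [rho, 1]] (x) R, hence positive definite.
# Positive definiteness is checked numerically for general rho.
simulation_covariance <- function(config) {
  R <- outcome_cor_matrix(config$cor_magnitude)
  A <- diag(sqrt(config$pre_post_correlation))
  C <- A %*% R %*% A
  corr12 <- rbind(cbind(R, C), cbind(C, R))
  sds <- c(config$pre_sd, config$post_sd)
  Sigma <- corr12 * tcrossprod(sds)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop_config("simulation_config implies a non-positive-definite covariance; reduce cor_magnitude or pre_post_correlation")
  Sigma
}

# Cholesky-based multivariate normal draw (deterministic under set.seed).
rmvnorm_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mu)), nrow = n)
  sweep(z %*% L, 2, mu, `+`)
}

#' Generate a synthetic participant cohort
#'
#' Draws pre and post outcome vectors jointly from the 12-dimensional
#' Gaussian implied by the configuration, applies the student baseline shift,
#' optional missingness at post, and logs (or clamps) values outside each
#' scale's bounds.  Deterministic under the config's seed.
#'
#' @param config A [simulation_config()].
#' @return Long-format data frame, one row per participant x timepoint:
#'   `participant_id`, `cohort` (`student`/`general`), `timepoint`
#'   (`pre`/`post`), six outcome columns.  Attributes: `truncation`
#'   (per-outcome fraction of draws outside scale bounds), `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  Sigma <- simulation_covariance(config)
  set.seed(config$seed)
  n <- config$n_participants
  n_students <- round(n * config$student_fraction)
  cohort <- rep(c("student", "general"), c(n_students, n - n_students))
  mu <- c(config$pre_mean, config$post_mean)
  # The configured SDs are total-cohort SDs; the student/general mean gap
  # contributes f(1-f)*gap^2 of mixture variance, so the within-cohort
  # covariance is shrunk to keep the marginal SDs on target.
  frac0 <- n_students / n
  gap_var <- frac0 * (1 - frac0) * (config$student_shift_sd * config$pre_sd)^2
  shrink2 <- 1 - gap_var / c(config$pre_sd, config$post_sd)^2
  if (any(shrink2 <= 0))
    stop_config("student_shift_sd too large for the configured SDs")
  Sigma <- Sigma * tcrossprod(sqrt(shrink2))
  X <- rmvnorm_chol(n, mu, Sigma)
  # Student-vs-general baseline gap, mean-preserving so the configured means
  # stay the *total-cohort* means (they describe the whole analysed sample):
  # students sit student_shift_sd pre-SDs below the general cohort in the
  # unhealthy direction, at both timepoints (worse baseline, no interaction).
  gap <- -OUTCOME_SIGN * config$student_shift_sd * config$pre_sd
  frac <- frac0
  stud <- cohort == "student"
  X[stud, ] <- sweep(X[stud, , drop = FALSE], 2, (1 - frac) * c(gap, gap), `+`)
  X[!stud, ] <- sweep(X[!stud, , drop = FALSE], 2, -frac * c(gap, gap), `+`)
  p <- length(OUTCOME_NAMES)
  pre <- X[, 1:p, drop = FALSE]
  post <- X[, (p + 1):(2 * p), drop = FALSE]
  colnames(pre) <- colnames(post) <- OUTCOME_NAMES
  scales <- default_scales()$outcomes
  trunc_frac <- vapply(seq_len(p), function(j) {
    lo <- scales[[j]]$score_min; hi <- scales[[j]]$score_max
    mean(c(pre[, j], post[, j]) < lo | c(pre[, j], post[, j]) > hi)
  }, numeric(1))
  names(trunc_frac) <- OUTCOME_NAMES
  if (config$bounds_action == "clamp") {
    for (j in seq_len(p)) {
      lo <- scales[[j]]$score_min; hi <- scales[[j]]$score_max
      pre[, j] <- pmin(pmax(pre[, j], lo), hi)
      post[, j] <- pmin(pmax(post[, j], lo), hi)
    }
  }
  if (config$missing_post_fraction > 0) {
    n_miss <- round(n * config$missing_post_fraction)
    miss <- sample.int(n, n_miss)
    post[miss, ] <- NA_real_
  }
  ids <- sprintf("P%03d", seq_len(n))
  out <- rbind(
    data.frame(participant_id = ids, cohort = cohort, timepoint = "pre",
               pre, stringsAsFactors = FALSE, check.names = FALSE),
    data.frame(participant_id = ids, cohort = cohort, timepoint = "post",
               post, stringsAsFactors = FALSE, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "truncation") <- trunc_frac
  attr(out, "config") <- config
  out
}

#' Write a cohort with generator provenance
#'
#' Emits the long-format CSV the pipeline ingests, with the generating
#' configuration embedded as `#`-prefixed header comments and as a side-car
#' JSON file (`<path>.config.json`).
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  config <- attr(cohort, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# dualchange synthetic cohort; seed=%d; n=%d",
                       config$seed, config$n_participants), con)
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV (skipping provenance comments)
#' @param path CSV path as written by [write_cohort_csv()] or hand-made.
#' @return Long-format outcome panel data frame.
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Correlation between a standard normal and its equal-probability binning
# into `levels` categories, by numeric integration; used to undo
# discretization attenuation in generate_item_level.
binned_normal_cor <- function(levels) {
  q <- qnorm(seq_len(levels - 1) / levels)
  # category values 0..levels-1; E[bin] and Var from uniform category probs
  vals <- 0:(levels - 1)
  pcat <- rep(1 / levels, levels)
  mu_b <- sum(vals * pcat)
  var_b <- sum((vals - mu_b)^2 * pcat)
  # E[z * bin] = sum_k k * E[z; z in bin k] = sum over thresholds of phi
  lo <- c(-Inf, q); hi <- c(q, Inf)
  ez <- vapply(seq_len(levels), function(k) dnorm(lo[k]) - dnorm(hi[k]), numeric(1))
  cov_zb <- sum(vals * ez)
  cov_zb / sqrt(var_b)
}

#' Generate item-level responses with a target Cronbach's alpha
#'
#' One-factor model with a common loading: for a target alpha and k items,
#' the implied common inter-item correlation is
#' \eqn{r = \alpha / (k - (k-1)\alpha)}; the latent correlation is inflated
#' by the (analytically computed) discretization attenuation so the
#' *discretized* responses attain the target.  Responses are binned to the
#' item range with equal-probability bins.
#'
#' @param scale A [scale_definition()] supplying item count and range.
#' @param target_alpha Target alpha in `[0, 1)`.
#' @param n Number of participants (>= 2).
#' @param seed Integer seed.
#' @return n x item_count integer matrix of responses.
#' @export
generate_item_level <- function(scale, target_alpha, n, seed = 1L) {
  stopifnot(inherits(scale, "scale_definition"))
  if (n < 2L) stop_input("generate_item_level: alpha undefined for n < 2")
  if (target_alpha < 0 || target_alpha >= 1)
    stop_input("generate_item_level: target_alpha must be in [0, 1)")
  k <- scale$item_count
  r_target <- target_alpha / (k - (k - 1) * target_alpha)
  levels <- scale$item_max - scale$item_min + 1L
  c_att <- binned_normal_cor(levels)
  r_latent <- r_target / c_att^2
  if (r_latent >= 1) {
    max_r <- c_att^2 * (1 - 1e-12)
    max_alpha <- k * max_r / (1 + (k - 1) * max_r)
    stop_input("generate_item_level: target_alpha %.3f unattainable with %d response levels; maximum ~%.3f",
               target_alpha, levels, max_alpha)
  }
  set.seed(seed)
  f <- rnorm(n)
  lam <- sqrt(r_latent)
  z <- lam * f + sqrt(1 - r_latent) * matrix(rnorm(n * k), nrow = n)
  u <- pnorm(z)
  resp <- scale$item_min + pmin(floor(u * levels), levels - 1L)
  colnames(resp) <- paste0(scale$name, "_", seq_len(k))
  storage.mode(resp) <- "integer"
  resp
}
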