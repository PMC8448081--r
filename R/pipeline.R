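#' Build a run configuration
#'
#' Validated up front; every default is recorded in the run log emitted by
#' [run_pipeline()] so a log suffices to re-derive all non-default decisions.
#'
#' @param input Path to a cohort CSV, a cohort data frame, or a
#'   [simulation_config()] to generate one.
#' @param scales_path Optional override JSON for [default_scales()].
#' @param sediff_variant `"difference"` (study formula) or
#'   `"jacobson_truax"`.
#' @param grouping Named character vector mapping outcomes to
#'   `wellbeing`/`distress`/`excluded`.
#' @param rci_threshold RCI critical value (default 1.96).
#' @param outlier_threshold z threshold for flagging (default 3.29).
#' @param exclude_ids Participant ids to exclude (explicit user action,
#'   logged).
#' @param welch Welch correction for stratified t tests (default TRUE).
#' @param robustness_transform Also run the stratified tests on rank-based
#'   inverse-normal transformed change scores (default FALSE).
#' @param out_dir Optional output directory for [write_result_bundle()].
#' @param seed Seed recorded in the log (used when `input` is a simulation
#'   config without its own seed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = simulation_config(),
                       scales_path = NULL,
                       sediff_variant = c("difference", "jacobson_truax"),
                       grouping = DEFAULT_GROUPING,
                       rci_threshold = 1.96,
                       outlier_threshold = 3.29,
                       exclude_ids = character(),
                       welch = TRUE,
                       robustness_transform = FALSE,
                       out_dir = NULL,
                       seed = 1L) {
  sediff_variant <- match.arg(sediff_variant)
  if (!all(OUTCOME_NAMES %in% names(grouping)))
    stop_config("run_config: grouping must cover all outcomes: %s",
                paste(setdiff(OUTCOME_NAMES, names(grouping)), collapse = ", "))
  if (!all(grouping %in% c("wellbeing", "distress", "excluded")))
    stop_config("run_config: grouping values must be wellbeing/distress/excluded")
  if (rci_threshold <= 0) stop_config("run_config: rci_threshold must be positive")
  structure(list(input = input, scales_path = scales_path,
                 sediff_variant = sediff_variant, grouping = grouping,
                 rci_threshold = rci_threshold,
                 outlier_threshold = outlier_threshold,
                 exclude_ids = exclude_ids, welch = welch,
                 robustness_transform = robustness_transform,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_input <- function(config) {
  input <- config$input
  if (inherits(input, "simulation_config")) return(generate_cohort(input))
  if (is.character(input)) {
    if (!file.exists(input)) stop_input("input file not found: %s", input)
    df <- read_cohort_csv(input)
    if (!all(OUTCOME_NAMES %in% names(df)) &&
        any(grepl("^(mhcsf|swls|dass21|brs)_\\d+$", names(df)))) {
      df <- panel_from_items(df, default_scales(config$scales_path))
    }
    return(df)
  }
  if (is.data.frame(input)) return(input)
  stop_input("run_config input must be a path, data frame or simulation_config")
}

#' Run the full dual-factor analysis pipeline
#'
#' Complete-case per stage: paired analyses use participants with both
#' timepoints and no missing outcome; every exclusion, default and variant is
#' recorded in the returned `log`.  Stages that degenerate (e.g. an empty
#' stratum) are reported as explicit gaps rather than aborting the rest.
#'
#' @param config A [run_config()], or anything accepted as its `input`.
#' @return Object of class `dual_result`: `table2` (per-outcome pre/post
#'   descriptives, problematic counts, univariate F/p/eta), `manova`
#'   (pre-post, baseline group, interaction), `correlations_pre`, `rci`,
#'   `patterns`, `frequencies`, `subgroups` (per distress type), `table3`
#'   (baseline-stratified tests; plus `table3_transformed` when requested),
#'   `outlier_flags`, `alpha` (when item-level input), `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(input = config)
  scales <- default_scales(config$scales_path)
  outcomes <- scales$outcomes
  log <- list(config = serializable_config(config),
              defaults = list(grouping = as.list(config$grouping),
                              sediff_variant = config$sediff_variant,
                              rci_threshold = config$rci_threshold,
                              outlier_threshold = config$outlier_threshold,
                              welch = config$welch),
              exclusions = list())

  panel <- resolve_input(config)
  if (length(config$exclude_ids)) {
    panel <- panel[!panel$participant_id %in% config$exclude_ids, , drop = FALSE]
    log$exclusions$user_excluded <- config$exclude_ids
  }
  wide <- panel_to_wide(panel, OUTCOME_NAMES)
  pre_cols <- paste0(OUTCOME_NAMES, "_pre")
  post_cols <- paste0(OUTCOME_NAMES, "_post")
  complete <- complete.cases(wide[, c(pre_cols, post_cols)])
  log$exclusions$incomplete_cases <-
    setdiff(unique(panel$participant_id), wide$participant_id[complete])
  log$n_input <- length(unique(panel$participant_id))
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  log$n_analyzed <- n
  if (n < 2L) stop_input("run_pipeline: need >= 2 participants with both timepoints")

  pre <- as.matrix(wide[, pre_cols]); colnames(pre) <- OUTCOME_NAMES
  post <- as.matrix(wide[, post_cols]); colnames(post) <- OUTCOME_NAMES

  # Table-2 analogue -----------------------------------------------------
  # Severity classification is defined on the scale range; scores outside it
  # (possible for unclamped synthetic cohorts) are clipped for the category
  # lookup only -- all statistics use the raw scores.
  clip_bounds <- function(m) {
    out <- as.data.frame(m)
    for (nm in OUTCOME_NAMES)
      out[[nm]] <- pmin(pmax(out[[nm]], outcomes[[nm]]$score_min),
                        outcomes[[nm]]$score_max)
    out
  }
  flags_pre <- classify_problematic(clip_bounds(pre), outcomes)
  flags_post <- classify_problematic(clip_bounds(post), outcomes)
  table2 <- do.call(rbind, lapply(OUTCOME_NAMES, function(nm) {
    a <- paired_rm_anova(pre[, nm], post[, nm])
    data.frame(outcome = nm,
               pre_mean = mean(pre[, nm]), pre_sd = sd(pre[, nm]),
               pre_problematic_n = sum(flags_pre[[nm]]),
               pre_problematic_pct = round(100 * mean(flags_pre[[nm]])),
               post_mean = mean(post[, nm]), post_sd = sd(post[, nm]),
               post_problematic_n = sum(flags_post[[nm]]),
               post_problematic_pct = round(100 * mean(flags_post[[nm]])),
               f_stat = a$f_stat, df_num = a$df_num, df_den = a$df_den,
               p_value = a$p_value, partial_eta_sq = a$partial_eta_sq)
  }))

  # MANOVA block ----------------------------------------------------------
  diffs <- post - pre
  manova <- list(pre_post = one_sample_manova(diffs))
  if ("cohort" %in% names(wide) && length(unique(wide$cohort)) == 2L) {
    manova$baseline_group <- two_group_manova(pre, wide$cohort)
    manova$interaction <- two_group_manova(diffs, wide$cohort)
  } else {
    log$gaps <- c(log$gaps, "cohort column absent or single-group: baseline/interaction MANOVA skipped")
  }

  correlations_pre <- outcome_correlations(as.data.frame(pre))

  # Reliable change -------------------------------------------------------
  long_complete <- rbind(
    data.frame(participant_id = wide$participant_id, timepoint = "pre",
               as.data.frame(pre), stringsAsFactors = FALSE),
    data.frame(participant_id = wide$participant_id, timepoint = "post",
               as.data.frame(post), stringsAsFactors = FALSE))
  rci <- rci_table(long_complete, outcomes, variant = config$sediff_variant,
                   threshold = config$rci_threshold)
  patterns <- change_pattern(rci, config$grouping)
  frequencies <- pattern_frequencies(patterns)
  baseline_flags <- cbind(participant_id = wide$participant_id,
                          flags_pre, stringsAsFactors = FALSE)
  subgroups <- lapply(c("depression", "anxiety", "stress"), function(dt)
    subgroup_pattern_frequencies(rci, baseline_flags, dt, config$grouping))
  names(subgroups) <- c("depression", "anxiety", "stress")

  # Table-3 analogue -------------------------------------------------------
  strat_one <- function(pre_v, post_v, flag, nm) {
    tryCatch(baseline_stratified_change_test(pre_v, post_v, flag, outcome = nm,
                                             welch = config$welch),
             dualchange_error = function(e) {
               log$gaps <<- c(log$gaps, sprintf("table3 '%s': %s", nm, conditionMessage(e)))
               NULL
             })
  }
  table3 <- lapply(OUTCOME_NAMES, function(nm)
    strat_one(pre[, nm], post[, nm], flags_pre[[nm]], nm))
  names(table3) <- OUTCOME_NAMES
  mw <- lapply(OUTCOME_NAMES, function(nm) {
    fl <- flags_pre[[nm]]
    if (length(unique(fl)) != 2L) return(NULL)
    tryCatch(mann_whitney_check(post[, nm] - pre[, nm], fl),
             dualchange_error = function(e) NULL)
  })
  names(mw) <- OUTCOME_NAMES
  table3_transformed <- NULL
  if (config$robustness_transform) {
    table3_transformed <- lapply(OUTCOME_NAMES, function(nm) {
      ch <- rank_inverse_normal(post[, nm] - pre[, nm])
      strat_one(rep(0, n), ch, flags_pre[[nm]], nm)
    })
    names(table3_transformed) <- OUTCOME_NAMES
  }

  outlier_flags <- flag_univariate_outliers(cbind(pre, post), config$outlier_threshold)
  log$outliers_flagged <- wide$participant_id[outlier_flags]

  structure(list(table2 = table2, manova = manova,
                 correlations_pre = correlations_pre,
                 rci = rci, patterns = patterns, frequencies = frequencies,
                 subgroups = subgroups, table3 = table3,
                 table3_transformed = table3_transformed,
                 mann_whitney = mw,
                 outlier_flags = setNames(outlier_flags, wide$participant_id),
                 log = log),
            class = "dual_result")
}

serializable_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$input, "simulation_config")) {
    out$input <- unclass(out$input)
    out$input_kind <- "simulation_config"
  } else if (is.data.frame(out$input)) {
    out$input <- sprintf("<data.frame: %d rows>", nrow(out$input))
    out$input_kind <- "data.frame"
  } else out$input_kind <- "path"
  out$grouping <- as.list(out$grouping)
  out
}

#' @export
print.dual_result <- function(x, ...) {
  cat(sprintf("Dual-factor change analysis: n = %d participants\n\n", x$log$n_analyzed))
  cat("Pre-post multivariate test:\n  ")
  print(x$manova$pre_post)
  t2 <- x$table2
  cat("\nPer-outcome change (pre -> post):\n")
  for (i in seq_len(nrow(t2)))
    cat(sprintf("  %-18s %6.2f (%5.2f) -> %6.2f (%5.2f)  F(%d,%d)=%.2f %s eta2=%.2f\n",
                t2$outcome[i], t2$pre_mean[i], t2$pre_sd[i],
                t2$post_mean[i], t2$post_sd[i],
                t2$df_num[i], t2$df_den[i], t2$f_stat[i],
                format_p(t2$p_value[i]), t2$partial_eta_sq[i]))
  fq <- x$frequencies
  cat(sprintf("\nReliable change in >= 1 outcome: %d/%d (%d%%)\n",
              fq$n_any_reliable_change, fq$n, fq$pct_any_reliable_change))
  sp <- fq$improvement_split
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-15s %d/%d (%d%%)\n", sp$pattern[i], sp$count[i],
                sp$denominator[i], sp$display_pct[i]))
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Tidy CSVs (Table-2/Table-3 analogues, per-participant RCI and pattern
#' tables, correlation matrix), a JSON summary of frequencies and MANOVA
#' statistics, and the run log as JSON.  Deterministic: re-running an
#' identical config reproduces byte-identical files.
#'
#' @param result A `dual_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  stopifnot(inherits(result, "dual_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm) write.csv(df, file.path(dir, nm), row.names = FALSE)
  wr(result$table2, "table2.csv")
  wr(result$rci, "rci.csv")
  wr(result$patterns, "patterns.csv")
  t3 <- do.call(rbind, lapply(result$table3, function(s)
    if (is.null(s)) NULL else as.data.frame(unclass(s)[c(
      "outcome", "n_problematic", "n_healthy", "t_stat", "df", "p_value", "cohen_d")])))
  if (!is.null(t3)) wr(t3, "table3.csv")
  write.csv(as.data.frame(result$correlations_pre), file.path(dir, "correlations_pre.csv"))
  summary <- list(
    manova = lapply(result$manova, function(m) unclass(m)),
    frequencies = result$frequencies,
    subgroups = result$subgroups)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
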