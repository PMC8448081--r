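#' Standard error of the difference between two administrations
#'
#' Default (`variant = "difference"`) reproduces the study formula
#' \eqn{SE_{diff} = SD_x \sqrt{1 - r_{xx}}} with \eqn{SD_x} the standard
#' deviation of the pre-post *difference* scores and \eqn{r_{xx}} the
#' pre-post correlation.  The classic Jacobson-Truax quantity,
#' \eqn{SD_{pre}\sqrt{2(1 - r_{xx})}}, is available as
#' `variant = "jacobson_truax"` (pass the baseline SD as `sd_x`).  Note the
#' two coincide only when `sd_x` is chosen accordingly; under equal pre/post
#' variances the JT quantity equals the SD of the difference scores itself,
#' so the default variant is *smaller* by a factor \eqn{\sqrt{1-r}} and the
#' resulting index is not a unit-variance z under the null (see the package
#' vignette).
#'
#' @param sd_x Non-negative SD in score units: SD of difference scores for
#'   `"difference"`, baseline SD for `"jacobson_truax"`.
#' @param r_prepost Pre-post correlation (or reliability), at most 1.
#' @param variant `"difference"` (default) or `"jacobson_truax"`.
#' @return SEdiff in score units, with attribute `degenerate = TRUE` when the
#'   result is 0 (downstream RCI undefined).
#' @examples
#' se_diff(10, 0.75)  # 5
#' @export
se_diff <- function(sd_x, r_prepost, variant = c("difference", "jacobson_truax")) {
  variant <- match.arg(variant)
  if (sd_x < 0) stop_input("se_diff: sd_x must be >= 0")
  if (r_prepost > 1) stop_input("se_diff: pre-post correlation cannot exceed 1")
  out <- switch(variant,
                difference = sd_x * sqrt(1 - r_prepost),
                jacobson_truax = sd_x * sqrt(2 * (1 - r_prepost)))
  if (out <= .Machine$double.eps) attr(out, "degenerate") <- TRUE
  out
}

#' Reliable change index for one participant and outcome
#'
#' Raw index is `(pre - post) / sediff`; the returned value is
#' orientation-normalised so that positive always means improvement (negated
#' for `higher_is_better` scales, where post > pre is the improvement).
#' Magnitude is unchanged by the orientation.
#'
#' @param pre,post Scores (vectorised).
#' @param sediff Positive standard error of the difference.
#' @param direction Scale direction, `"higher_is_better"` or
#'   `"lower_is_better"`.
#' @return Signed unitless index; positive = improvement.
#' @export
rci_score <- function(pre, post, sediff,
                      direction = c("higher_is_better", "lower_is_better")) {
  direction <- match.arg(direction)
  if (length(sediff) != 1 || !is.finite(sediff) || sediff <= 0)
    stop_degenerate("rci_score: SEdiff must be a single positive number (got %s)",
                    format(sediff))
  raw <- (pre - post) / sediff
  if (direction == "higher_is_better") -raw else raw
}

#' Classify a reliable change index
#'
#' Strict threshold: improved iff `rci > threshold`, deteriorated iff
#' `rci < -threshold`; a value exactly at 1.96 is "no reliable change".
#'
#' @param rci Orientation-normalised index (positive = improvement).
#' @param threshold Two-sided critical value, default 1.96.
#' @return Factor with levels `reliably_deteriorated`, `no_reliable_change`,
#'   `reliably_improved`.
#' @export
classify_reliable <- function(rci, threshold = 1.96) {
  if (any(!is.finite(rci)))
    stop_input("classify_reliable: non-finite RCI value")
  lv <- c("reliably_deteriorated", "no_reliable_change", "reliably_improved")
  factor(ifelse(rci > threshold, lv[3], ifelse(rci < -threshold, lv[1], lv[2])),
         levels = lv)
}

#' Per-participant, per-outcome reliable change table
#'
#' For each outcome, SEdiff is estimated from the analysed sample itself (the
#' study's self-referential usage): sample SD of the difference scores and
#' sample Pearson pre-post correlation for the `"difference"` variant;
#' baseline SD for `"jacobson_truax"`.
#'
#' @param panel Long outcome panel (participant x timepoint rows) with
#'   `participant_id`, `timepoint` in `{pre, post}` and outcome columns.
#' @param outcomes Named list of outcome definitions ([default_scales()]);
#'   only names present in `panel` are used.
#' @param variant SEdiff variant, see [se_diff()].
#' @param threshold RCI threshold, default 1.96.
#' @return Data frame, one row per participant x outcome: `participant_id`,
#'   `outcome`, `pre_score`, `post_score`, `diff` (pre - post), `se_diff`,
#'   `rci_value` (positive = improvement), `classification`, `variant`.
#'   Participants lacking either timepoint or with a missing score on an
#'   outcome are dropped for that outcome (complete-case), with the count in
#'   attribute `n_excluded`.
#' @export
rci_table <- function(panel, outcomes = default_scales()$outcomes,
                      variant = c("difference", "jacobson_truax"),
                      threshold = 1.96) {
  variant <- match.arg(variant)
  wide <- panel_to_wide(panel, names(outcomes))
  nms <- intersect(names(outcomes), sub("_pre$", "", grep("_pre$", names(wide), value = TRUE)))
  res <- lapply(nms, function(nm) {
    pre <- wide[[paste0(nm, "_pre")]]
    post <- wide[[paste0(nm, "_post")]]
    ok <- !is.na(pre) & !is.na(post)
    pre <- pre[ok]; post <- post[ok]
    if (sum(ok) < 3L)
      stop_input("rci_table: fewer than 3 complete cases for outcome '%s'", nm)
    r <- cor(pre, post)
    sd_x <- if (variant == "difference") sd(pre - post) else sd(pre)
    sediff <- se_diff(sd_x, r, variant = variant)
    if (isTRUE(attr(sediff, "degenerate")))
      stop_degenerate("rci_table: degenerate SEdiff (0) for outcome '%s'", nm)
    rci <- rci_score(pre, post, sediff, direction = outcomes[[nm]]$direction)
    data.frame(participant_id = wide$participant_id[ok],
               outcome = nm,
               pre_score = pre, post_score = post,
               diff = pre - post,
               se_diff = as.numeric(sediff),
               rci_value = rci,
               classification = classify_reliable(rci, threshold),
               variant = variant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_excluded") <- length(unique(panel$participant_id)) -
    length(unique(out$participant_id))
  out
}

# Reshape a long participant x timepoint panel to one row per participant
# with <outcome>_pre / <outcome>_post columns.
panel_to_wide <- function(panel, outcome_names) {
  need <- c("participant_id", "timepoint")
  if (!all(need %in% names(panel)))
    stop_input("panel needs columns: %s", paste(need, collapse = ", "))
  if (!all(panel$timepoint %in% c("pre", "post")))
    stop_input("timepoint must be 'pre' or 'post'")
  nms <- intersect(outcome_names, names(panel))
  pre <- panel[panel$timepoint == "pre", , drop = FALSE]
  post <- panel[panel$timepoint == "post", , drop = FALSE]
  ids <- intersect(pre$participant_id, post$participant_id)
  pre <- pre[match(ids, pre$participant_id), , drop = FALSE]
  post <- post[match(ids, post$participant_id), , drop = FALSE]
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  if ("cohort" %in% names(pre)) out$cohort <- pre$cohort
  for (nm in nms) {
    out[[paste0(nm, "_pre")]] <- pre[[nm]]
    out[[paste0(nm, "_post")]] <- post[[nm]]
  }
  out
}

#' Dual-factor change pattern per participant
#'
#' Crosses reliable improvement on the well-being dimension with reliable
#' improvement on the distress dimension.  `improved_wellbeing` /
#' `improved_distress` are TRUE when the participant is `reliably_improved`
#' on at least one outcome mapped to that dimension.
#'
#' @param rci Data frame from [rci_table()].
#' @param grouping Named character vector mapping each outcome present in
#'   `rci` to `"wellbeing"`, `"distress"` or `"excluded"`.
#' @return Data frame, one row per participant: the two booleans and
#'   `pattern` in `{both, wellbeing_only, distress_only, none}`, plus
#'   `any_reliable_change` (any classification other than no_reliable_change,
#'   over *all* outcomes including excluded ones and deteriorations) and
#'   `any_reliable_improvement` (any reliably_improved anywhere).
#' @export
change_pattern <- function(rci, grouping = DEFAULT_GROUPING) {
  outs <- unique(rci$outcome)
  unmapped <- setdiff(outs, names(grouping))
  if (length(unmapped))
    stop_config("change_pattern: outcome(s) missing from grouping: %s",
                paste(unmapped, collapse = ", "))
  bad <- setdiff(unique(grouping), c("wellbeing", "distress", "excluded"))
  if (length(bad))
    stop_config("change_pattern: invalid dimension label(s): %s", paste(bad, collapse = ", "))
  ids <- unique(rci$participant_id)
  imp <- rci$classification == "reliably_improved"
  anych <- rci$classification != "no_reliable_change"
  dim_of <- grouping[rci$outcome]
  agg <- function(mask) {
    as.logical(tapply(mask, factor(rci$participant_id, levels = ids), any))
  }
  iw <- agg(imp & dim_of == "wellbeing")
  id_ <- agg(imp & dim_of == "distress")
  pattern <- ifelse(iw & id_, "both",
             ifelse(iw, "wellbeing_only",
             ifelse(id_, "distress_only", "none")))
  data.frame(participant_id = ids,
             improved_wellbeing = iw,
             improved_distress = id_,
             pattern = factor(pattern, levels = c("both", "wellbeing_only",
                                                  "distress_only", "none")),
             any_reliable_change = agg(anych),
             any_reliable_improvement = agg(imp),
             stringsAsFactors = FALSE)
}

#' Frequencies of dual-factor change patterns
#'
#' Percentages for the `both` / `wellbeing_only` / `distress_only` split are
#' computed over the participants showing at least one reliable improvement
#' (the improvement denominator); exact fractions are retained alongside
#' integer-rounded display percentages.
#'
#' @param patterns Data frame from [change_pattern()].
#' @return List with `n` (participants), `counts` (named integer vector over
#'   the four patterns), `n_any_improvement`, `n_any_reliable_change`,
#'   `pct_any_reliable_change` (of all participants, with `display` rounding),
#'   and `improvement_split`: data frame of count / exact fraction / display
#'   percent per pattern among improvers.
#' @export
pattern_frequencies <- function(patterns) {
  if (nrow(patterns) == 0) stop_input("pattern_frequencies: empty input")
  counts <- table(patterns$pattern)
  n <- nrow(patterns)
  n_imp <- sum(patterns$any_reliable_improvement)
  n_any <- sum(patterns$any_reliable_change)
  split_patterns <- c("both", "wellbeing_only", "distress_only")
  split_counts <- as.integer(counts[split_patterns])
  frac <- if (n_imp > 0) split_counts / n_imp else rep(NA_real_, 3)
  list(
    n = n,
    counts = setNames(as.integer(counts), names(counts)),
    n_any_improvement = n_imp,
    n_any_reliable_change = n_any,
    frac_any_reliable_change = n_any / n,
    pct_any_reliable_change = round(100 * n_any / n),
    improvement_split = data.frame(
      pattern = split_patterns,
      count = split_counts,
      denominator = n_imp,
      fraction = frac,
      display_pct = round(100 * frac))
  )
}

#' Pattern breakdown within a baseline distress subgroup
#'
#' Restricts to participants who met the configured "mild" threshold on the
#' named DASS subscale at baseline *and* showed at least one reliable
#' improvement on any outcome, then recomputes the dual-factor pattern with
#' the distress dimension restricted to that single subscale (other distress
#' outcomes excluded).
#'
#' @param rci Data frame from [rci_table()].
#' @param baseline_flags Data frame from [classify_problematic()] applied to
#'   the baseline panel; must carry `participant_id`.
#' @param distress_type One of `"depression"`, `"anxiety"`, `"stress"`.
#' @param grouping Full outcome grouping (used for the well-being side and
#'   for the "any reliable improvement" gate).
#' @return List: `distress_type`, `denominator` (may be 0, reported
#'   explicitly), `counts` and `display_pct` over
#'   `{both, wellbeing_only, distress_only, none}`.
#' @export
subgroup_pattern_frequencies <- function(rci, baseline_flags,
                                         distress_type = c("depression", "anxiety", "stress"),
                                         grouping = DEFAULT_GROUPING) {
  distress_type <- tryCatch(match.arg(distress_type),
                            error = function(e) stop_config(
                              "subgroup_pattern_frequencies: unknown distress_type"))
  flag_col <- paste0("dass_", distress_type)
  if (!flag_col %in% names(baseline_flags))
    stop_config("baseline_flags lacks column '%s'", flag_col)
  sub_grouping <- grouping
  distress_outs <- names(grouping)[grouping == "distress"]
  sub_grouping[setdiff(distress_outs, flag_col)] <- "excluded"
  full_pat <- change_pattern(rci, grouping)
  sub_pat <- change_pattern(rci, sub_grouping)
  met <- baseline_flags$participant_id[baseline_flags[[flag_col]] %in% TRUE]
  improved <- full_pat$participant_id[full_pat$any_reliable_improvement]
  keep <- intersect(met, improved)
  sel <- sub_pat[sub_pat$participant_id %in% keep, , drop = FALSE]
  counts <- table(sel$pattern)
  denom <- nrow(sel)
  list(distress_type = distress_type,
       denominator = denom,
       counts = setNames(as.integer(counts), names(counts)),
       display_pct = setNames(
         if (denom > 0) round(100 * as.integer(counts) / denom)
         else rep(NA_real_, length(counts)),
         names(counts)))
}
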