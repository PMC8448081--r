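#' Construct a scale definition
#'
#' A `scale_definition` is a declarative description of one self-report
#' instrument: how many items it has, their response bounds, which items are
#' reverse-coded, how items aggregate to a total (`sum`, `sum_times_two` for
#' DASS-21 scores on the DASS-42-equivalent metric, or `mean` as for the BRS),
#' optional subscales, and an ordered severity cutoff table.
#'
#' Cutoffs are `(label, lower)` pairs with strictly increasing inclusive lower
#' bounds; the first bound must equal the scale minimum so that every valid
#' score maps to exactly one label.
#'
#' @param name Identifier for the instrument (used in error messages).
#' @param item_count Number of items, a positive integer.
#' @param item_min,item_max Integer response bounds per item.
#' @param scoring_rule One of `"sum"`, `"sum_times_two"`, `"mean"`.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param reverse_items Integer indices (1-based) of reverse-coded items.
#' @param subscales Named list mapping subscale name to item index vector.
#' @param cutoffs Data frame with columns `label` and `lower`, or `NULL`.
#' @param problematic_labels Character vector of cutoff labels counted as
#'   "problematic" (e.g. DASS bands at or above mild).
#' @param score_min,score_max Bounds of the total score; derived from the item
#'   bounds and scoring rule when omitted.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(name, item_count, item_min, item_max,
                             scoring_rule = c("sum", "sum_times_two", "mean"),
                             direction = c("higher_is_better", "lower_is_better"),
                             reverse_items = integer(),
                             subscales = NULL,
                             cutoffs = NULL,
                             problematic_labels = character(),
                             score_min = NULL, score_max = NULL) {
  scoring_rule <- match.arg(scoring_rule)
  direction <- match.arg(direction)
  item_count <- as.integer(item_count)
  if (is.na(item_count) || item_count < 1L)
    stop_config("scale '%s': item_count must be a positive integer", name)
  if (item_min >= item_max)
    stop_config("scale '%s': item_min must be < item_max", name)
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) && (any(reverse_items < 1L) || any(reverse_items > item_count)))
    stop_config("scale '%s': reverse_items outside 1..%d", name, item_count)
  if (!is.null(subscales)) {
    idx <- unlist(subscales, use.names = FALSE)
    if (any(idx < 1L) || any(idx > item_count))
      stop_config("scale '%s': subscale item index outside 1..%d", name, item_count)
  }
  nsub <- if (is.null(subscales)) 1L else max(1L, length(subscales))
  per_item <- switch(scoring_rule, sum = 1, sum_times_two = 2, mean = NA_real_)
  derived_min <- if (scoring_rule == "mean") item_min else item_count * item_min * per_item
  derived_max <- if (scoring_rule == "mean") item_max else item_count * item_max * per_item
  score_min <- if (is.null(score_min)) derived_min else score_min
  score_max <- if (is.null(score_max)) derived_max else score_max
  if (!is.null(cutoffs)) {
    cutoffs <- as.data.frame(cutoffs)
    if (!all(c("label", "lower") %in% names(cutoffs)))
      stop_config("scale '%s': cutoffs need 'label' and 'lower' columns", name)
    if (any(diff(cutoffs$lower) <= 0))
      stop_config("scale '%s': cutoff lower bounds must be strictly increasing", name)
    if (abs(cutoffs$lower[1] - score_min) > 1e-9)
      stop_config("scale '%s': first cutoff bound (%s) must equal the scale minimum (%s)",
                  name, cutoffs$lower[1], score_min)
    if (!all(problematic_labels %in% cutoffs$label))
      stop_config("scale '%s': problematic label not present in cutoffs", name)
  }
  structure(
    list(name = name, item_count = item_count,
         item_min = item_min, item_max = item_max,
         scoring_rule = scoring_rule, direction = direction,
         reverse_items = reverse_items, subscales = subscales,
         cutoffs = cutoffs, problematic_labels = problematic_labels,
         score_min = score_min, score_max = score_max),
    class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items in [%s, %s], rule=%s, %s\n",
              x$name, x$item_count, x$item_min, x$item_max,
              x$scoring_rule, x$direction))
  if (length(x$reverse_items))
    cat("  reverse-coded items:", paste(x$reverse_items, collapse = ", "), "\n")
  if (!is.null(x$subscales))
    cat("  subscales:", paste(names(x$subscales), collapse = ", "), "\n")
  if (!is.null(x$cutoffs))
    cat("  cutoffs:", paste(sprintf("%s>=%s", x$cutoffs$label, x$cutoffs$lower),
                            collapse = ", "), "\n")
  invisible(x)
}

scale_def_from_list <- function(lst) {
  subs <- lst$subscales
  if (!is.null(subs) && length(subs) == 0) subs <- NULL
  cuts <- lst$cutoffs
  if (!is.null(cuts)) cuts <- data.frame(label = vapply(cuts, function(z) z$label, ""),
                                         lower = vapply(cuts, function(z) as.numeric(z$lower), 0))
  scale_definition(
    name = lst$name, item_count = lst$item_count,
    item_min = lst$item_min, item_max = lst$item_max,
    scoring_rule = lst$scoring_rule, direction = lst$direction,
    reverse_items = if (is.null(lst$reverse_items)) integer() else unlist(lst$reverse_items),
    subscales = if (is.null(subs)) NULL else lapply(subs, unlist),
    cutoffs = cuts,
    problematic_labels = if (is.null(lst$problematic_labels)) character() else unlist(lst$problematic_labels),
    score_min = lst$score_min, score_max = lst$score_max)
}

#' Load the packaged instrument and outcome definitions
#'
#' Reads a JSON configuration describing the four instruments (MHC-SF, SWLS,
#' DASS-21, BRS) and the six analysis outcomes (overall well-being, life
#' satisfaction, DASS depression/anxiety/stress on the doubled
#' DASS-42-equivalent metric, resilience) with their severity cutoff tables.
#' The shipped numeric cutoffs for "high well-being" (MHC-SF total >= 48),
#' "high life satisfaction" (SWLS total >= 20) and BRS bands (normal >= 3.00,
#' high >= 4.31) are documented implementer defaults; users may point `path`
#' at an override file with the same structure.
#'
#' @param path Path to a scales JSON file; defaults to the packaged one.
#' @return A list with elements `instruments` (named list of
#'   [scale_definition()]s) and `outcomes` (named list of outcome
#'   definitions, each a `scale_definition` describing the derived score with
#'   its cutoffs, plus `instrument`/`subscale` provenance fields).
#' @export
default_scales <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scales.json", package = "dualchange", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  instruments <- lapply(raw$instruments, scale_def_from_list)
  outcomes <- lapply(names(raw$outcomes), function(nm) {
    o <- raw$outcomes[[nm]]
    cuts <- data.frame(label = vapply(o$cutoffs, function(z) z$label, ""),
                       lower = vapply(o$cutoffs, function(z) as.numeric(z$lower), 0))
    inst <- instruments[[o$instrument]]
    def <- scale_definition(
      name = nm,
      item_count = if (is.null(o$subscale)) inst$item_count else length(inst$subscales[[o$subscale]]),
      item_min = inst$item_min, item_max = inst$item_max,
      scoring_rule = inst$scoring_rule, direction = o$direction,
      cutoffs = cuts,
      problematic_labels = unlist(o$problematic_labels),
      score_min = o$score_min, score_max = o$score_max)
    def$instrument <- o$instrument
    def$subscale <- o$subscale
    def
  })
  names(outcomes) <- names(raw$outcomes)
  list(instruments = instruments, outcomes = outcomes)
}

#' Score one instrument from item responses
#'
#' Applies reverse coding where the instrument prescribes it, then aggregates
#' per the scale's scoring rule (`sum`, `sum_times_two`, or `mean`).  Subscale
#' scores use the same rule restricted to the subscale's items.
#'
#' @param responses Integer vector of item responses, length `item_count`.
#' @param scale A [scale_definition()].
#' @return List with `total` and (if the scale has subscales) a named numeric
#'   vector `subscales`.
#' @examples
#' brs <- default_scales()$instruments$brs
#' score_scale(c(1, 5, 1, 5, 1, 5), brs)$total  # all-minimum after reversal: 1
#' @export
score_scale <- function(responses, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (length(responses) != scale$item_count)
    stop_input("scale '%s': expected %d responses, got %d",
               scale$name, scale$item_count, length(responses))
  if (anyNA(responses))
    stop_input("scale '%s': missing item responses (complete-case policy: reject the record)",
               scale$name)
  bad <- which(responses < scale$item_min | responses > scale$item_max)
  if (length(bad))
    stop_input("scale '%s': response out of range [%s, %s] at item %d (value %s)",
               scale$name, scale$item_min, scale$item_max, bad[1], responses[bad[1]])
  vals <- responses
  if (length(scale$reverse_items))
    vals[scale$reverse_items] <- scale$item_min + scale$item_max - vals[scale$reverse_items]
  agg <- function(v) switch(scale$scoring_rule,
                            sum = sum(v),
                            sum_times_two = 2 * sum(v),
                            mean = mean(v))
  out <- list(total = agg(vals))
  if (!is.null(scale$subscales))
    out$subscales <- vapply(scale$subscales, function(idx) agg(vals[idx]), numeric(1))
  out
}

#' Map a score to its severity category
#'
#' Returns the label of the highest cutoff whose (inclusive) lower bound does
#' not exceed the score.  Because the first bound equals the scale minimum,
#' the mapping is total over the valid score range; a score exactly at a bound
#' receives that bound's label.
#'
#' @param score Numeric score (vectorised).
#' @param scale A [scale_definition()] with a cutoff table.
#' @return Character vector of cutoff labels.
#' @export
severity_category <- function(score, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  if (is.null(scale$cutoffs))
    stop_config("scale '%s' has no cutoff table", scale$name)
  out_of_bounds <- !is.na(score) & (score < scale$score_min - 1e-9 | score > scale$score_max + 1e-9)
  if (any(out_of_bounds))
    stop_input("scale '%s': score %s outside [%s, %s]",
               scale$name, score[out_of_bounds][1], scale$score_min, scale$score_max)
  idx <- findInterval(score + 1e-9, scale$cutoffs$lower)
  ifelse(is.na(score), NA_character_, scale$cutoffs$label[idx])
}

#' Flag problematic baseline scores per outcome
#'
#' An outcome is "problematic" when it fails its healthy criterion: severity
#' label in the outcome's `problematic_labels` (below "high" well-being or
#' life satisfaction, below "normal" resilience, or at/above "mild" on any
#' DASS subscale).  Composites follow by definition: `any_distress` is the OR
#' over the three DASS flags and `problematic_any` the OR over all six.
#'
#' @param panel Data frame of outcome panels (one row per participant at one
#'   timepoint) with the six outcome columns; see [generate_cohort()].
#' @param outcomes Named list of outcome definitions, as from
#'   [default_scales()]`$outcomes`.
#' @return Data frame: `participant_id` (if present in `panel`), one logical
#'   flag per outcome, `any_distress`, `problematic_any`.  Missing scores give
#'   `NA` flags; composites are computed when determinable under OR logic
#'   (a `TRUE` flag decides the composite even with other flags missing).
#' @export
classify_problematic <- function(panel, outcomes = default_scales()$outcomes) {
  nms <- names(outcomes)
  missing_cols <- setdiff(nms, names(panel))
  if (length(missing_cols))
    stop_input("panel lacks outcome column(s): %s", paste(missing_cols, collapse = ", "))
  flags <- lapply(nms, function(nm) {
    sc <- outcomes[[nm]]
    lab <- severity_category(panel[[nm]], sc)
    ifelse(is.na(lab), NA, lab %in% sc$problematic_labels)
  })
  names(flags) <- nms
  or_na <- function(m) {
    # OR with NA handling: TRUE wins, all-FALSE gives FALSE, else NA
    apply(m, 1, function(r) if (any(r %in% TRUE)) TRUE else if (anyNA(r)) NA else FALSE)
  }
  dass <- cbind(flags$dass_depression, flags$dass_anxiety, flags$dass_stress)
  res <- data.frame(flags, check.names = FALSE)
  res$any_distress <- or_na(dass)
  res$problematic_any <- or_na(as.matrix(res[, nms]))
  if ("participant_id" %in% names(panel))
    res <- cbind(participant_id = panel$participant_id, res)
  res
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{k} is the item count, \eqn{s_i^2} the item variances and
#' \eqn{s_T^2} the variance of the item sums.
#'
#' @param item_matrix Numeric matrix or data frame, participants in rows,
#'   items in columns; no missing cells (apply complete-case first).
#' @return Alpha, a scalar in \eqn{(-\infty, 1]}.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L) stop_input("cronbach_alpha needs >= 2 items")
  if (nrow(m) < 2L) stop_input("cronbach_alpha needs >= 2 participants")
  if (anyNA(m)) stop_input("cronbach_alpha: missing cells; apply complete-case first")
  total_var <- var(rowSums(m))
  if (total_var <= .Machine$double.eps)
    stop_degenerate("cronbach_alpha undefined: zero variance of total scores")
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Score a wide item-level table into an outcome panel
#'
#' Expects one row per participant x timepoint with columns
#' `<instrument>_<item#>` (e.g. `mhcsf_1` ... `mhcsf_14`, `dass21_1` ...),
#' plus `participant_id`, `cohort`, `timepoint`.  Rows with any missing item
#' for an instrument get `NA` for that instrument's outcomes (complete-case
#' per scale).
#'
#' @param items Data frame of item responses.
#' @param scales As returned by [default_scales()].
#' @return Outcome panel data frame with the six outcome columns.
#' @export
panel_from_items <- function(items, scales = default_scales()) {
  out <- items[, intersect(c("participant_id", "cohort", "timepoint"), names(items)), drop = FALSE]
  inst_scores <- lapply(scales$instruments, function(sc) {
    cols <- paste0(sc$name, "_", seq_len(sc$item_count))
    miss <- setdiff(cols, names(items))
    if (length(miss))
      stop_input("item table lacks column(s) %s for scale '%s'",
                 paste(miss, collapse = ", "), sc$name)
    m <- as.matrix(items[, cols])
    k <- 1 + if (is.null(sc$subscales)) 0 else length(sc$subscales)
    res <- apply(m, 1, function(r) {
      if (anyNA(r)) return(rep(NA_real_, k))
      s <- score_scale(r, sc)
      c(s$total, s$subscales)
    })
    # apply() drops to a vector when the scale has no subscales
    if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
  })
  names(inst_scores) <- names(scales$instruments)
  for (nm in names(scales$outcomes)) {
    o <- scales$outcomes[[nm]]
    block <- inst_scores[[o$instrument]]
    col <- if (is.null(o$subscale)) 1L else {
      1L + match(o$subscale, names(scales$instruments[[o$instrument]]$subscales))
    }
    out[[nm]] <- block[, col]
  }
  out
}

#' Write a scale definition to JSON
#'
#' Round-trips through the same structure [default_scales()] reads, so a
#' written definition re-read from disk scores identically.
#'
#' @param scale A [scale_definition()].
#' @param path Output path.
#' @export
write_scale_definition <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  lst <- unclass(scale)
  if (!is.null(lst$cutoffs))
    lst$cutoffs <- lapply(seq_len(nrow(lst$cutoffs)), function(i)
      list(label = lst$cutoffs$label[i], lower = lst$cutoffs$lower[i]))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a single scale definition written by [write_scale_definition()]
#' @param path JSON path.
#' @return A [scale_definition()].
#' @export
read_scale_definition <- function(path) {
  scale_def_from_list(jsonlite::read_json(path))
}
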