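# Shared fixtures and independent oracles for the test suite.

# Long-format panel from pre/post score matrices (participants x outcomes).
make_panel <- function(pre, post, ids = sprintf("P%03d", seq_len(nrow(pre))),
                       cohort = NULL) {
  stopifnot(identical(dim(pre), dim(post)))
  build <- function(m, tp) {
    df <- data.frame(participant_id = ids, timepoint = tp,
                     as.data.frame(m), stringsAsFactors = FALSE)
    if (!is.null(cohort)) df$cohort <- cohort
    df
  }
  rbind(build(pre, "pre"), build(post, "post"))
}

# A tiny 2-item toy scale with severity cutoffs, exhaustively checkable.
toy_scale <- function() {
  scale_definition("toy", item_count = 2, item_min = 0, item_max = 3,
                   scoring_rule = "sum", direction = "lower_is_better",
                   cutoffs = data.frame(label = c("normal", "mild", "severe"),
                                        lower = c(0, 3, 5)),
                   problematic_labels = c("mild", "severe"))
}

# Independent Mann-Whitney oracle: exhaustive enumeration of the U null
# distribution for small groups; returns U for the observed data and the
# exact two-sided p.
mw_enumerate <- function(x, y) {
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Paired t oracle used for the F = t^2 equivalences.
paired_t_oracle <- function(pre, post) {
  tt <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

# Per-participant brute-force recount of dual-factor patterns from an RCI
# table, written independently of change_pattern().
recount_patterns <- function(rci, grouping) {
  ids <- unique(rci$participant_id)
  out <- lapply(ids, function(id) {
    rows <- rci[rci$participant_id == id, ]
    imp <- rows$outcome[rows$classification == "reliably_improved"]
    iw <- any(grouping[imp] == "wellbeing")
    idist <- any(grouping[imp] == "distress")
    pat <- if (iw && idist) "both" else if (iw) "wellbeing_only" else
      if (idist) "distress_only" else "none"
    data.frame(participant_id = id, pattern = pat, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

default_outcomes_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_scales()$outcomes
    cache
  }
})
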