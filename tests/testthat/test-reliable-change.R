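grouping6 <- c(overall_wellbeing = "wellbeing", life_satisfaction = "wellbeing",
               dass_depression = "distress", dass_anxiety = "distress",
               dass_stress = "distress", resilience = "excluded")

test_that("se_diff evaluates the printed formula and flags degeneracy", {
  expect_equal(as.numeric(se_diff(10, 0.75)), 5.0)  # 10 * sqrt(0.25)
  z <- se_diff(10, 1)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_true(isTRUE(attr(se_diff(0, 0), "degenerate")))
  expect_error(se_diff(10, 1.2), class = "dualchange_input_error")
  # classic Jacobson-Truax variant
  expect_equal(as.numeric(se_diff(10, 0.5, variant = "jacobson_truax")), 10)
})

test_that("rci_score orients positive = improvement for both directions", {
  expect_equal(rci_score(20, 20, 5, "lower_is_better"), 0)
  expect_equal(rci_score(20, 10, 5, "lower_is_better"), 2.0)
  expect_equal(rci_score(40, 50, 5, "higher_is_better"), 2.0)
  # magnitude unchanged by orientation
  expect_equal(abs(rci_score(10, 20, 5, "lower_is_better")),
               abs(rci_score(10, 20, 5, "higher_is_better")))
  expect_error(rci_score(1, 2, 0, "lower_is_better"),
               class = "dualchange_degenerate_error")
})

test_that("classify_reliable uses strict 1.96 threshold both ways", {
  expect_equal(as.character(classify_reliable(c(1.96, 1.97, -2.5, -1.96, 0))),
               c("no_reliable_change", "reliably_improved",
                 "reliably_deteriorated", "no_reliable_change",
                 "no_reliable_change"))
  expect_error(classify_reliable(NaN), class = "dualchange_input_error")
})

test_that("change_pattern implements the 2x2 of dimension booleans", {
  rci <- data.frame(
    participant_id = rep(c("A", "B", "C", "D"), each = 3),
    outcome = rep(c("overall_wellbeing", "dass_depression", "resilience"), 4),
    classification = c("reliably_improved", "reliably_improved", "no_reliable_change",   # A: both
                       "no_reliable_change", "reliably_improved", "no_reliable_change",  # B: distress only
                       "reliably_improved", "no_reliable_change", "no_reliable_change",  # C: wellbeing only
                       "no_reliable_change", "reliably_deteriorated", "reliably_improved"), # D: none
    stringsAsFactors = FALSE)
  pat <- change_pattern(rci, grouping6)
  expect_equal(as.character(pat$pattern), c("both", "distress_only", "wellbeing_only", "none"))
  # D improved only on an excluded outcome: counts as improvement but not a dimension
  expect_true(pat$any_reliable_improvement[4])
  expect_true(pat$any_reliable_change[4])
  expect_error(change_pattern(rci, grouping6[-1]), class = "dualchange_config_error")
  # four patterns partition the participants
  expect_equal(sum(table(pat$pattern)), 4)
})

test_that("pattern_frequencies retains exact fractions with display rounding", {
  mk <- function(pattern, any_change, any_imp) {
    data.frame(participant_id = seq_along(pattern), improved_wellbeing = NA,
               improved_distress = NA,
               pattern = factor(pattern, levels = c("both", "wellbeing_only",
                                                    "distress_only", "none")),
               any_reliable_change = any_change,
               any_reliable_improvement = any_imp)
  }
  pat <- mk(rep(c("both", "wellbeing_only", "distress_only", "none"), c(42, 24, 17, 6)),
            any_change = rep(c(TRUE, FALSE), c(83, 6)),
            any_imp = rep(c(TRUE, FALSE), c(83, 6)))
  fq <- pattern_frequencies(pat)
  expect_equal(fq$n, 89)
  expect_equal(fq$n_any_improvement, 83)
  expect_equal(fq$improvement_split$count, c(42, 24, 17))
  expect_equal(fq$improvement_split$fraction, c(42, 24, 17) / 83)
  expect_equal(fq$improvement_split$display_pct, c(51, 29, 20))
  # degenerate extremes
  all_none <- mk(rep("none", 5), rep(FALSE, 5), rep(FALSE, 5))
  fq0 <- pattern_frequencies(all_none)
  expect_equal(fq0$n_any_improvement, 0)
  expect_true(all(is.na(fq0$improvement_split$fraction)))
  one <- mk("both", TRUE, TRUE)
  expect_equal(pattern_frequencies(one)$improvement_split$display_pct[1], 100)
  expect_error(pattern_frequencies(pat[0, ]), class = "dualchange_input_error")
})

test_that("rci_table + change_pattern agree with a brute-force recount", {
  cfg <- simulation_config(n_participants = 500, seed = 101,
                           true_change = c(0, 0, -5, 0, 0, 0))  # depression-only effect
  cohort <- generate_cohort(cfg)
  rci <- rci_table(cohort, default_outcomes_cached())
  pat <- change_pattern(rci, grouping6)
  oracle <- recount_patterns(rci, grouping6)
  expect_equal(as.character(pat$pattern)[match(oracle$participant_id, pat$participant_id)],
               oracle$pattern)
  # depression-driven world: distress-involved patterns dominate wellbeing-only
  counts <- table(pat$pattern)
  expect_gt(counts[["distress_only"]] + counts[["both"]], counts[["wellbeing_only"]])
})

test_that("subgroup breakdown uses the met-threshold AND improved intersection", {
  cfg <- simulation_config(n_participants = 500, seed = 102,
                           true_change = c(0, 0, -5, 0, 0, 0))
  cohort <- generate_cohort(cfg)
  outcomes <- default_outcomes_cached()
  rci <- rci_table(cohort, outcomes)
  pat <- change_pattern(rci, grouping6)
  pre <- cohort[cohort$timepoint == "pre", ]
  pre$dass_depression <- pmin(pmax(pre$dass_depression, 0), 42)
  pre$dass_anxiety <- pmin(pmax(pre$dass_anxiety, 0), 42)
  pre$dass_stress <- pmin(pmax(pre$dass_stress, 0), 42)
  pre$overall_wellbeing <- pmin(pmax(pre$overall_wellbeing, 0), 70)
  pre$life_satisfaction <- pmin(pmax(pre$life_satisfaction, 5), 35)
  pre$resilience <- pmin(pmax(pre$resilience, 1), 5)
  flags <- classify_problematic(pre, outcomes)
  sub <- subgroup_pattern_frequencies(rci, flags, "depression", grouping6)

  # independent recount: flagged at baseline, >=1 reliable improvement anywhere,
  # distress dimension restricted to dass_depression
  met <- flags$participant_id[flags$dass_depression]
  improved <- pat$participant_id[pat$any_reliable_improvement]
  keep <- intersect(met, improved)
  expect_equal(sub$denominator, length(keep))
  sub_grouping <- grouping6
  sub_grouping[c("dass_anxiety", "dass_stress")] <- "excluded"
  oracle <- recount_patterns(rci[rci$participant_id %in% keep, ], sub_grouping)
  expect_equal(sub$counts, setNames(as.integer(table(
    factor(oracle$pattern, levels = c("both", "wellbeing_only", "distress_only", "none")))),
    c("both", "wellbeing_only", "distress_only", "none")))
  # subgroup denominator never exceeds the full improvement denominator
  expect_lte(sub$denominator, sum(pat$any_reliable_improvement))
  expect_error(subgroup_pattern_frequencies(rci, flags, "mood", grouping6),
               class = "dualchange_config_error")
})

test_that("no participant meets the threshold -> explicit zero denominator", {
  cfg <- simulation_config(n_participants = 30, seed = 103)
  cohort <- generate_cohort(cfg)
  outcomes <- default_outcomes_cached()
  rci <- rci_table(cohort, outcomes)
  flags <- data.frame(participant_id = unique(cohort$participant_id),
                      dass_depression = FALSE)
  sub <- subgroup_pattern_frequencies(rci, flags, "depression", grouping6)
  expect_equal(sub$denominator, 0)
  expect_true(all(is.na(sub$display_pct)))
})

test_that("classification is invariant to sign/direction flips (orientation)", {
  set.seed(104)
  n <- 60
  pre <- rnorm(n, 20, 5)
  post <- pre - rnorm(n, 2, 4)
  panel_lo <- make_panel(cbind(x = pre), cbind(x = post))
  outs_lo <- list(x = list(direction = "lower_is_better"))
  outs_hi <- list(x = list(direction = "higher_is_better"))
  rci_lo <- rci_table(panel_lo, outs_lo)
  panel_hi <- make_panel(cbind(x = -pre), cbind(x = -post))
  rci_hi <- rci_table(panel_hi, outs_hi)
  expect_equal(rci_lo$rci_value, rci_hi$rci_value)
  expect_equal(as.character(rci_lo$classification), as.character(rci_hi$classification))
})

test_that("small instances match exhaustive hand computation", {
  # 3 participants, 1 outcome; hand-computed RCI
  pre <- c(10, 20, 30)
  post <- c(10, 14, 30)
  panel <- make_panel(cbind(y = pre), cbind(y = post))
  rci <- rci_table(panel, list(y = list(direction = "lower_is_better")))
  d <- pre - post                      # 0, 6, 0
  r <- cor(pre, post)
  sediff <- sd(d) * sqrt(1 - r)
  expect_equal(rci$se_diff, rep(sediff, 3))
  expect_equal(rci$rci_value, d / sediff)
  expect_equal(as.character(rci$classification),
               ifelse(d / sediff > 1.96, "reliably_improved", "no_reliable_change"))
})
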