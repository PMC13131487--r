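p5 <- generate_protocol(5)

test_that("dF/F is zero for constant traces and exact for known peaks", {
  tr <- make_toy_trace(rep(0, 5), p5)
  dff <- compute_dff(tr, p5)
  expect_true(all(dff$dff == 0))

  tr2 <- make_toy_trace(c(1, 1, 1, 1, 1), p5)   # F doubles at each peak
  e <- trial_excitability(compute_dff(tr2, p5), p5)
  expect_equal(e$e, rep(1, 5))
  expect_equal(e$trial_index, 0:4)
})

test_that("dF/F is invariant to detector gain", {
  tr <- make_toy_trace(c(0.8, 0.9, 0.4, 0.7, 0.8), p5)
  for (g in c(0.01, 3, 1000)) {
    tr_g <- tr
    tr_g$F <- tr_g$F * g
    expect_equal(compute_dff(tr_g, p5)$dff, compute_dff(tr, p5)$dff,
                 tolerance = 1e-12)
  }
})

test_that("non-positive baseline fluorescence raises a degenerate-baseline condition", {
  tr <- make_toy_trace(rep(0.5, 5), p5)
  tr$F[tr$time_s < 15] <- -1   # poison the first F0 window
  expect_error(compute_dff(tr, p5), class = "degenerate-baseline")
})

test_that("trial excitability is the plain max, without clipping", {
  # all-negative response window still yields its (negative) max
  tr <- make_toy_trace(rep(0, 5), p5)
  dip <- tr$time_s >= 615 & tr$time_s < 645
  tr$F[dip] <- c(95, 90)[1 + (seq_len(sum(dip)) %% 2)]
  e <- trial_excitability(compute_dff(tr, p5), p5)
  expect_equal(e$e[e$trial_index == 2], -0.05)
})

test_that("baseline QC applies the strict 15% rule on the chosen denominator", {
  expect_true(qc_baseline(1.00, 1.10))    # 0.10/1.05 = 0.0952
  expect_false(qc_baseline(1.00, 1.20))   # 0.20/1.10 = 0.182
  expect_true(qc_baseline(2.5, 2.5))
  expect_false(qc_baseline(0, 0))         # degenerate mean fails, no error
  expect_false(qc_baseline(1, -1))
  expect_false(qc_baseline(NaN, 1))
  # alternative denominator: relative to the first trial
  expect_true(qc_baseline(1.0, 1.14, denominator = "first"))
  expect_false(qc_baseline(1.0, 1.16, denominator = "first"))
})

test_that("classification follows the strict +/-15% rule around the two-trial mean", {
  expect_equal(classify_cell(1, 1, 0.80)$label, "inhibited")
  expect_equal(classify_cell(1, 1, 0.85)$label, "unchanged")  # boundary
  expect_equal(classify_cell(1, 1, 1.15)$label, "unchanged")  # boundary
  expect_equal(classify_cell(1, 1, 1.16)$label, "enhanced")
  frag <- classify_cell(1.0, 1.1, 1.30)   # baseline 1.05, r = 1.238
  expect_equal(frag$label, "enhanced")
  expect_equal(frag$relative_excitability, 1.30 / 1.05)
  expect_equal(classify_cell(1.0, 1.2, 1.0)$label, "excluded")
  expect_equal(classify_cell(1.0, 1.2, 1.0)$reason, "baseline-qc")
})

test_that("label is a two-threshold step function of relative excitability", {
  r_grid <- seq(0.5, 1.5, by = 0.001)
  labels <- vapply(r_grid, function(r) classify_cell(1, 1, r)$label, "")
  changes <- which(labels[-1] != labels[-length(labels)])
  expect_length(changes, 2L)
  expect_equal(r_grid[changes[1] + 1], 0.85)   # first inhibited->unchanged
  expect_equal(r_grid[changes[2] + 1], 1.151)  # first enhanced value
  # monotone: decreasing e_drug never moves toward enhanced
  ord <- factor(labels, levels = c("inhibited", "unchanged", "enhanced"))
  expect_true(all(diff(as.integer(ord)) >= 0))
})

test_that("diameter strata use the inclusive 25-35 um medium band", {
  expect_equal(stratify_by_diameter(c(24.9, 25, 35, 35.1, NA)),
               c("small", "medium", "medium", "large", "unknown"))
  expect_error(stratify_by_diameter(-1), class = "invalid-measurement")
})

test_that("population summary counts conserve and fractions use QC-passing cells", {
  cls <- data.frame(
    label = c(rep("inhibited", 4), "enhanced", rep("unchanged", 3),
              rep("excluded", 2)),
    stratum = "unknown", relative_excitability = NA_real_)
  s <- summarize_population(cls)
  expect_equal(s$overall$fraction_inhibited, 0.5)
  expect_equal(with(s$overall,
                    n_inhibited + n_enhanced + n_unchanged + n_excluded),
               s$overall$n_total)
  all_exc <- data.frame(label = rep("excluded", 3), stratum = "unknown")
  s2 <- summarize_population(all_exc)
  expect_true(s2$overall$undefined)
  expect_true(is.na(s2$overall$fraction_inhibited))
})

test_that("score_calcium runs the full per-cell pipeline on toy traces", {
  e_mat <- rbind(
    c(1.0, 1.0, 0.5, 1.0, 1.0),   # inhibited, full washout recovery
    c(1.0, 1.1, 1.3, 1.0, 1.0),   # enhanced (r = 1.238)
    c(1.0, 1.0, 1.0, 1.0, 1.0),   # unchanged
    c(1.0, 1.3, 1.0, 1.0, 1.0))   # fails baseline QC
  traces <- make_toy_population(e_mat, p5,
                                diameters = c(20, 30, 40, NA))
  cls <- score_calcium(traces, p5)
  expect_equal(cls$label, c("inhibited", "enhanced", "unchanged", "excluded"))
  expect_equal(cls$stratum, c("small", "medium", "large", "unknown"))
  expect_equal(cls$washout_ratio[1], 1.0)
  expect_equal(cls$relative_excitability[1], 0.5)
  e_tab <- attr(cls, "excitability")
  expect_equal(nrow(e_tab), 4 * 5)
})

test_that("washout ratio is absent without post-drug trials", {
  p3 <- generate_protocol(3)
  e <- data.frame(trial_index = 0:2, e = c(1, 1, 0.5))
  expect_true(is.na(washout_check(e, p3)))
  e5 <- data.frame(trial_index = 0:4, e = c(1, 1, 0.5, 0.5, 0.5))
  expect_equal(washout_check(e5, p5), 0.5)  # persistent effect
})
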