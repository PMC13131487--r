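test_that("von Frey threshold is the lowest filament with >=5/10 responses", {
  expect_equal(von_frey_threshold(c(0.04, 0.16, 0.6), c(2, 5, 8)), 0.16)
  expect_equal(von_frey_threshold(0.008, 10), 0.008)
  above <- von_frey_threshold(c(0.04, 0.16, 0.6), c(2, 4, 4))
  expect_true(is.infinite(above))
  expect_true(attr(above, "above_range"))
  expect_error(von_frey_threshold(numeric(), numeric()),
               class = "invalid-argument")
  expect_error(von_frey_threshold(c(0.1, 0.1), c(5, 5)),
               class = "invalid-argument")
  expect_error(von_frey_threshold(0.1, 11), class = "invalid-argument")
})

test_that("von Frey threshold is monotone in added responses", {
  forces <- c(0.008, 0.04, 0.16, 0.6, 1, 2, 4)
  base <- c(0, 1, 2, 6, 7, 8, 9)
  t0 <- von_frey_threshold(forces, base)
  for (i in seq_along(forces)) {
    bumped <- base
    bumped[i] <- min(10, bumped[i] + 4)
    expect_lte(von_frey_threshold(forces, bumped), t0)
  }
})

test_that("brush score is the mean of per-trial maxima; cutoff inclusive", {
  s <- brush_allodynia(list(c(0, 2), c(1, 0), c(2, 1)))
  expect_equal(s$score, 5 / 3)
  expect_true(s$allodynic)
  s2 <- brush_allodynia(list(1, 1, 2))
  expect_equal(s2$score, 4 / 3)
  expect_false(s2$allodynic)
  # exact boundary reachable with two trials: maxima (1, 2) -> mean 1.5
  s3 <- brush_allodynia(list(1, 2))
  expect_equal(s3$score, 1.5)
  expect_true(s3$allodynic)
  expect_error(brush_allodynia(list()), class = "invalid-argument")
  expect_error(brush_allodynia(list(c(1, 2), numeric())),
               class = "invalid-argument")
  expect_error(brush_allodynia(list(c(0, 4))), class = "invalid-argument")
  expect_error(brush_allodynia(list(1.5)), class = "invalid-argument")
})

test_that("pinprick validity, onsets and AUC follow the stated thresholds", {
  # weak contact (1.4 V peak) -> invalid
  weak <- simulate_pinprick_trial(contact_peak_V = 1.4)
  expect_false(pinprick_metrics(weak)$valid)
  # strong contact, constant 0.2 V accelerometer -> rectangle AUC
  tr <- simulate_pinprick_trial(contact_peak_V = 3, movement_peak_V = 0)
  tr$accelerometer$V <- 0.2
  m <- pinprick_metrics(tr)
  expect_true(m$valid)
  expect_equal(m$stimulus_onset_s, tr$truth$contact_on_s, tolerance = 2e-3)
  expect_equal(m$magnitude_Vs, 0.2 * 0.4, tolerance = 1e-6)
  expect_equal(m$movement_onset_s, m$stimulus_onset_s)  # already >= 0.15 V
  # sub-threshold movement: onset absent, magnitude still computed
  still <- simulate_pinprick_trial(contact_peak_V = 3, movement_peak_V = 0.1)
  m2 <- pinprick_metrics(still)
  expect_true(m2$valid)
  expect_true(is.na(m2$movement_onset_s))
  expect_gte(m2$magnitude_Vs, 0)
  expect_error(pinprick_metrics(list(button_time_s = 1)),
               class = "missing-channel")
})

test_that("luminance ratio masks zero frames and reports both summary forms", {
  eq <- data.frame(ipsi = rep(5, 100), contra = rep(5, 100))
  r <- luminance_ratio(eq)
  expect_equal(r$mean_log10_ratio, 0)
  expect_equal(r$ratio_of_means, 1)
  half <- data.frame(ipsi = rep(2.5, 50), contra = rep(5, 50))
  expect_equal(luminance_ratio(half)$mean_log10_ratio, -log10(2))
  masked <- data.frame(ipsi = c(0, 5, 5), contra = c(5, 0, 5))
  rm_ <- luminance_ratio(masked)
  expect_equal(rm_$n_masked, 2L)
  expect_equal(rm_$mean_log10_ratio, 0)
  dead <- data.frame(ipsi = c(0, 0), contra = c(1, 0))
  expect_true(luminance_ratio(dead)$undefined)
  # antisymmetry under swapping paws
  set.seed(1)
  s <- data.frame(ipsi = runif(200, 1, 10), contra = runif(200, 1, 10))
  swapped <- data.frame(ipsi = s$contra, contra = s$ipsi)
  expect_equal(luminance_ratio(swapped)$mean_log10_ratio,
               -luminance_ratio(s)$mean_log10_ratio)
})

test_that("locomotion split recovers planted states and splits the ratios", {
  s <- simulate_luminance_session(duration_s = 120, fps = 25,
                                  ipsi_factor = 0.6,
                                  locomotion_fraction = 0.4,
                                  speed_locomoting = 8, speed_resting = 0.2,
                                  speed_noise_sd = 0.2, seed = 21)
  sp <- locomotion_split(s)
  acc <- mean(sp$locomoting == s$truth$locomoting)
  expect_gt(acc, 0.95)
  expect_false(is.null(sp$ratios$locomoting))
  expect_false(is.null(sp$ratios$non_locomoting))
  # zero speed -> all frames non-locomoting
  s0 <- simulate_luminance_session(duration_s = 10, fps = 25,
                                   locomotion_fraction = 0.5,
                                   speed_locomoting = 0, speed_resting = 0,
                                   speed_noise_sd = 0, seed = 22)
  expect_true(all(!locomotion_split(s0)$locomoting))
  s_nospeed <- simulate_luminance_session(duration_s = 10, seed = 23)
  expect_error(locomotion_split(s_nospeed), class = "missing-channel")
})

test_that("preference fractions are complementary over the two sides", {
  sides <- c(rep("A", 30), rep("B", 70))
  expect_equal(preference_fraction(sides, "A"), 0.3)
  expect_equal(preference_fraction(sides, "A") +
                 preference_fraction(sides, "B"), 1)
  expect_equal(preference_fraction(rep("A", 10), "A"), 1)
  expect_equal(preference_fraction(rep(c("A", "B"), 50), "A"), 0.5)
  expect_error(preference_fraction(character(), "A"),
               class = "invalid-argument")
  expect_error(preference_fraction(c("A", "C"), "A"),
               class = "invalid-argument")
})

test_that("event summaries count within the window and censor empty sessions", {
  s <- event_summary(c(5, 12, 40), 60)
  expect_equal(s$count, 3L)
  expect_equal(s$latency_s, 5)
  expect_false(s$censored)
  none <- event_summary(numeric(), 60)
  expect_equal(none$count, 0L)
  expect_equal(none$latency_s, 60)
  expect_true(none$censored)
  expect_equal(event_summary(59.9, 60)$count, 1L)   # boundary inside
  expect_equal(event_summary(c(10, 70), 60)$count, 1L)
  expect_error(event_summary(-1, 60), class = "invalid-argument")
})
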