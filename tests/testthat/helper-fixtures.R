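# Shared fixture builders. All fixtures are constructed in code so tests
# are self-contained and deterministic.

# Flat-baseline trace whose per-trial max dF/F equals e_per_trial exactly:
# F = f0 everywhere except a single-sample peak inside each response window.
make_toy_trace <- function(e_per_trial, protocol, f0 = 100, id = "c1",
                           diameter_um = NA_real_) {
  stopifnot(length(e_per_trial) == n_trials(protocol))
  dt <- 1 / protocol$sampling_rate_hz
  t_end <- max(protocol$pulse_onsets_s) + protocol$response_window_s
  time_s <- seq(0, t_end, by = dt)
  F <- rep(f0, length(time_s))
  for (k in seq_along(e_per_trial)) {
    peak_t <- protocol$pulse_onsets_s[k] + 2 * dt
    i <- which.min(abs(time_s - peak_t))
    F[i] <- f0 * (1 + e_per_trial[k])
  }
  data.frame(cell_id = id, time_s = time_s, F = F,
             diameter_um = diameter_um)
}

# Stack several toy traces into one tidy table.
make_toy_population <- function(e_matrix, protocol, diameters = NULL) {
  n <- nrow(e_matrix)
  if (is.null(diameters)) diameters <- rep(NA_real_, n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_toy_trace(e_matrix[i, ], protocol, id = sprintf("toy%02d", i),
                   diameter_um = diameters[i])
  }))
}

# Independent brute-force labeller for toy traces: direct max over samples
# plus plain arithmetic; shares no code with the pipeline under test.
brute_force_labels <- function(traces, protocol) {
  vapply(split(traces, traces$cell_id), function(tr) {
    e <- vapply(seq_along(protocol$pulse_onsets_s), function(k) {
      on <- protocol$pulse_onsets_s[k]
      base <- tr$F[tr$time_s >= on - protocol$f0_window_s & tr$time_s < on]
      resp <- tr$F[tr$time_s >= on &
                     tr$time_s < on + protocol$response_window_s]
      f0 <- sum(base) / length(base)
      max((resp - f0) / f0)
    }, numeric(1))
    e0 <- e[1]; e1 <- e[2]; ed <- e[protocol$drug_trial_index + 1]
    m <- (e0 + e1) / 2
    if (m <= 0 || abs(e0 - e1) / m >= 0.15) return("excluded")
    r <- ed / m
    if (r < 0.85) "inhibited" else if (r > 1.15) "enhanced" else "unchanged"
  }, character(1))
}

default_protocol <- function() generate_protocol(5)
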