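#' Simulation configuration for the calcium-imaging population generator
#'
#' Bundles the knobs of [simulate_population()]. Defaults emulate a typical
#' dissociated DRG culture imaged at 2 Hz: KCl transients roughly doubling
#' fluorescence, a 40% responder fraction, drug halving the responders'
#' drug-trial transient, and low additive noise. All of these are nominal
#' (the source assay does not report its noise levels or transient
#' kinetics) and fully configurable.
#'
#' @param seed Root seed; per-generator streams are derived from it (see
#'   the package vignette).
#' @param n_cells Number of cells.
#' @param responder_fraction Fraction of cells whose drug-trial transient is
#'   scaled by `effect_multiplier` (in `[0, 1]`).
#' @param effect_multiplier Multiplicative scale applied to responders'
#'   drug-trial transient amplitude (1 = null effect; 0.5 = halved).
#' @param noise_sd Additive Gaussian noise SD, as a fraction of baseline
#'   fluorescence.
#' @param drift_per_min Linear baseline drift per minute, as a fraction of
#'   baseline fluorescence (photobleaching is negative drift).
#' @param transient_decay_s Single-exponential decay constant of the KCl
#'   transient, seconds.
#' @param transient_amplitude Mean transient amplitude as a multiple of
#'   baseline fluorescence (peak dF/F around this value).
#' @param diameter_distribution Data frame with columns `stratum`
#'   (`small`/`medium`/`large`), `prob`, `mean_um`, `sd_um`; diameters are
#'   drawn per stratum from normals truncated at zero.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells = 500L, responder_fraction = 0.4,
                       effect_multiplier = 0.5, noise_sd = 0.01,
                       drift_per_min = 0, transient_decay_s = 8,
                       transient_amplitude = 2,
                       diameter_distribution = default_diameters()) {
  check_count(seed, "seed")
  n_cells <- check_count(n_cells, "n_cells")
  check_number(responder_fraction, "responder_fraction", nonneg = TRUE)
  if (responder_fraction > 1)
    ns_stop("responder_fraction must be in [0, 1]", "invalid-argument")
  check_number(effect_multiplier, "effect_multiplier", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(drift_per_min, "drift_per_min")
  check_number(transient_decay_s, "transient_decay_s", positive = TRUE)
  check_number(transient_amplitude, "transient_amplitude", positive = TRUE)
  dd <- diameter_distribution
  stopifnot(is.data.frame(dd),
            all(c("stratum", "prob", "mean_um", "sd_um") %in% names(dd)),
            all(dd$prob >= 0), sum(dd$prob) > 0)
  structure(list(seed = as.integer(seed), n_cells = n_cells,
                 responder_fraction = responder_fraction,
                 effect_multiplier = effect_multiplier, noise_sd = noise_sd,
                 drift_per_min = drift_per_min,
                 transient_decay_s = transient_decay_s,
                 transient_amplitude = transient_amplitude,
                 diameter_distribution = dd),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_diameters <- function() {
  data.frame(stratum = c("small", "medium", "large"),
             prob = c(0.5, 0.3, 0.2),
             mean_um = c(20, 30, 40),
             sd_um = c(2.5, 2.5, 3))
}

#' Simulate a population of KCl-pulsed calcium traces with known truth
#'
#' Each cell's raw fluorescence is
#' `F(t) = F0 * (1 + drift(t)) + transient(t) + noise`, where each KCl pulse
#' contributes an instantaneous rise at pulse onset followed by a
#' single-exponential decay, the per-cell transient amplitude is lognormal
#' around `transient_amplitude * F0`, and noise is i.i.d. Gaussian with SD
#' `noise_sd * F0`. A `responder_fraction` of cells (chosen at random) has
#' its drug-trial transient amplitude multiplied by `effect_multiplier`.
#' Identical configs (including the seed) give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param protocol A [stimulus_protocol()] (see [generate_protocol()]).
#' @return A list with `traces` (tidy table: `cell_id`, `time_s`, `F`,
#'   `diameter_um`) and `truth` (per-cell: `cell_id`, `responder`,
#'   `diameter_um`, `stratum`, `amplitude`). `n_cells = 0` yields empty
#'   tables.
#' @export
simulate_population <- function(config, protocol) {
  stopifnot(inherits(config, "sim_config"),
            inherits(protocol, "stimulus_protocol"))
  n <- config$n_cells
  if (n == 0L) {
    empty_tr <- data.frame(cell_id = character(), time_s = numeric(),
                           F = numeric(), diameter_um = numeric())
    empty_gt <- data.frame(cell_id = character(), responder = logical(),
                           diameter_um = numeric(), stratum = character(),
                           amplitude = numeric())
    return(list(traces = empty_tr, truth = empty_gt))
  }
  dt <- 1 / protocol$sampling_rate_hz
  t_end <- max(protocol$pulse_onsets_s) + protocol$response_window_s
  time_s <- seq(0, t_end, by = dt)
  nt <- length(time_s)
  ids <- sprintf("cell%04d", seq_len(n))

  set.seed(stream_seed(config$seed, "diameters"))
  dd <- config$diameter_distribution
  strata <- sample(dd$stratum, n, replace = TRUE,
                   prob = dd$prob / sum(dd$prob))
  mu <- dd$mean_um[match(strata, dd$stratum)]
  sdv <- dd$sd_um[match(strata, dd$stratum)]
  diam <- stats::rnorm(n, mu, sdv)
  while (any(diam <= 0)) {   # truncate at zero by redraw
    bad <- diam <= 0
    diam[bad] <- stats::rnorm(sum(bad), mu[bad], sdv[bad])
  }

  set.seed(stream_seed(config$seed, "population"))
  responder <- seq_len(n) %in%
    sample.int(n, size = round(config$responder_fraction * n))
  f0 <- stats::runif(n, 80, 120)
  amp <- config$transient_amplitude *
    stats::rlnorm(n, meanlog = 0, sdlog = 0.25)   # peak dF/F spread

  drug_k <- protocol$drug_trial_index + 1L
  # transient kernel per pulse: step at onset, exp decay
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    transient <- numeric(nt)
    for (k in seq_along(protocol$pulse_onsets_s)) {
      a <- amp[i] * f0[i]
      if (k == drug_k && responder[i]) a <- a * config$effect_multiplier
      on <- protocol$pulse_onsets_s[k]
      idx <- time_s >= on
      transient[idx] <- transient[idx] +
        a * exp(-(time_s[idx] - on) / config$transient_decay_s)
    }
    drift <- config$drift_per_min * time_s / 60
    noise <- stats::rnorm(nt, 0, config$noise_sd * f0[i])
    traces[[i]] <- data.frame(
      cell_id = ids[i], time_s = time_s,
      F = f0[i] * (1 + drift) + transient + noise,
      diameter_um = diam[i])
  }
  list(
    traces = do.call(rbind, traces),
    truth = data.frame(cell_id = ids, responder = responder,
                       diameter_um = diam,
                       stratum = stratify_by_diameter(diam),
                       amplitude = amp)
  )
}

#' Simulate a gene-by-subtype expression matrix with planted restricted genes
#'
#' Builds a nonnegative expression-summary matrix in which a planted gene
#' set is guaranteed restricted (above `on_threshold` in at least one CGRP+
#' subtype, below `off_threshold` in every LTMR and proprioceptor subtype)
#' and a disjoint decoy set violates restriction by being expressed in an
#' LTMR subtype. Remaining genes get low background expression. Dropout
#' zeroes each planted on-value independently (planted genes keep at least
#' one CGRP+ subtype on, so recovery at `dropout = 0` is exact by
#' construction).
#'
#' @param n_genes Total number of genes (ids `g0001`, ...).
#' @param subtypes Subtype annotation from [subtype_annotation()].
#' @param planted_restricted Character vector of gene ids to plant as
#'   CGRP-restricted (must be in the gene universe).
#' @param planted_broad_k Number of CGRP+ subtypes in which each planted
#'   gene is on: 1 for exclusive genes, or up to the number of CGRP+
#'   subtypes; vector recycled over planted genes.
#' @param n_decoys Number of decoy genes (restricted-looking but on in one
#'   LTMR subtype).
#' @param dropout Probability of zeroing any individual planted on-value
#'   beyond the first.
#' @param on_level,off_level Expression values used for "on" and background
#'   cells (defaults 1 and 0.02, on the package's default 0.1 threshold
#'   scale).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A list: `matrix` (genes x subtypes), `truth` (per-gene
#'   `planted` / `decoy` flags and the planted breadth).
#' @export
simulate_expression_matrix <- function(n_genes, subtypes, planted_restricted,
                                       planted_broad_k = 1L, n_decoys = 10L,
                                       dropout = 0, on_level = 1,
                                       off_level = 0.02, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  stopifnot(is.data.frame(subtypes))
  check_number(dropout, "dropout", nonneg = TRUE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!all(planted_restricted %in% genes))
    ns_stop("planted gene not in the gene universe", "invalid-argument")
  cgrp <- subtypes$subtype_id[subtypes$class == "CGRP"]
  off_classes <- subtypes$subtype_id[subtypes$class %in%
                                       c("LTMR", "proprioceptor")]
  if (length(cgrp) == 0L || length(off_classes) == 0L)
    ns_stop("need at least one CGRP and one LTMR/proprioceptor subtype",
            "invalid-argument")
  set.seed(stream_seed(seed, "expression"))
  m <- matrix(stats::runif(n_genes * nrow(subtypes), 0, off_level),
              nrow = n_genes,
              dimnames = list(genes, subtypes$subtype_id))
  k <- rep_len(pmin(planted_broad_k, length(cgrp)),
               length(planted_restricted))
  for (j in seq_along(planted_restricted)) {
    on_sub <- sample(cgrp, k[j])
    vals <- on_level * stats::runif(k[j], 1, 2)
    if (dropout > 0 && k[j] > 1L) {
      drop <- stats::runif(k[j]) < dropout
      drop[1L] <- FALSE            # always keep one subtype on
      vals[drop] <- 0
    }
    m[planted_restricted[j], on_sub] <- vals
  }
  decoy_pool <- setdiff(genes, planted_restricted)
  decoys <- if (n_decoys > 0L) sample(decoy_pool, min(n_decoys,
                                                      length(decoy_pool)))
            else character()
  for (g in decoys) {
    m[g, sample(cgrp, 1L)] <- on_level * stats::runif(1, 1, 2)
    m[g, sample(off_classes, 1L)] <- on_level * stats::runif(1, 1, 2)
  }
  list(matrix = m,
       truth = data.frame(gene = genes,
                          planted = genes %in% planted_restricted,
                          decoy = genes %in% decoys,
                          breadth = ifelse(genes %in% planted_restricted,
                                           k[match(genes,
                                                   planted_restricted)], 0L)))
}

#' Simulate a paw-luminance session
#'
#' Ipsilateral and contralateral hind-paw luminance at `fps` over
#' `duration_s` (defaults: 25 fps, 30 min, i.e. 45,000 frames), with the
#' ipsilateral paw's luminance reduced by `ipsi_factor` (weight-bearing
#' shift after nerve injury). Optionally plants alternating
#' locomoting/resting bouts reflected in a centroid-speed channel.
#'
#' @param duration_s Session length in seconds (default 1800).
#' @param fps Frame rate (default 25).
#' @param ipsi_factor True ipsi/contra luminance ratio (1 = symmetric).
#' @param base_luminance Mean contralateral luminance (arbitrary units).
#' @param noise_sd Multiplicative noise SD on each paw's luminance.
#' @param locomotion_fraction Fraction of frames in the locomoting state;
#'   0 disables the speed channel.
#' @param bout_s Mean bout length for the locomotion state, seconds.
#' @param speed_locomoting,speed_resting Mean centroid speed (cm/s) per
#'   state.
#' @param speed_noise_sd Gaussian SD of the speed channel.
#' @param seed Integer seed.
#' @return A list of class `luminance_session`: `frames` data frame
#'   (`time_s`, `ipsi`, `contra`, and `speed_cm_s` if enabled), `fps`, and
#'   `truth` (planted ratio and, if enabled, the planted locomotion mask).
#' @export
simulate_luminance_session <- function(duration_s = 1800, fps = 25,
                                       ipsi_factor = 1, base_luminance = 100,
                                       noise_sd = 0.05,
                                       locomotion_fraction = 0, bout_s = 20,
                                       speed_locomoting = 8,
                                       speed_resting = 0.3,
                                       speed_noise_sd = 0.5, seed = 1L) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(fps, "fps", positive = TRUE)
  check_number(ipsi_factor, "ipsi_factor", positive = TRUE)
  set.seed(stream_seed(seed, "luminance"))
  n <- round(duration_s * fps)
  time_s <- (seq_len(n) - 1) / fps
  contra <- base_luminance * exp(stats::rnorm(n, 0, noise_sd))
  ipsi <- base_luminance * ipsi_factor * exp(stats::rnorm(n, 0, noise_sd))
  frames <- data.frame(time_s = time_s, ipsi = ipsi, contra = contra)
  truth <- list(ipsi_factor = ipsi_factor)
  if (locomotion_fraction > 0) {
    # alternating exponential-length bouts, scaled to the target fraction
    state <- logical(n)
    i <- 1L
    loco <- stats::runif(1) < locomotion_fraction
    while (i <= n) {
      mean_len <- if (loco) bout_s * locomotion_fraction * 2
                  else bout_s * (1 - locomotion_fraction) * 2
      len <- max(1L, round(stats::rexp(1, 1 / (mean_len * fps))))
      state[i:min(n, i + len - 1L)] <- loco
      i <- i + len
      loco <- !loco
    }
    frames$speed_cm_s <- pmax(0, ifelse(state, speed_locomoting,
                                        speed_resting) +
                                   stats::rnorm(n, 0, speed_noise_sd))
    truth$locomoting <- state
  }
  structure(list(frames = frames, fps = fps, truth = truth),
            class = "luminance_session")
}

#' Simulate a pinprick trial
#'
#' Contact and accelerometer channels on a shared 1 kHz clock. The pin
#' contacts the skin `contact_delay_s` after the button press with the given
#' peak contact voltage; the paw-withdrawal movement appears on the
#' accelerometer `movement_delay_s` after contact with the given peak.
#'
#' @param button_time_s Button-press time (default 1 s into the record).
#' @param contact_peak_V Peak of the contact (conductance) channel.
#' @param movement_peak_V Peak accelerometer deflection (0 = no movement).
#' @param contact_delay_s Button-to-contact delay.
#' @param movement_delay_s Contact-to-movement delay.
#' @param duration_s Record length.
#' @param rate_hz Sampling rate (default 1000).
#' @param noise_sd Gaussian noise SD on both channels.
#' @param seed Integer seed.
#' @return A list of class `pinprick_trial` with `button_time_s`, `contact`
#'   and `accelerometer` data frames (`time_s`, `V`), and `truth`.
#' @export
simulate_pinprick_trial <- function(button_time_s = 1, contact_peak_V = 3,
                                    movement_peak_V = 1,
                                    contact_delay_s = 0.05,
                                    movement_delay_s = 0.03,
                                    duration_s = 3, rate_hz = 1000,
                                    noise_sd = 0, seed = 1L) {
  set.seed(stream_seed(seed, "pinprick"))
  t <- seq(0, duration_s, by = 1 / rate_hz)
  contact_on <- button_time_s + contact_delay_s
  contact <- ifelse(t >= contact_on & t < contact_on + 0.2,
                    contact_peak_V, 0)
  move_on <- contact_on + movement_delay_s
  accel <- ifelse(t >= move_on & t < move_on + 0.3,
                  movement_peak_V *
                    sin(pi * (t - move_on) / 0.3),   # half-sine burst
                  0)
  if (noise_sd > 0) {
    contact <- contact + stats::rnorm(length(t), 0, noise_sd)
    accel <- accel + stats::rnorm(length(t), 0, noise_sd)
  }
  structure(list(button_time_s = button_time_s,
                 contact = data.frame(time_s = t, V = contact),
                 accelerometer = data.frame(time_s = t, V = accel),
                 truth = list(contact_on_s = contact_on,
                              movement_on_s = move_on,
                              contact_peak_V = contact_peak_V)),
            class = "pinprick_trial")
}

#' Simulate an optically evoked EPSC amplitude series
#'
#' Sweeps every `sweep_interval_s` across a pre-drug baseline, a drug
#' application, and a wash-out. From `drug_on_s` the true amplitude is
#' multiplied by `suppression` (reached immediately; wash-out returns to
#' baseline if `washout = TRUE`). Multiplicative Gaussian sweep noise.
#'
#' @param baseline_s,drug_s,washout_s Segment lengths, seconds (defaults
#'   600/600/300 per the 10 min baseline + 10 min drug design).
#' @param sweep_interval_s Sweep spacing (default 30).
#' @param amplitude_pA True baseline oEPSC magnitude.
#' @param suppression Multiplicative drug effect on amplitude (1 = none).
#' @param noise_sd Relative SD of sweep-to-sweep noise.
#' @param washout Whether amplitudes recover after drug offset.
#' @param resistance_drift Total fractional drift of the monitored series
#'   resistance across the recording (planted stability-QC ground truth).
#' @param seed Integer seed.
#' @return A list of class `oepsc_series`: `sweeps` (`time_s`,
#'   `amplitude_pA`), `drug_on_s`, `drug_off_s`, `stability` (`time_s`,
#'   `value`), and `truth`.
#' @export
simulate_oepsc_series <- function(baseline_s = 600, drug_s = 600,
                                  washout_s = 300, sweep_interval_s = 30,
                                  amplitude_pA = 100, suppression = 0.6,
                                  noise_sd = 0.05, washout = TRUE,
                                  resistance_drift = 0, seed = 1L) {
  set.seed(stream_seed(seed, "oepsc"))
  t <- seq(0, baseline_s + drug_s + washout_s - 1e-9, by = sweep_interval_s)
  drug_on <- baseline_s
  drug_off <- baseline_s + drug_s
  scale <- ifelse(t >= drug_on & (t < drug_off | !washout), suppression, 1)
  amp <- amplitude_pA * scale * (1 + stats::rnorm(length(t), 0, noise_sd))
  stab_t <- seq(0, max(t), by = 60)
  stab <- 100 * (1 + resistance_drift * stab_t / max(stab_t))
  structure(list(
    sweeps = data.frame(time_s = t, amplitude_pA = amp),
    drug_on_s = drug_on, drug_off_s = drug_off,
    stability = data.frame(time_s = stab_t, value = stab),
    truth = list(suppression = suppression, amplitude_pA = amplitude_pA)),
    class = "oepsc_series")
}

#' Simulate a GloSensor cAMP plate
#'
#' Wells carry a baseline luminescence segment followed by an
#' isoproterenol-driven rise. Vector wells reach `iso_fold` times baseline;
#' receptor wells scale that response by a constitutive factor
#' (`constitutive` < 1 for Gi-like, > 1 for Gs-like) and, when an agonist
#' dose is given, by a Hill-type suppression with the planted `ic50_M`.
#'
#' @param receptors Character vector of receptor labels (`"vector"` is the
#'   empty-vector control).
#' @param constitutive Named numeric: per-receptor constitutive scale
#'   (vector control is 1).
#' @param agonist Agonist label for dosed wells.
#' @param doses Molar doses (0 = vehicle) applied to each non-vector
#'   receptor.
#' @param ic50_M Planted IC50 of the agonist suppression (molar).
#' @param max_suppression Fraction of the iso response removed at saturating
#'   agonist.
#' @param n_replicates Replicate wells per (receptor, dose).
#' @param iso_fold Fold luminescence rise of vector wells post-iso.
#' @param baseline_rlu Mean baseline luminescence.
#' @param noise_sd Relative noise SD on every sample.
#' @param seed Integer seed.
#' @return A tidy well table: `well_id`, `receptor`, `agonist`, `dose`,
#'   `replicate_index`, `time_s`, `RLU`. Baseline samples span 0-120 s;
#'   iso is added at 120 s and response samples span 5-20 min after it.
#' @export
simulate_camp_plate <- function(receptors = c("vector", "ADRA2A"),
                                constitutive = c(vector = 1, ADRA2A = 0.5),
                                agonist = "none", doses = 0, ic50_M = 1e-7,
                                max_suppression = 0.8, n_replicates = 3,
                                iso_fold = 10, baseline_rlu = 1000,
                                noise_sd = 0.03, seed = 1L) {
  set.seed(stream_seed(seed, "camp"))
  base_t <- seq(0, 120, by = 30)
  resp_t <- 120 + seq(300, 1200, by = 100)   # 5-20 min post-iso
  rows <- list()
  wid <- 0L
  for (rec in receptors) {
    cvec <- if (rec %in% names(constitutive)) constitutive[[rec]] else 1
    dvec <- if (rec == "vector") 0 else doses
    for (dose in dvec) {
      hill <- if (dose > 0 && rec != "vector")
        1 - max_suppression * dose / (dose + ic50_M) else 1
      for (rep in seq_len(n_replicates)) {
        wid <- wid + 1L
        gain <- exp(stats::rnorm(1, 0, 0.05))   # per-well detector gain
        resp_level <- baseline_rlu * iso_fold * cvec * hill
        rlu <- c(rep(baseline_rlu, length(base_t)),
                 rep(resp_level, length(resp_t))) * gain *
          exp(stats::rnorm(length(base_t) + length(resp_t), 0, noise_sd))
        rows[[wid]] <- data.frame(
          well_id = sprintf("W%03d", wid), receptor = rec,
          agonist = if (dose > 0) agonist else "none", dose = dose,
          replicate_index = rep, time_s = c(base_t, resp_t), RLU = rlu)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "iso_time_s") <- 120
  out
}

#' Subtype annotation table
#'
#' @param subtype_id Unique subtype identifiers.
#' @param class One of `"CGRP"`, `"LTMR"`, `"proprioceptor"`, `"other"` per
#'   subtype.
#' @param display_name Optional human-readable names.
#' @return A data frame usable by [restriction_screen()] and
#'   [simulate_expression_matrix()].
#' @export
subtype_annotation <- function(subtype_id, class,
                               display_name = subtype_id) {
  if (anyDuplicated(subtype_id))
    ns_stop("subtype ids must be unique", "invalid-argument")
  if (!all(class %in% c("CGRP", "LTMR", "proprioceptor", "other")))
    ns_stop("unknown subtype class", "invalid-argument")
  data.frame(subtype_id = as.character(subtype_id),
             class = as.character(class),
             display_name = as.character(display_name))
}

#' @rdname subtype_annotation
#' @export
default_subtypes <- function() {
  subtype_annotation(
    subtype_id = c("CGRP-a", "CGRP-b", "CGRP-c", "CGRP-d",
                   "Ab-LTMR", "Ad-LTMR", "C-LTMR", "Proprio",
                   "TrpM8", "MrgprD"),
    class = c(rep("CGRP", 4), rep("LTMR", 3), "proprioceptor",
              "other", "other"))
}
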