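#' Von Frey 50% withdrawal threshold
#'
#' The threshold is the lowest filament force eliciting 5 or more positive
#' responses out of the 10 stimuli delivered at that filament. If no
#' filament qualifies the series is above range.
#'
#' @param forces_g Strictly increasing filament forces in grams.
#' @param responses Positive-response counts per filament (0..n_stimuli).
#' @param n_stimuli Stimuli per filament (default 10).
#' @param min_responses Qualifying count (default 5, inclusive).
#' @return The threshold force in grams, or `Inf` (with attribute
#'   `above_range = TRUE`) when no filament qualifies.
#' @examples
#' von_frey_threshold(c(0.04, 0.16, 0.6), c(2, 5, 8))  # 0.16
#' @export
von_frey_threshold <- function(forces_g, responses, n_stimuli = 10,
                               min_responses = 5) {
  if (length(forces_g) == 0L)
    ns_stop("empty von Frey series", "invalid-argument")
  if (length(forces_g) != length(responses))
    ns_stop("forces and responses differ in length", "invalid-argument")
  if (any(diff(forces_g) <= 0))
    ns_stop("forces must be strictly increasing", "invalid-argument")
  if (any(responses < 0 | responses > n_stimuli))
    ns_stop("response counts must lie in [0, n_stimuli]",
            "invalid-argument")
  hit <- which(responses >= min_responses)
  if (length(hit) == 0L)
    return(structure(Inf, above_range = TRUE))
  forces_g[hit[1L]]
}

#' Dynamic-brush allodynia score
#'
#' The score of each trial is the maximal response grade within it
#' (grades 0-3: no response, lifting/withdrawal, lateral kicking, licking);
#' the session score is the mean of per-trial maxima. Animals scoring 1.5
#' or higher are classified allodynic (inclusive boundary).
#'
#' @param trials A list, one element per trial, each an integer vector of
#'   per-stimulus grades in 0..3.
#' @param cutoff Allodynia cutoff (default 1.5, inclusive).
#' @return A list: `score` (in `[0, 3]`), `allodynic`, `trial_maxima`.
#' @examples
#' brush_allodynia(list(c(0, 2), c(1), c(2, 1)))  # score 5/3, allodynic
#' @export
brush_allodynia <- function(trials, cutoff = 1.5) {
  if (length(trials) == 0L)
    ns_stop("at least one trial is required", "invalid-argument")
  grades <- unlist(trials)
  if (length(grades) == 0L || any(vapply(trials, length, 1L) == 0L))
    ns_stop("empty trial", "invalid-argument")
  if (any(grades != as.integer(grades)) || any(grades < 0 | grades > 3))
    ns_stop("grades must be integers in 0..3", "invalid-argument")
  maxima <- vapply(trials, max, numeric(1))
  score <- mean(maxima)
  list(score = score, allodynic = score >= cutoff, trial_maxima = maxima)
}

#' Pinprick trial validity, onsets and movement magnitude
#'
#' A trial is valid only if the pin made strong skin contact after the
#' button press: contact channel strictly above `contact_threshold_V`
#' (1.5 V). Stimulus onset is the first supra-threshold contact sample;
#' movement onset is the first accelerometer sample at or above
#' `onset_threshold_V` (0.15 V) after stimulus onset; movement magnitude is
#' the trapezoidal area under the accelerometer across `auc_window_s`
#' (0.4 s) after stimulus onset, computed whether or not a movement onset
#' was found.
#'
#' @param trial A `pinprick_trial` (see [simulate_pinprick_trial()]) or any
#'   list with `button_time_s` and `contact` / `accelerometer` data frames
#'   (`time_s`, `V`) on a shared clock.
#' @param contact_threshold_V Contact validity threshold, strict `>`
#'   (default 1.5).
#' @param onset_threshold_V Movement-onset threshold, inclusive `>=`
#'   (default 0.15).
#' @param auc_window_s AUC window length (default 0.4).
#' @return A list: `valid`, `stimulus_onset_s` (`NA` if invalid),
#'   `movement_onset_s` (`NA` if never reached), `magnitude_Vs`.
#' @export
pinprick_metrics <- function(trial, contact_threshold_V = 1.5,
                             onset_threshold_V = 0.15, auc_window_s = 0.4) {
  if (is.null(trial$contact) || is.null(trial$accelerometer))
    ns_stop("trial must carry contact and accelerometer channels",
            "missing-channel")
  ct <- trial$contact
  ac <- trial$accelerometer
  post <- ct$time_s > trial$button_time_s
  hit <- post & ct$V > contact_threshold_V
  if (!any(hit)) {
    return(list(valid = FALSE, stimulus_onset_s = NA_real_,
                movement_onset_s = NA_real_, magnitude_Vs = NA_real_))
  }
  onset <- ct$time_s[hit][1L]
  if (max(ac$time_s) < onset + auc_window_s)
    ns_stop("accelerometer record does not cover the AUC window",
            "invalid-argument")
  after <- ac$time_s >= onset
  move_hit <- after & ac$V >= onset_threshold_V
  movement_onset <- if (any(move_hit)) ac$time_s[move_hit][1L] else NA_real_
  win <- ac$time_s >= onset & ac$time_s <= onset + auc_window_s
  magnitude <- trapz(ac$time_s[win], ac$V[win])
  list(valid = TRUE, stimulus_onset_s = onset,
       movement_onset_s = movement_onset, magnitude_Vs = magnitude)
}

#' Paw-luminance ratio of a session
#'
#' Per-frame log10 ratio of ipsilateral to contralateral hind-paw
#' luminance; frames where either paw reads zero are masked and excluded
#' from the mean. Two session summaries are emitted, because the field
#' reports both forms: the mean of the per-frame log-ratios
#' (`mean_log10_ratio`) and the ratio of the session-mean luminances
#' (`ratio_of_means`, the headline number).
#'
#' @param session A `luminance_session` (see
#'   [simulate_luminance_session()]) or a data frame with columns `ipsi`
#'   and `contra`.
#' @return A list: `log_ratio` (per-frame, masked frames `NA`),
#'   `mean_log10_ratio`, `ratio_of_means`, `n_masked`, `undefined`
#'   (`TRUE`, with both summaries `NA`, when every frame is masked).
#' @export
luminance_ratio <- function(session) {
  frames <- if (inherits(session, "luminance_session")) session$frames
            else session
  ipsi <- frames$ipsi
  contra <- frames$contra
  if (any(ipsi < 0) || any(contra < 0))
    ns_stop("luminance must be nonnegative", "invalid-argument")
  mask <- ipsi == 0 | contra == 0
  lr <- rep(NA_real_, length(ipsi))
  lr[!mask] <- log10(ipsi[!mask] / contra[!mask])
  undefined <- all(mask)
  list(log_ratio = lr,
       mean_log10_ratio = if (undefined) NA_real_ else mean(lr[!mask]),
       ratio_of_means = if (undefined) NA_real_
                        else mean(ipsi[!mask]) / mean(contra[!mask]),
       n_masked = sum(mask), undefined = undefined)
}

#' Split a luminance session by locomotion state
#'
#' Frames are locomoting when the smoothed centroid speed is at or above
#' the threshold (default 2 cm/s on a 0.5 s moving average, a conventional
#' open-field cutoff). Luminance ratios are recomputed per state.
#'
#' @param session A `luminance_session` whose frames carry `speed_cm_s`.
#' @param speed_threshold_cm_s Locomotion threshold (default 2).
#' @param smooth_s Moving-average window for the speed channel, seconds.
#' @return A list: `locomoting` (per-frame logical), `ratios` (a list with
#'   `locomoting` and `non_locomoting` entries of [luminance_ratio()]
#'   summaries; `NULL` for an empty state).
#' @export
locomotion_split <- function(session, speed_threshold_cm_s = 2,
                             smooth_s = 0.5) {
  stopifnot(inherits(session, "luminance_session"))
  frames <- session$frames
  if (is.null(frames$speed_cm_s))
    ns_stop("session has no speed channel", "missing-channel")
  k <- max(1L, round(smooth_s * session$fps))
  kernel <- rep(1 / k, k)
  sm <- stats::filter(frames$speed_cm_s, kernel, sides = 2)
  sm[is.na(sm)] <- frames$speed_cm_s[is.na(sm)]   # edges: raw values
  loco <- as.numeric(sm) >= speed_threshold_cm_s
  ratio_for <- function(state) {
    sub <- frames[loco == state, , drop = FALSE]
    if (nrow(sub) == 0L) NULL else luminance_ratio(sub)
  }
  list(locomoting = loco,
       ratios = list(locomoting = ratio_for(TRUE),
                     non_locomoting = ratio_for(FALSE)))
}

#' Fraction of time on the target side of a two-plate arena
#'
#' @param sides Per-frame side labels, each `"A"` or `"B"`.
#' @param target Target side label.
#' @return Fraction of frames spent on `target`.
#' @export
preference_fraction <- function(sides, target) {
  if (length(sides) == 0L)
    ns_stop("empty preference track", "invalid-argument")
  if (!all(sides %in% c("A", "B")))
    ns_stop("side labels must be 'A' or 'B'", "invalid-argument")
  if (!target %in% c("A", "B"))
    ns_stop("target must be 'A' or 'B'", "invalid-argument")
  mean(sides == target)
}

#' Count and first-event latency of annotated nocifensive events
#'
#' Counts the events falling inside the observation window and reports the
#' latency to the first one. With no event the latency is censored at the
#' window length and flagged.
#'
#' @param event_times_s Event time stamps in seconds (nonnegative).
#' @param window_s Observation window length (60 s cold plate, 30 s hot
#'   plate, 300 s guarding).
#' @return A list: `count`, `latency_s`, `censored`.
#' @examples
#' event_summary(c(5, 12, 40), 60)  # count 3, latency 5
#' @export
event_summary <- function(event_times_s, window_s) {
  check_number(window_s, "window_s", positive = TRUE)
  if (any(event_times_s < 0))
    ns_stop("event times must be nonnegative", "invalid-argument")
  inside <- event_times_s[event_times_s <= window_s]
  if (length(inside) == 0L)
    return(list(count = 0L, latency_s = window_s, censored = TRUE))
  list(count = length(inside), latency_s = min(inside), censored = FALSE)
}
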