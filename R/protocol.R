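#' Stimulus protocol for a KCl-pulse calcium-imaging session
#'
#' Describes the timing of repeated depolarising KCl pulses, which pulse is
#' delivered together with the drug, and the windows used for scoring. Trial
#' indices are 0-based throughout (the drug trial of the standard design is
#' trial 2, i.e. the third pulse).
#'
#' @param pulse_onsets_s Strictly increasing pulse onset times in seconds.
#' @param pulse_duration_s Duration of each KCl pulse in seconds.
#' @param drug_trial_index 0-based index of the pulse delivered with the
#'   drug. At least two baseline trials must precede it.
#' @param sampling_rate_hz Nominal acquisition rate in Hz (metadata; traces
#'   carry their own time stamps).
#' @param response_window_s Length, in seconds after each pulse onset, of the
#'   window over which the trial response is scored. Default is
#'   `pulse_duration_s + 15`, which captures the peak without reaching the
#'   next trial's baseline window.
#' @param f0_window_s Length of the pre-onset baseline window used for the
#'   per-trial F0 (seconds). Default 10.
#'
#' @return An object of class `stimulus_protocol`.
#' @seealso [generate_protocol()] for the standard design,
#'   [read_protocol()]/[write_protocol()] for the plain-text representation.
#' @export
stimulus_protocol <- function(pulse_onsets_s, pulse_duration_s,
                              drug_trial_index,
                              sampling_rate_hz = 2,
                              response_window_s = pulse_duration_s + 15,
                              f0_window_s = 10) {
  if (length(pulse_onsets_s) < 1L || anyNA(pulse_onsets_s))
    ns_stop("pulse onsets must be a non-missing numeric vector",
            "invalid-protocol")
  if (any(diff(pulse_onsets_s) <= 0))
    ns_stop("pulse onsets must be strictly increasing", "invalid-protocol")
  check_number(pulse_duration_s, "pulse_duration_s", positive = TRUE)
  check_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_number(response_window_s, "response_window_s", positive = TRUE)
  check_number(f0_window_s, "f0_window_s", positive = TRUE)
  drug_trial_index <- check_count(drug_trial_index, "drug_trial_index")
  if (drug_trial_index < 2L || drug_trial_index > length(pulse_onsets_s) - 1L)
    ns_stop("drug_trial_index must leave two baseline trials before it and lie within the pulse train",
            "invalid-protocol")
  if (length(pulse_onsets_s) > 1L &&
      any(diff(pulse_onsets_s) < response_window_s))
    ns_stop("response windows overlap the next pulse onset",
            "invalid-protocol")
  structure(
    list(
      pulse_onsets_s = as.numeric(pulse_onsets_s),
      pulse_duration_s = as.numeric(pulse_duration_s),
      drug_trial_index = drug_trial_index,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      response_window_s = as.numeric(response_window_s),
      f0_window_s = as.numeric(f0_window_s)
    ),
    class = "stimulus_protocol"
  )
}

#' Number of trials in a protocol
#' @param protocol A [stimulus_protocol()].
#' @return Integer trial count.
#' @export
n_trials <- function(protocol) length(protocol$pulse_onsets_s)

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %d pulses of %g s; drug on trial %d (0-based)\n",
    n_trials(x), x$pulse_duration_s, x$drug_trial_index))
  cat("  onsets (s):", paste(format(x$pulse_onsets_s), collapse = ", "), "\n")
  cat(sprintf("  response window %g s, F0 window %g s, %g Hz\n",
              x$response_window_s, x$f0_window_s, x$sampling_rate_hz))
  invisible(x)
}

#' Build the standard repeated-KCl protocol
#'
#' The standard session starts with a 15 s lead-in of observation solution,
#' then delivers `n_pulses` KCl pulses whose onsets are spaced
#' `inter_pulse_s` apart (a 15 s pulse followed by 285 s of wash-out gives
#' the default 300 s spacing). The drug (or vehicle) is perfused during the
#' 5 min preceding the drug trial and during the drug trial itself; the two
#' pulses before it establish baseline excitability and any pulses after it
#' probe wash-out.
#'
#' @param n_pulses Number of KCl pulses (>= 3).
#' @param pulse_duration_s Pulse duration in seconds (default 15).
#' @param inter_pulse_s Onset-to-onset spacing in seconds (default 300).
#' @param drug_trial_index 0-based drug trial index (default 2, the third
#'   pulse).
#' @param lead_in_s Observation-solution lead-in before the first pulse
#'   (default 15 s).
#' @inheritParams stimulus_protocol
#' @return A [stimulus_protocol()]. The drug application window is attached
#'   as attributes `drug_window_s` (start/end in seconds).
#' @examples
#' generate_protocol(5)  # onsets at 15, 315, 615, 915, 1215 s
#' @export
generate_protocol <- function(n_pulses, pulse_duration_s = 15,
                              inter_pulse_s = 300, drug_trial_index = 2,
                              lead_in_s = 15, sampling_rate_hz = 2) {
  n_pulses <- check_count(n_pulses, "n_pulses", min = 3L)
  check_number(pulse_duration_s, "pulse_duration_s", positive = TRUE)
  check_number(inter_pulse_s, "inter_pulse_s", positive = TRUE)
  check_number(lead_in_s, "lead_in_s", positive = TRUE)
  onsets <- lead_in_s + (seq_len(n_pulses) - 1) * inter_pulse_s
  p <- stimulus_protocol(onsets, pulse_duration_s, drug_trial_index,
                         sampling_rate_hz = sampling_rate_hz)
  # drug perfusion covers the 5 min before the drug pulse and the pulse itself
  drug_onset <- onsets[p$drug_trial_index + 1L]
  attr(p, "drug_window_s") <- c(start = max(0, drug_onset - 300),
                                end = drug_onset + pulse_duration_s)
  p
}

#' Read / write a stimulus protocol as plain-text key-value lines
#'
#' The on-disk form is one `key = value` pair per line; the onset vector is
#' comma-separated. Writing then reading reproduces the protocol exactly.
#'
#' @param path File path.
#' @return `read_protocol()` returns a [stimulus_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) ns_stop("malformed protocol line(s)", "invalid-protocol")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) ns_stop(sprintf("protocol file missing key '%s'", k),
                          "invalid-protocol")
    vals[i]
  }
  stimulus_protocol(
    pulse_onsets_s = as.numeric(strsplit(get1("pulse_onsets_s"), ",")[[1]]),
    pulse_duration_s = as.numeric(get1("pulse_duration_s")),
    drug_trial_index = as.integer(get1("drug_trial_index")),
    sampling_rate_hz = as.numeric(get1("sampling_rate_hz")),
    response_window_s = as.numeric(get1("response_window_s")),
    f0_window_s = as.numeric(get1("f0_window_s"))
  )
}

#' @rdname read_protocol
#' @param protocol A [stimulus_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  lines <- c(
    sprintf("pulse_onsets_s = %s",
            paste(format(protocol$pulse_onsets_s, digits = 15),
                  collapse = ",")),
    sprintf("pulse_duration_s = %s",
            format(protocol$pulse_duration_s, digits = 15)),
    sprintf("drug_trial_index = %d", protocol$drug_trial_index),
    sprintf("sampling_rate_hz = %s",
            format(protocol$sampling_rate_hz, digits = 15)),
    sprintf("response_window_s = %s",
            format(protocol$response_window_s, digits = 15)),
    sprintf("f0_window_s = %s", format(protocol$f0_window_s, digits = 15))
  )
  writeLines(lines, path)
  invisible(path)
}
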