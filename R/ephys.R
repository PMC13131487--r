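#' Recording-stability QC for patch-clamp series
#'
#' A recording passes when every monitored quantity (input resistance,
#' series resistance) stays within 20% of its first value throughout:
#' `max |v - v1| / v1 <= 0.20`, so a change of exactly 20% still passes
#' (the exclusion rule is a strict "changed by more than 20%"). The
#' alternative criterion, range relative to the series mean, is available.
#'
#' @param values Numeric stability series for one monitored quantity
#'   (>= 2 samples), or a data frame with a `value` column.
#' @param tol Fractional change tolerated (default 0.20).
#' @param reference `"first"` (default) or `"mean"`.
#' @return `TRUE` if the recording passes. Non-positive reference fails.
#' @export
qc_stability <- function(values, tol = 0.20, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  if (is.data.frame(values)) values <- values$value
  if (length(values) < 2L)
    ns_stop("need at least two stability samples", "invalid-argument")
  ref <- if (reference == "first") values[1L] else mean(values)
  if (!is.finite(ref) || ref <= 0) return(FALSE)
  max(abs(values - ref)) / ref <= tol
}

#' Normalize an oEPSC amplitude series to its pre-drug baseline
#'
#' Each sweep amplitude is divided by the mean amplitude over the 10 min
#' window immediately preceding drug onset (`[drug_on - baseline_s,
#' drug_on)`, half-open: a sweep exactly at drug onset belongs to the drug
#' period). Amplitudes are magnitudes (positive; inward currents are
#' recorded negative and stored as absolute values).
#'
#' @param series An `oepsc_series` (see [simulate_oepsc_series()]) or any
#'   list with `sweeps` (`time_s`, `amplitude_pA`) and `drug_on_s`.
#' @param baseline_s Baseline window length (default 600).
#' @return The input with an added `sweeps$normalized` column; the
#'   baseline mean is attached as attribute `baseline_mean_pA`.
#' @export
normalize_series <- function(series, baseline_s = 600) {
  sw <- series$sweeps
  on <- series$drug_on_s
  base <- sw$amplitude_pA[sw$time_s >= on - baseline_s & sw$time_s < on]
  if (length(base) == 0L)
    ns_stop("no sweeps in the baseline window", "empty-window")
  b <- mean(base)
  if (b == 0) ns_stop("zero baseline mean amplitude", "degenerate-baseline")
  series$sweeps$normalized <- sw$amplitude_pA / b
  attr(series, "baseline_mean_pA") <- b
  series
}

#' Drug effect on oEPSC amplitudes
#'
#' Compares the mean amplitude over the 2 min immediately before drug
#' application (`[drug_on - 120, drug_on)`) with the mean over the 2 min at
#' 8-10 min after application (`[drug_on + 480, drug_on + 600)`, just
#' before wash-out). Both windows are half-open on the right. The series is
#' baseline-normalized first, so `pre_mean` is ~1 and `effect_ratio =
#' post_mean / pre_mean` is gain-invariant.
#'
#' @inheritParams normalize_series
#' @param pre_window_s,post_window_s Offsets in seconds relative to drug
#'   onset, `c(start, end)` (defaults `c(-120, 0)` and `c(480, 600)`).
#' @param stability Optional stability series (vector or data frame) run
#'   through [qc_stability()]; when it fails, effect fields are returned
#'   but flagged unusable via `qc_pass = FALSE`.
#' @return A list of class `drug_effect`: `normalized` (sweep table),
#'   `pre_mean`, `post_mean`, `effect_ratio`, `qc_pass`.
#' @export
drug_effect <- function(series, pre_window_s = c(-120, 0),
                        post_window_s = c(480, 600), baseline_s = 600,
                        stability = NULL) {
  series <- normalize_series(series, baseline_s = baseline_s)
  sw <- series$sweeps
  on <- series$drug_on_s
  pre <- sw$normalized[sw$time_s >= on + pre_window_s[1] &
                         sw$time_s < on + pre_window_s[2]]
  post <- sw$normalized[sw$time_s >= on + post_window_s[1] &
                          sw$time_s < on + post_window_s[2]]
  if (length(pre) == 0L)
    ns_stop("no sweeps in the pre-drug comparison window", "empty-window")
  if (length(post) == 0L)
    ns_stop("no sweeps in the post-drug comparison window", "empty-window")
  qc <- if (is.null(stability)) {
    if (!is.null(series$stability)) qc_stability(series$stability) else TRUE
  } else qc_stability(stability)
  structure(list(normalized = sw, pre_mean = mean(pre),
                 post_mean = mean(post),
                 effect_ratio = mean(post) / mean(pre), qc_pass = qc),
            class = "drug_effect")
}

#' @export
print.drug_effect <- function(x, ...) {
  cat(sprintf("<drug_effect> pre %.3f, post %.3f, ratio %.3f (QC %s)\n",
              x$pre_mean, x$post_mean, x$effect_ratio,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}
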