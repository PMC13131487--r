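#' Per-trial fractional fluorescence change for one cell
#'
#' Converts a raw fluorescence trace into per-trial dF/F series. Each trial
#' uses its own baseline F0, the mean fluorescence over the
#' `f0_window_s` seconds immediately preceding the pulse onset, so slow
#' drift across the ~25 min session does not contaminate the response
#' measure. Within each trial,
#' `dF/F(t) = (F(t) - F0) / F0` over the response window
#' `[onset, onset + response_window_s)`.
#'
#' @param trace A data frame with columns `time_s` (strictly increasing) and
#'   `F` (raw fluorescence, finite) for a single cell.
#' @param protocol A [stimulus_protocol()].
#' @return A data frame with columns `trial_index` (0-based), `time_s`,
#'   `dff`; the per-trial baselines are attached as attribute `f0`.
#'   A non-positive trial baseline raises a condition of class
#'   `"degenerate-baseline"`; the population pipeline catches it and
#'   excludes the cell with a reason code.
#' @export
compute_dff <- function(trace, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  t <- trace$time_s
  f <- trace$F
  if (length(t) < 2L || any(diff(t) <= 0))
    ns_stop("trace times must be strictly increasing", "invalid-trace")
  if (anyNA(f) || any(!is.finite(f)))
    ns_stop("trace fluorescence must be finite", "invalid-trace")
  onsets <- protocol$pulse_onsets_s
  out <- vector("list", length(onsets))
  f0s <- numeric(length(onsets))
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    base_idx <- t >= on - protocol$f0_window_s & t < on
    resp_idx <- t >= on & t < on + protocol$response_window_s
    if (!any(base_idx))
      ns_stop(sprintf("empty F0 window for trial %d", k - 1L),
              "empty-window")
    if (!any(resp_idx))
      ns_stop(sprintf("empty response window for trial %d", k - 1L),
              "empty-window")
    f0 <- mean(f[base_idx])
    if (f0 <= 0)
      ns_stop(sprintf("non-positive baseline F0 in trial %d", k - 1L),
              "degenerate-baseline")
    f0s[k] <- f0
    out[[k]] <- data.frame(trial_index = k - 1L, time_s = t[resp_idx],
                           dff = (f[resp_idx] - f0) / f0)
  }
  res <- do.call(rbind, out)
  attr(res, "f0") <- f0s
  res
}

#' Per-trial excitability (max dF/F) for one cell
#'
#' Cell excitability for a trial is the maximum dF/F within that trial's
#' response window. The maximum is taken as-is (no clipping at zero).
#'
#' @param dff Output of [compute_dff()].
#' @param protocol The matching [stimulus_protocol()].
#' @return A data frame with columns `trial_index` (0-based) and `e`.
#' @export
trial_excitability <- function(dff, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  idx <- sort(unique(dff$trial_index))
  expected <- seq_len(n_trials(protocol)) - 1L
  if (!identical(as.integer(idx), expected))
    ns_stop("dF/F series must cover every trial of the protocol",
            "empty-window")
  e <- vapply(expected,
              function(k) max(dff$dff[dff$trial_index == k]),
              numeric(1))
  data.frame(trial_index = expected, e = e)
}

#' Baseline-consistency QC for the two pre-drug trials
#'
#' A cell enters the analysis only if its first two trials show comparable
#' excitability: relative difference strictly below 15%. The denominator is
#' the mean of the two trials by default (symmetric in trial order); the
#' first trial alone can be requested instead. Degenerate baselines
#' (denominator <= 0, or non-finite inputs) fail QC rather than raising.
#'
#' @param e0,e1 Excitability of trials 0 and 1.
#' @param tol Relative-difference cutoff (default 0.15; strict `<`).
#' @param denominator `"mean"` (default) or `"first"`.
#' @return `TRUE` if the cell passes QC.
#' @examples
#' qc_baseline(1.00, 1.10)  # TRUE: 0.10/1.05 < 0.15
#' qc_baseline(1.00, 1.20)  # FALSE: 0.20/1.10 > 0.15
#' @export
qc_baseline <- function(e0, e1, tol = 0.15,
                        denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  if (!is.finite(e0) || !is.finite(e1)) return(FALSE)
  denom <- if (denominator == "mean") (e0 + e1) / 2 else e0
  if (denom <= 0) return(FALSE)
  abs(e0 - e1) / denom < tol
}

#' Classify one cell's drug response
#'
#' Baseline excitability is the mean of trials 0 and 1. The relative
#' excitability is `r = e_drug / baseline`. A QC-passing cell is
#' `inhibited` if `r < 1 - tol`, `enhanced` if `r > 1 + tol`, and
#' `unchanged` otherwise — both thresholds strict, so a drug trial at
#' exactly 85% (or 115%) of baseline is `unchanged`. Cells failing baseline
#' QC, or with non-positive baseline, are `excluded` with a reason code.
#'
#' @param e0,e1 Baseline trial excitabilities.
#' @param e_drug Drug-trial excitability.
#' @param tol Effect threshold as a fraction of baseline (default 0.15).
#' @inheritParams qc_baseline
#' @return A one-row data frame: `qc_pass`, `label`, `baseline_e`,
#'   `relative_excitability`, `reason` (`NA` unless excluded).
#' @examples
#' classify_cell(1, 1, 0.80)$label  # "inhibited"
#' classify_cell(1, 1, 0.85)$label  # "unchanged" (boundary is strict)
#' @export
classify_cell <- function(e0, e1, e_drug, tol = 0.15,
                          denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  baseline <- (e0 + e1) / 2
  if (!qc_baseline(e0, e1, tol = tol, denominator = denominator)) {
    return(data.frame(qc_pass = FALSE, label = "excluded",
                      baseline_e = baseline, relative_excitability = NA_real_,
                      reason = "baseline-qc", stringsAsFactors = FALSE))
  }
  if (!is.finite(baseline) || baseline <= 0) {
    return(data.frame(qc_pass = FALSE, label = "excluded",
                      baseline_e = baseline, relative_excitability = NA_real_,
                      reason = "nonpositive-baseline",
                      stringsAsFactors = FALSE))
  }
  r <- e_drug / baseline
  label <- if (r < 1 - tol) "inhibited" else if (r > 1 + tol) "enhanced"
           else "unchanged"
  data.frame(qc_pass = TRUE, label = label, baseline_e = baseline,
             relative_excitability = r, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Soma-diameter stratum
#'
#' Small-diameter (< 25 um) somata correspond to unmyelinated C-fibre
#' neurons, medium (25–35 um, both bounds inclusive) and large (> 35 um) to
#' myelinated A-fibre neurons. Missing diameters map to `"unknown"`.
#'
#' @param diameter_um Numeric vector of soma diameters in micrometres
#'   (`NA` allowed; non-positive values are invalid measurements).
#' @return Character vector in `{"small","medium","large","unknown"}`.
#' @export
stratify_by_diameter <- function(diameter_um) {
  if (any(!is.na(diameter_um) & diameter_um <= 0))
    ns_stop("soma diameter must be positive", "invalid-measurement")
  out <- rep("unknown", length(diameter_um))
  out[!is.na(diameter_um) & diameter_um < 25] <- "small"
  out[!is.na(diameter_um) & diameter_um >= 25 & diameter_um <= 35] <- "medium"
  out[!is.na(diameter_um) & diameter_um > 35] <- "large"
  out
}

#' Wash-out recovery ratio
#'
#' Mean excitability over the post-drug trials divided by the baseline
#' (mean of trials 0 and 1). Report-only: no classification depends on it.
#'
#' @param e A per-trial excitability table from [trial_excitability()].
#' @param protocol The [stimulus_protocol()].
#' @return The recovery ratio, or `NA` if the protocol has no post-drug
#'   trials or the baseline is non-positive.
#' @export
washout_check <- function(e, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  post <- e$e[e$trial_index > protocol$drug_trial_index]
  if (length(post) == 0L) return(NA_real_)
  baseline <- mean(e$e[e$trial_index %in% c(0L, 1L)])
  if (!is.finite(baseline) || baseline <= 0) return(NA_real_)
  mean(post) / baseline
}

#' Score a population of calcium traces
#'
#' The full per-cell pipeline: dF/F per trial, per-trial max (excitability),
#' baseline QC, the +/-15% drug-effect rule, diameter stratification and the
#' wash-out recovery ratio. Cells whose dF/F cannot be computed (degenerate
#' baseline fluorescence) are excluded with a reason code rather than
#' dropped.
#'
#' @param traces Tidy trace table: columns `cell_id`, `time_s`, `F`, and
#'   optionally `diameter_um` (constant within a cell).
#' @param protocol A [stimulus_protocol()].
#' @param tol Effect / QC threshold (default 0.15).
#' @inheritParams qc_baseline
#' @return A data frame, one row per cell: `cell_id`, `qc_pass`, `label`,
#'   `baseline_e`, `e_drug`, `relative_excitability`, `stratum`,
#'   `washout_ratio`, `reason`. The long per-(cell, trial) excitability
#'   table is attached as attribute `excitability`.
#' @export
score_calcium <- function(traces, protocol, tol = 0.15,
                          denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("cell_id", "time_s", "F") %in% names(traces)))
  cells <- split(traces, factor(traces$cell_id,
                                levels = unique(traces$cell_id)))
  drug_k <- protocol$drug_trial_index
  rows <- vector("list", length(cells))
  e_tabs <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    tr <- cells[[i]]
    id <- tr$cell_id[1L]
    diam <- if ("diameter_um" %in% names(tr)) tr$diameter_um[1L] else NA_real_
    stratum <- stratify_by_diameter(diam)
    res <- tryCatch({
      dff <- compute_dff(tr, protocol)
      e <- trial_excitability(dff, protocol)
      frag <- classify_cell(e$e[e$trial_index == 0L],
                            e$e[e$trial_index == 1L],
                            e$e[e$trial_index == drug_k],
                            tol = tol, denominator = denominator)
      frag$e_drug <- e$e[e$trial_index == drug_k]
      frag$washout_ratio <- washout_check(e, protocol)
      e_tabs[[i]] <- cbind(cell_id = id, e)
      frag
    }, `degenerate-baseline` = function(cnd) {
      data.frame(qc_pass = FALSE, label = "excluded", baseline_e = NA_real_,
                 relative_excitability = NA_real_,
                 reason = "degenerate-baseline", e_drug = NA_real_,
                 washout_ratio = NA_real_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- data.frame(cell_id = id, qc_pass = res$qc_pass,
                            label = res$label, baseline_e = res$baseline_e,
                            e_drug = res$e_drug,
                            relative_excitability = res$relative_excitability,
                            stratum = stratum,
                            washout_ratio = res$washout_ratio,
                            reason = res$reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excitability") <- do.call(rbind, e_tabs)
  out
}

#' Population summary of drug-effect classifications
#'
#' Counts and, over QC-passing cells, fractions of inhibited / enhanced /
#' unchanged cells, overall and per diameter stratum. If every cell is
#' excluded the fractions are `NA` and `undefined` is flagged, not an error.
#'
#' @param classifications Per-cell classification table from
#'   [score_calcium()] (or any data frame with columns `label` and,
#'   optionally, `stratum` and `relative_excitability`).
#' @return A list of class `population_summary`: `overall` (one-row data
#'   frame), `by_stratum` (one row per known stratum), and
#'   `relative_excitability` (the QC-passing cells' values).
#' @export
summarize_population <- function(classifications) {
  if (nrow(classifications) == 0L)
    ns_stop("at least one classification is required", "invalid-argument")
  count_block <- function(df) {
    n_total <- nrow(df)
    n_exc <- sum(df$label == "excluded")
    n_inh <- sum(df$label == "inhibited")
    n_enh <- sum(df$label == "enhanced")
    n_unc <- sum(df$label == "unchanged")
    n_pass <- n_total - n_exc
    data.frame(
      n_total = n_total, n_excluded = n_exc, n_inhibited = n_inh,
      n_enhanced = n_enh, n_unchanged = n_unc,
      fraction_inhibited = if (n_pass > 0) n_inh / n_pass else NA_real_,
      fraction_enhanced = if (n_pass > 0) n_enh / n_pass else NA_real_,
      undefined = n_pass == 0
    )
  }
  overall <- count_block(classifications)
  by_stratum <- NULL
  if ("stratum" %in% names(classifications)) {
    known <- classifications[classifications$stratum != "unknown", ,
                             drop = FALSE]
    if (nrow(known) > 0L) {
      parts <- lapply(split(known, known$stratum), count_block)
      by_stratum <- do.call(rbind, parts)
      by_stratum <- cbind(stratum = rownames(by_stratum), by_stratum)
      rownames(by_stratum) <- NULL
    }
  }
  rel <- NULL
  if ("relative_excitability" %in% names(classifications))
    rel <- classifications$relative_excitability[
      classifications$label != "excluded"]
  structure(list(overall = overall, by_stratum = by_stratum,
                 relative_excitability = rel),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<population_summary> %d cells (%d excluded)\n",
              o$n_total, o$n_excluded))
  if (isTRUE(o$undefined)) {
    cat("  all cells excluded; fractions undefined\n")
  } else {
    cat(sprintf("  inhibited %d (%.1f%%), enhanced %d (%.1f%%), unchanged %d\n",
                o$n_inhibited, 100 * o$fraction_inhibited,
                o$n_enhanced, 100 * o$fraction_enhanced, o$n_unchanged))
  }
  if (!is.null(x$by_stratum)) {
    for (i in seq_len(nrow(x$by_stratum))) {
      s <- x$by_stratum[i, ]
      cat(sprintf("  %-6s n=%d inhibited %.1f%%\n", s$stratum, s$n_total,
                  100 * s$fraction_inhibited))
    }
  }
  invisible(x)
}
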