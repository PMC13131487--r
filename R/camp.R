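#' Normalize one GloSensor well
#'
#' Divides the summarised luminescence over the response window (the
#' 5-20 min post-isoproterenol span in the standard design) by the mean
#' baseline luminescence acquired before compound addition. The response
#' summary is the window maximum by default (robust to slow GloSensor
#' kinetics); the window mean is available.
#'
#' @param series Data frame with `time_s` (increasing) and `RLU`
#'   (nonnegative) for a single well.
#' @param baseline_window Length-2 numeric `[start, end)` in seconds,
#'   before compound addition.
#' @param response_window Length-2 numeric `[start, end)` in seconds.
#' @param summary `"max"` (default) or `"mean"`.
#' @return Dimensionless normalized response. A non-positive baseline
#'   returns `NA` with a `"degenerate-well"` warning rather than an error.
#' @export
normalize_well <- function(series, baseline_window, response_window,
                           summary = c("max", "mean")) {
  summary <- match.arg(summary)
  t <- series$time_s
  rlu <- series$RLU
  if (any(diff(t) <= 0)) ns_stop("well times must be increasing",
                                 "invalid-argument")
  if (any(rlu < 0)) ns_stop("RLU must be nonnegative", "invalid-argument")
  if (baseline_window[1] >= response_window[1])
    ns_stop("baseline window must precede the response window",
            "invalid-argument")
  base <- rlu[t >= baseline_window[1] & t < baseline_window[2]]
  resp <- rlu[t >= response_window[1] & t < response_window[2]]
  if (length(base) == 0L || length(resp) == 0L)
    ns_stop("empty baseline or response window", "empty-window")
  b <- mean(base)
  if (b <= 0) {
    warning(warningCondition("non-positive baseline luminescence; well flagged degenerate",
                             class = "degenerate-well"))
    return(NA_real_)
  }
  if (summary == "max") max(resp) / b else mean(resp) / b
}

# Normalize every well of a tidy plate table; internal.
normalize_plate <- function(plate, baseline_window, response_window,
                            summary = "max") {
  wells <- split(plate, plate$well_id)
  out <- lapply(wells, function(w) {
    data.frame(well_id = w$well_id[1L], receptor = w$receptor[1L],
               agonist = w$agonist[1L], dose = w$dose[1L],
               replicate_index = w$replicate_index[1L],
               response = normalize_well(w, baseline_window,
                                         response_window, summary))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dose-response table for one receptor/agonist pair
#'
#' Per-dose mean and SD of the normalized well responses, sorted ascending
#' by dose (vehicle, dose 0, first). The qualitative trend is the sign of
#' the Spearman rank correlation between dose and per-dose mean response:
#' `"decreasing"`, `"increasing"` or `"none"`. With
#' `fit_hill = TRUE` a four-parameter logistic curve is fitted by
#' least squares on log10 dose and the half-maximal dose is reported.
#'
#' @param wells Normalized well table (columns `dose`, `response`), e.g.
#'   one receptor/agonist subset of [normalize_plate] output, or a tidy
#'   plate table plus `baseline_window`/`response_window` to normalize
#'   first.
#' @param baseline_window,response_window Passed to [normalize_well()] when
#'   `wells` still carries raw `RLU`.
#' @param fit_hill Fit the 4PL refinement and report `ec50_M`.
#' @return A list of class `dose_response`: `table` (dose, n, mean, sd),
#'   `trend`, and optionally `ec50_M`. Fewer than 2 doses leaves `trend`
#'   `NA`; fewer than 2 replicates at any dose triggers a warning.
#' @export
dose_response_table <- function(wells, baseline_window = NULL,
                                response_window = NULL, fit_hill = FALSE) {
  if (!"response" %in% names(wells)) {
    if (is.null(baseline_window))
      ns_stop("raw plate input needs baseline and response windows",
              "invalid-argument")
    wells <- normalize_plate(wells, baseline_window, response_window)
  }
  doses <- sort(unique(wells$dose))
  tab <- do.call(rbind, lapply(doses, function(d) {
    r <- wells$response[wells$dose == d]
    data.frame(dose = d, n = length(r), mean = mean(r),
               sd = if (length(r) > 1L) stats::sd(r) else NA_real_)
  }))
  if (any(tab$n < 2L))
    warning("fewer than 2 replicates at some dose(s)")
  trend <- NA_character_
  if (nrow(tab) >= 2L) {
    rho <- suppressWarnings(
      stats::cor(tab$dose, tab$mean, method = "spearman"))
    trend <- if (is.na(rho) || rho == 0) "none"
             else if (rho < 0) "decreasing" else "increasing"
  }
  out <- list(table = tab, trend = trend)
  if (fit_hill && nrow(tab) >= 4L) out$ec50_M <- fit_hill_ec50(tab)
  class(out) <- "dose_response"
  out
}

# 4PL least-squares on log10 dose; vehicle (dose 0) anchors the top
# asymptote. Returns the half-maximal dose in molar.
fit_hill_ec50 <- function(tab) {
  dosed <- tab[tab$dose > 0, ]
  top0 <- if (any(tab$dose == 0)) tab$mean[tab$dose == 0][1L]
          else max(dosed$mean)
  ld <- log10(dosed$dose)
  obj <- function(p) {
    top <- p[1]; bottom <- p[2]; lec50 <- p[3]; hill <- exp(p[4])
    pred <- bottom + (top - bottom) / (1 + 10^((ld - lec50) * hill))
    sum((pred - dosed$mean)^2)
  }
  fit <- stats::optim(c(top0, min(dosed$mean), stats::median(ld), 0), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  10^fit$par[3]
}

#' Constitutive-activity index
#'
#' Ratio of the mean normalized response of receptor-expressing wells to
#' that of vector-expressing wells under the same stimulation. An index
#' below `1 - delta` is called Gi-like (the over-expressed receptor
#' suppresses cAMP accumulation without a ligand), above `1 + delta`
#' Gs-like, otherwise none. The margin replaces the original significance
#' tests with a fixed effect-size criterion; replicate dispersion is
#' reported alongside.
#'
#' @param receptor_wells,vector_wells Normalized well tables (column
#'   `response`) for the two groups.
#' @param delta Call margin (default 0.2).
#' @return A list of class `constitutive_call`: `index`, `call`
#'   (`"Gi-like"`, `"Gs-like"` or `"none"`), per-group `n`, means and SDs.
#' @export
constitutive_index <- function(receptor_wells, vector_wells, delta = 0.2) {
  check_number(delta, "delta", nonneg = TRUE)
  r <- receptor_wells$response
  v <- vector_wells$response
  if (length(r) == 0L || length(v) == 0L)
    ns_stop("both well groups must be non-empty", "invalid-argument")
  idx <- mean(r) / mean(v)
  call <- if (idx < 1 - delta) "Gi-like"
          else if (idx > 1 + delta) "Gs-like" else "none"
  structure(list(index = idx, call = call,
                 n_receptor = length(r), n_vector = length(v),
                 mean_receptor = mean(r), sd_receptor = stats::sd(r),
                 mean_vector = mean(v), sd_vector = stats::sd(v)),
            class = "constitutive_call")
}

#' @export
print.constitutive_call <- function(x, ...) {
  cat(sprintf("<constitutive_call> index %.3f -> %s (n=%d vs %d)\n",
              x$index, x$call, x$n_receptor, x$n_vector))
  invisible(x)
}
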