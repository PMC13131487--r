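#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors go through stop() with
# a class so callers (and tests) can distinguish failure modes.

ns_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nociscreen_error")))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    ns_stop(sprintf("`%s` must be a single non-missing number", name),
            "invalid-argument")
  if (finite && !is.finite(x))
    ns_stop(sprintf("`%s` must be finite", name), "invalid-argument")
  if (positive && x <= 0)
    ns_stop(sprintf("`%s` must be > 0", name), "invalid-argument")
  if (nonneg && x < 0)
    ns_stop(sprintf("`%s` must be >= 0", name), "invalid-argument")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name)
  if (x != as.integer(x) || x < min)
    ns_stop(sprintf("`%s` must be an integer >= %d", name, min),
            "invalid-argument")
  invisible(as.integer(x))
}

# Derived seed streams: one root seed, a documented per-stream offset, kept
# below 2^31 so it is always a valid R integer seed.
stream_seed <- function(seed, stream) {
  offsets <- c(
    population = 101L, diameters = 211L, expression = 307L,
    luminance = 401L, pinprick = 503L, oepsc = 601L, camp = 701L
  )
  if (!stream %in% names(offsets))
    ns_stop(sprintf("unknown seed stream '%s'", stream), "invalid-argument")
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

# Trapezoidal integral of y(t) over its sampling grid.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-n] + y[-1L]) / 2)
}
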