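#' Canonical double-gamma hemodynamic response function
#'
#' Unit-peak impulse response `h(t)` modelling the hemodynamic response: a
#' gamma density peaking at `peak_s` minus a second gamma density peaking at
#' `undershoot_s` scaled by `undershoot_ratio`. With the defaults the response
#' peaks at 6 s, undershoots around 16 s, and is zero at `t = 0`. The same
#' kernel is used for all simulated populations; downstream analysis assumes
#' only a hemodynamic lag, so the exact shape is a simulator convention.
#'
#' @param t time in seconds (`t >= 0`; values < 0 return 0).
#' @param peak_s positive peak time.
#' @param undershoot_s undershoot trough time.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric response values, maximum 1.
#' @export
hrf <- function(t, peak_s = 6, undershoot_s = 16, undershoot_ratio = 1 / 6) {
  a1 <- peak_s + 1        # gamma(shape a, rate 1) peaks at shape - 1
  a2 <- undershoot_s + 1
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt > 0
    tp <- tt[pos]
    g1 <- exp((a1 - 1) * log(tp) - tp - lgamma(a1))
    g2 <- exp((a2 - 1) * log(tp) - tp - lgamma(a2))
    out[pos] <- g1 - undershoot_ratio * g2
    out
  }
  peak_val <- max(raw(seq(0.5 * peak_s, 2 * peak_s, by = 0.01)))
  raw(t) / peak_val
}

# Discrete HRF kernel normalised to unit sum, so that a sustained boxcar
# convolved with it plateaus at the boxcar's amplitude.
hrf_kernel <- function(fs, span_s = 32, ...) {
  k <- hrf(seq(0, span_s, by = 1 / fs), ...)
  k / sum(k)
}
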