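# Butterworth IIR design and zero-phase filtering.
#
# No DSP package is assumed; the designs below are the textbook analog
# Butterworth prototype mapped through the bilinear transform with frequency
# pre-warping, normalised digitally (exact unity gain at DC for low-pass, at
# Nyquist for high-pass). Validated in tests against the analytic magnitude
# response |H(f)| = 1/sqrt(1 + (f/fc)^(2n)).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth filter
#'
#' @param order filter order.
#' @param fc corner frequency (Hz), `0 < fc < fs/2`.
#' @param fs sampling rate (Hz).
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b`, denominator `a` (a\[1\] = 1), a cascade of
#'   well-conditioned second-order sections `sos` (used for the actual
#'   filtering; the monolithic `b`/`a` form is numerically fragile for narrow
#'   high-pass designs), and the largest pole modulus `max_pole_r`.
#' @export
butter_design <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (!(fc > 0 && fc < fs / 2)) {
    stop_fcoi(sprintf("corner %g Hz incompatible with fs = %g Hz", fc, fs),
              "fcoi_config_error")
  }
  warp <- 2 * fs * tan(pi * fc / fs)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP poles
  if (type == "low") {
    p_s <- warp * p_proto
    z_ref <- 1 + 0i    # unity gain at DC
    zero <- -1
  } else {
    p_s <- warp / p_proto
    z_ref <- -1 + 0i   # unity gain at Nyquist
    zero <- 1
  }
  p_d <- (2 * fs + p_s) / (2 * fs - p_s)
  a <- Re(poly_from_roots(p_d))
  b <- Re(poly_from_roots(rep(zero + 0i, order)))
  ref_pow <- function(coefs) {
    # evaluate a descending-power polynomial at z_ref
    n <- length(coefs) - 1
    sum(coefs * z_ref^(n:0))
  }
  b <- b * Re(ref_pow(a) / ref_pow(b))

  # second-order sections: conjugate pole pairs (+ one real pole if odd),
  # each with matched zeros and unity gain at the reference frequency
  sos <- list()
  cplx <- p_d[Im(p_d) > 1e-9]
  for (p in cplx) {
    a_s <- Re(poly_from_roots(c(p, Conj(p))))
    b_s <- Re(poly_from_roots(c(zero + 0i, zero + 0i)))
    b_s <- b_s * Re(ref_pow(a_s) / ref_pow(b_s))
    sos[[length(sos) + 1]] <- list(b = b_s, a = a_s)
  }
  for (p in p_d[abs(Im(p_d)) <= 1e-9]) {
    a_s <- Re(poly_from_roots(p))
    b_s <- c(1, -zero)
    b_s <- b_s * Re(ref_pow(a_s) / ref_pow(b_s))
    sos[[length(sos) + 1]] <- list(b = b_s, a = a_s)
  }
  out <- list(b = b, a = a, sos = sos, max_pole_r = max(Mod(p_d)))
  attr(out, "sos_m") <- sos_matrix(out)
  out
}

# (b0 b1 b2 a1 a2) rows for the compiled cascade; cached on the design.
sos_matrix <- function(coefs) {
  m <- attr(coefs, "sos_m")
  if (!is.null(m)) return(m)
  t(vapply(coefs$sos, function(sec) {
    b <- c(sec$b, 0, 0)[1:3]
    a <- c(sec$a, 0, 0)[1:3]
    c(b, a[2:3])
  }, numeric(5)))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so that the effective magnitude
#' response is |H|^2 with exactly zero phase -- block means must not be
#' time-shifted. Edge transients are controlled by odd-reflection padding
#' sized to about three time constants of the slowest pole, and by removing
#' the series mean before filtering (re-added only for low-pass filters,
#' whose DC gain is unity).
#'
#' @param coefs list with `b`, `a` from [butter_design()].
#' @param x numeric vector or matrix (filtered column-wise).
#' @param dc_gain1 logical; `TRUE` for low-pass (the mean passes through).
#' @return filtered object of the same shape.
#' @export
filtfilt_bw <- function(coefs, x, dc_gain1 = TRUE) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- filtfilt_bw(coefs, x[, j], dc_gain1)
    return(out)
  }
  n <- length(x)
  # pad by ~3 time constants of the slowest pole, capped at n - 1
  r_max <- min(coefs$max_pole_r, 1 - 1e-12)
  tc <- -1 / log(r_max)
  pad <- min(n - 1L, max(30L, ceiling(3 * tc)))
  mu <- mean(x)
  xc <- x - mu
  ext <- c(2 * xc[1] - xc[(pad + 1):2],
           xc,
           2 * xc[n] - xc[(n - 1):(n - pad)])
  sos_m <- sos_matrix(coefs)
  y <- sos_filter_cpp(sos_m, ext)
  y <- rev(sos_filter_cpp(sos_m, rev(y)))
  y <- y[(pad + 1):(pad + n)]
  if (dc_gain1) y <- y + mu
  y
}

#' Analytic Butterworth magnitude response
#'
#' `|H(f)|` of an order-`n` analog Butterworth filter with corner `fc`; used
#' as the independent oracle for empirical filter gains.
#'
#' @param f frequency (Hz); @param fc corner (Hz); @param order filter order;
#' @param type `"low"` or `"high"`.
#' @return gain values in `[0, 1]`.
#' @export
butter_gain <- function(f, fc, order, type = c("low", "high")) {
  type <- match.arg(type)
  r <- if (type == "low") f / fc else fc / f
  1 / sqrt(1 + r^(2 * order))
}
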