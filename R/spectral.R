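#' Spectral density of a correlation profile
#'
#' The discrete Fourier transform of the W-windowed correlation values
#' (plain DFT, implicit circularity, no taper by default). Frequency bin
#' `k` (0-based) corresponds to genomic length scale `W / k` bp; because
#' the input is real, amplitudes are conjugate-symmetric and bin `W - k`
#' carries the same scale.
#'
#' @param x a `correlation_profile`, an `arpeggio_profile`, or a numeric
#'   vector of length W.
#' @param taper apply a Hann window before transforming (off by default;
#'   the stored correlation is transformed as-is).
#' @return A `spectral_density`: list with `sample_id`, `n_bins` and the
#'   complex `values`.
#' @export
spectral_density <- function(x, taper = FALSE) {
  if (inherits(x, "correlation_profile")) {
    v <- x$values; id <- x$sample_id
  } else if (inherits(x, "arpeggio_profile")) {
    v <- x$values; id <- x$sample_id
  } else if (is.numeric(x)) {
    v <- as.numeric(x); id <- "sample"
  } else stop("unsupported input for spectral_density")
  if (taper) {
    n <- length(v)
    v <- v * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n))
  }
  structure(list(sample_id = id, n_bins = length(v), values = fft(v)),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("spectral_density '%s': %d bins, total magnitude %.6g\n",
              x$sample_id, x$n_bins, sum(Mod(x$values))))
  invisible(x)
}

#' Spectral magnitude at a genomic length scale
#'
#' Magnitude of the frequency bin whose period is closest to `scale_bp`
#' (bin `round(W / scale_bp)`, clamped to the non-redundant half).
#'
#' @param sd a [spectral_density()].
#' @param scale_bp length scale(s) in bp, each in `(2, W]`.
#' @return Numeric vector of magnitudes.
#' @export
magnitude_at_scale <- function(sd, scale_bp) {
  stopifnot(inherits(sd, "spectral_density"))
  W <- sd$n_bins
  k <- pmin(pmax(round(W / scale_bp), 1L), W %/% 2L)
  Mod(sd$values[k + 1L])
}

#' Low-pass filter a spectral density
#'
#' Hard cutoff: amplitudes at length scales shorter than `cutoff_scale`
#' bp are zeroed (both halves of each conjugate pair, so symmetry — and
#' hence realness after inversion — is preserved). The DC bin is kept.
#'
#' @param sd a [spectral_density()].
#' @param cutoff_scale minimum retained scale in bp (default 40 bp, below
#'   which spikey read-count noise dominates); must be >= 2.
#' @return A filtered `spectral_density`.
#' @export
low_pass <- function(sd, cutoff_scale = 40) {
  stopifnot(inherits(sd, "spectral_density"))
  if (cutoff_scale < 2) stop("cutoff_scale must be >= 2")
  W <- sd$n_bins
  k <- seq_len(W) - 1L
  keff <- pmin(k, W - k)          # folded frequency index; 0 = DC
  period <- ifelse(keff == 0, Inf, W / keff)
  sd$values[period < cutoff_scale] <- 0 + 0i
  sd
}

.spectral_ratio <- function(num, den, epsilon_rel) {
  m <- max(Mod(den))
  if (m == 0) stop("no control signal: denominator spectrum is all zero")
  thresh <- epsilon_rel * m
  small <- Mod(den) < thresh
  if (any(small)) {
    d <- den[small]
    zero <- Mod(d) == 0
    d[!zero] <- d[!zero] * (1 + thresh / Mod(d[!zero]))
    d[zero] <- thresh + 0i
    den[small] <- d
  }
  ratio <- num / den
  if (any(!is.finite(ratio))) {
    bad <- which(!is.finite(ratio))[1]
    stop("non-finite spectral ratio at frequency bin ", bad - 1L,
         " despite regularization")
  }
  list(ratio = ratio, n_guarded = sum(small))
}

.real_ifft <- function(z, context = "inverse transform") {
  v <- fft(z, inverse = TRUE) / length(z)
  scale <- max(Mod(v))
  if (scale > 0 && max(abs(Im(v))) / scale > 1e-6)
    warning("non-negligible imaginary residue discarded in ", context)
  Re(v)
}

#' Harmonic deconvolution of ChIP vs control autocorrelation
#'
#' The measured ChIP signal is modelled as the convolution of the true IP
#' signal with technical variability (accessibility, library biases),
#' whose autocorrelation is estimated by a matched control. By the
#' convolution theorem, the autocorrelation of the true IP signal is
#' recovered as the inverse transform of the frequency-wise ratio of the
#' two autocorrelation spectra. The result is the Arpeggio profile: a
#' genome-aggregated interaction signature in which an isolated factor
#' appears as a sharply decaying pulse, a phased nucleosome array as a
#' damped oscillation, and a control deconvolved against itself as a pure
#' impulse (no true IP signal).
#'
#' Near-zero denominator bins are Tikhonov-style guarded: a denominator
#' `d` with `|d| < epsilon_rel * max|F(control)|` is replaced by
#' `d * (1 + epsilon_rel * max|F(control)| / |d|)`, which leaves
#' well-conditioned spectra untouched and bounds the ratio otherwise.
#'
#' @param chip `correlation_profile` (kind `auto`) of the ChIP sample.
#' @param control `correlation_profile` (kind `auto`) of the matched
#'   control, same `max_lag`.
#' @param epsilon_rel relative regularization threshold (default 1e-6).
#' @return An `arpeggio_profile`: real `values` over lags `[0, W)`, the
#'   `epsilon_rel` used, the number of guarded bins, and a `flatness`
#'   score `1 - max_{tau>0}|v| / v[0]` (1 for a perfect impulse).
#' @export
deconvolve <- function(chip, control, epsilon_rel = 1e-6) {
  stopifnot(inherits(chip, "correlation_profile"),
            inherits(control, "correlation_profile"))
  if (chip$max_lag != control$max_lag)
    stop("profiles have different max_lag")
  if (all(control$values == 0)) stop("no control signal")
  r <- .spectral_ratio(fft(chip$values), fft(control$values), epsilon_rel)
  values <- .real_ifft(r$ratio, "deconvolution")
  flat <- if (values[1] > 0)
    1 - max(abs(values[-1])) / values[1] else NA_real_
  structure(list(sample_id = chip$sample_id, control_id = control$sample_id,
                 values = values, epsilon_rel = epsilon_rel,
                 flatness = flat, n_guarded = r$n_guarded),
            class = "arpeggio_profile")
}

#' @export
print.arpeggio_profile <- function(x, ...) {
  cat(sprintf(
    "arpeggio_profile '%s' (control '%s'): W = %d, flatness %.4f, %d guarded bin(s)\n",
    x$sample_id, x$control_id, length(x$values), x$flatness, x$n_guarded))
  invisible(x)
}

#' Nucleosome-spacing ratio alpha
#'
#' Ratio of the spectral magnitude at the nucleosome repeat period
#' (default 190 bp) to the median magnitude at off-period scales within a
#' comparison band. Values clearly above one indicate strict periodic
#' spacing of events; values near one indicate isolated or flexibly
#' spaced events. Scale-invariant (any multiplicative constant cancels).
#'
#' @param sd a [spectral_density()] (typically of an Arpeggio profile).
#' @param period repeat length of interest in bp (default 190).
#' @param exclusion_halfwidth half-width in bp of the band around
#'   `period` excluded from the off-period median (default 30).
#' @param band comparison band `(lo, hi)` in bp (default 100-300).
#' @return A positive number; errors on a flat/empty spectrum in band.
#' @export
alpha_ratio <- function(sd, period = 190, exclusion_halfwidth = 30,
                        band = c(100, 300)) {
  stopifnot(inherits(sd, "spectral_density"))
  if (period < band[1] || period > band[2])
    stop("period must lie within the comparison band")
  scales <- seq(band[1], band[2])
  off <- scales[abs(scales - period) > exclusion_halfwidth]
  denom <- stats::median(magnitude_at_scale(sd, off))
  if (denom == 0) stop("flat/empty spectrum in band")
  magnitude_at_scale(sd, period) / denom
}

#' Moving-average smoothing (display only)
#'
#' Centered running mean used to aid visualization of noisy profiles;
#' never applied to stored values.
#'
#' @param values numeric vector.
#' @param window odd window width in bp (default 11).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, window = 11L) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1) return(values)
  kern <- rep(1 / window, window)
  sm <- as.numeric(stats::filter(values, kern, sides = 2, circular = FALSE))
  # edges: shrink the window instead of dropping to NA
  half <- window %/% 2
  n <- length(values)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(values[lo:hi])
  }
  sm
}

#' Local maxima of a profile beyond a minimum lag
#'
#' Lags (bp) at which the lightly smoothed profile is a strict local
#' maximum, restricted to lags greater than `min_lag`. The first element
#' is the location of the leading positive-lag peak — e.g. the nucleosome
#' repeat length for a phased-array Arpeggio profile.
#'
#' @param profile an `arpeggio_profile`, `correlation_profile`, or
#'   numeric vector over lags `[0, W)`.
#' @param min_lag ignore lags `<= min_lag` bp (default 40, below which
#'   read-scale noise dominates).
#' @param smooth_window odd moving-average width applied before peak
#'   picking (default 11 bp); the stored profile is untouched.
#' @param min_height minimum peak height as a fraction of the smoothed
#'   profile's dynamic range beyond `min_lag` (default 0.5), so that
#'   noise wiggles in the troughs of a damped oscillation are not
#'   reported as maxima.
#' @return Integer vector of peak lags in increasing order.
#' @export
profile_local_maxima <- function(profile, min_lag = 40, smooth_window = 11L,
                                 min_height = 0.5) {
  v <- if (inherits(profile, "arpeggio_profile") ||
           inherits(profile, "correlation_profile")) profile$values
       else as.numeric(profile)
  s <- smooth_profile(v, smooth_window)
  n <- length(s)
  idx <- 2:(n - 1)
  peak <- s[idx] > s[idx - 1] & s[idx] >= s[idx + 1]
  lags <- idx[peak] - 1L   # values index 1 = lag 0
  lags <- lags[lags > min_lag]
  if (length(lags) && min_height > 0) {
    tail_vals <- s[(min_lag + 2):n]
    lo <- min(tail_vals)
    rng <- max(tail_vals) - lo
    if (rng > 0)
      lags <- lags[s[lags + 1] >= lo + min_height * rng]
  }
  lags
}
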