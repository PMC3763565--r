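#' Recover the fragment-length distribution from single-end reads
#'
#' A fragment of length f that yields a minus-strand read places that
#' read's 5' end f - 1 bp downstream of where a plus-strand read from the
#' same fragment would start (0-based convention, minus-strand 5' end at
#' the rightmost aligned base). When fragment start positions are
#' independent of fragment length, the minus-strand read-start intensity
#' is the plus-strand one convolved with the fragment-length
#' distribution, so the opposing-strand cross-correlation equals the
#' same-strand autocorrelation convolved with it, and a frequency-domain
#' ratio recovers the full distribution — not just its mean — from
#' single-end reads alone. (When every fragment is constrained to cover
#' a point source, start and length are coupled and the ratio reduces to
#' a pure phase factor: the estimate collapses toward an impulse at the
#' mean length. The mode remains accurate; the shape does not. See the
#' methods vignette.)
#'
#' The stored autocorrelation is one-sided; since the DSP autocorrelation
#' is an even function of lag, it is mirrored to its circular even
#' extension before transforming. Deconvolution lag tau corresponds to
#' fragment length tau + 1; the returned pmf is indexed by length on
#' that shifted axis. Negative deconvolution values (noise) are clipped
#' to zero and the result renormalized to sum one (the normalization
#' constant c).
#'
#' With `denoise = TRUE` (default) the raw frequency-wise ratio is
#' additionally cleaned with standard spectral-estimation steps that
#' leave a noise-free ratio essentially untouched: each bin is shrunk by
#' a Wiener-style factor m^2/(1 + m^2), where m is the cross-correlation
#' spectrum's magnitude in units of its own noise floor (estimated
#' robustly from the lower decile of the high-frequency tail), a light
#' moving average is applied to the ratio after demodulating by the
#' dominant delay (the cross-correlation peak lag) so that smoothing
#' does not damp components away from the peak, and frequencies beyond
#' the last reliable band are cosine-tapered to zero.
#'
#' @param cross `correlation_profile` of kind `"cross"`.
#' @param auto `correlation_profile` of kind `"auto"` for the same
#'   sample, same `max_lag` (by default the plus+minus sum; pass a
#'   plus-only profile for the single-strand variant).
#' @param epsilon_rel regularization threshold for near-zero denominator
#'   bins, as in [deconvolve()].
#' @param denoise apply the band-limited denoised estimator (default
#'   `TRUE`); `FALSE` gives the plain guarded ratio.
#' @param max_length truncate the pmf support to lengths `<=
#'   max_length` bp before renormalizing (default 1024; sheared ChIP
#'   libraries are size-selected well below that). `NA` keeps the full
#'   window.
#' @param noise_mult multiple of the numerator's high-frequency noise
#'   floor below which a bin counts as unreliable (default 2.5).
#' @param smooth_bins odd moving-average width (frequency bins) applied
#'   to the demodulated ratio (default 5).
#' @param clip_threshold pmf bins below this fraction of the peak are
#'   zeroed before renormalizing (default 0.02), suppressing the
#'   broadband ripple left by noise-dominated frequencies; 0 disables.
#' @param read_length known read length in bp, or `NA`; used only to
#'   annotate the pmf bin at the read length, where an artifactual spike
#'   has been observed in opposing-strand cross-correlation of real
#'   data.
#' @return A `fragment_length_distribution`: `pmf` data.frame
#'   (`length_bp`, `probability`), `mode`, `mean`, the fraction of mass
#'   clipped, the reliable band limit `kmax` (NA when `denoise =
#'   FALSE`), and the read-length annotation (`read_length_bp`,
#'   `read_length_spike`: pmf at the read length over the median pmf
#'   within 25 bp of it).
#' @export
fragment_length_distribution <- function(cross, auto, epsilon_rel = 1e-6,
                                         denoise = TRUE, max_length = 1024,
                                         noise_mult = 2.5, smooth_bins = 5L,
                                         clip_threshold = 0.02,
                                         read_length = NA_real_) {
  stopifnot(inherits(cross, "correlation_profile"),
            inherits(auto, "correlation_profile"))
  if (cross$kind != "cross" || auto$kind != "auto")
    stop("need a cross profile and an auto profile")
  if (cross$max_lag != auto$max_lag) stop("profiles have different max_lag")
  if (all(auto$values == 0)) stop("no control signal: autocorrelation is all zero")
  W <- auto$max_lag
  # circular even extension of the one-sided autocorrelation
  av <- auto$values
  av[2:W] <- av[2:W] + rev(av[2:W])
  num <- fft(cross$values)
  r <- .spectral_ratio(num, fft(av), epsilon_rel)
  if (denoise) {
    ratio <- .denoise_ratio(r$ratio, num, cross$values, noise_mult,
                            smooth_bins)
    raw <- .real_ifft(ratio$values, "fragment-length deconvolution")
    kmax <- ratio$kmax
  } else {
    raw <- .real_ifft(r$ratio, "fragment-length deconvolution")
    kmax <- NA_integer_
  }
  clipped_mass <- sum(abs(raw[raw < 0]))
  raw[raw < 0] <- 0
  if (!is.na(max_length) && max_length < W)
    raw[seq_along(raw) > max_length] <- 0
  if (clip_threshold > 0 && any(raw > 0))
    raw[raw < clip_threshold * max(raw)] <- 0
  total <- sum(raw)
  if (total == 0) stop("no strand signal: deconvolved pmf is all zero")
  p <- raw / total
  len <- seq_along(p)  # lag tau -> fragment length tau + 1
  mode_bp <- len[which.max(p)]
  mean_bp <- sum(p * len)
  spike <- NA_real_
  if (!is.na(read_length) && read_length >= 1 && read_length <= length(p)) {
    near <- len[abs(len - read_length) <= 25 & len != read_length]
    ref <- stats::median(p[near])
    spike <- if (ref > 0) p[read_length] / ref else NA_real_
  }
  structure(list(sample_id = cross$sample_id,
                 pmf = data.frame(length_bp = len, probability = p),
                 mode = mode_bp, mean = mean_bp,
                 clipped_mass_fraction = clipped_mass / (total + clipped_mass),
                 n_guarded = r$n_guarded, kmax = kmax,
                 read_length_bp = read_length,
                 read_length_spike = spike),
            class = "fragment_length_distribution")
}

# Band-limited Wiener-style cleaning of a deconvolution ratio.
# Reliability is judged on the numerator spectrum against its own
# high-frequency noise floor; each bin is shrunk by m^2/(1+m^2) with m
# the numerator magnitude in noise-floor units, smoothing is applied to
# the mu0-demodulated ratio, and the band edge is cosine-tapered.
.denoise_ratio <- function(ratio, num, cross_values, noise_mult,
                           smooth_bins) {
  W <- length(ratio)
  half <- W %/% 2
  kk <- seq_len(half)
  keff <- pmin(0:(W - 1), W - (0:(W - 1)))
  # noise floor from the lower decile of the high-frequency tail: robust
  # to signal that persists at high frequency (discrete length mixtures);
  # 0.459 is the 10th percentile of a unit-scale Rayleigh magnitude
  floor_est <- stats::quantile(Mod(num)[keff > W / 4], 0.10,
                               names = FALSE) / 0.459
  rel <- Mod(num)[kk + 1] > noise_mult * floor_est
  if (!any(rel)) stop("no reliable frequency band in the cross-correlation")
  # band limit: last k whose trailing window is at least half reliable
  win <- 16L
  cs <- cumsum(rel)
  frac <- (cs - c(rep(0, win), utils::head(cs, -win))) / pmin(kk, win)
  kmax <- max(max(which(frac >= 0.5)), win)
  mu0 <- which.max(smooth_profile(cross_values, 21L)) - 1L
  w <- 2 * pi * kk / W
  demod <- ratio[kk + 1] * exp(1i * w * mu0)
  reF <- Re(demod)
  imF <- Im(demod)
  if (smooth_bins > 1) {
    reF <- smooth_profile(reF, smooth_bins)
    imF <- smooth_profile(imF, smooth_bins)
  }
  m <- Mod(num)[kk + 1] / (noise_mult * floor_est)
  shrink <- m^2 / (1 + m^2)
  ktaper <- max(8, round(kmax / 2))
  L <- ifelse(kk <= kmax, 1,
              ifelse(kk >= kmax + ktaper, 0,
                     0.5 * (1 + cos(pi * (kk - kmax) / ktaper))))
  sm <- complex(real = reF, imaginary = imF) * shrink * L *
    exp(-1i * w * mu0)
  full <- complex(length.out = W)
  full[1] <- mean(reF[1:4])  # DC from the adjacent low-frequency band
  full[kk + 1] <- sm
  mirror <- kk[kk < half]
  full[W + 1 - mirror] <- Conj(sm[mirror])
  if (W %% 2 == 0) full[half + 1] <- Re(sm[half])
  list(values = full, kmax = kmax, mu0 = mu0)
}

#' @export
print.fragment_length_distribution <- function(x, ...) {
  cat(sprintf(
    "fragment_length_distribution '%s': mode %d bp, mean %.1f bp (%.2f%% mass clipped)\n",
    x$sample_id, x$mode, x$mean, 100 * x$clipped_mass_fraction))
  invisible(x)
}

#' Compare a recovered fragment-length pmf to true fragment lengths
#'
#' Divergence between the single-end estimate and a paired-end-style
#' ground truth: the Kolmogorov-Smirnov distance between the pmf's CDF
#' and the empirical CDF of the given fragment lengths, plus the offset
#' of the modes.
#'
#' @param fld a [fragment_length_distribution()].
#' @param fragments integer vector of true fragment lengths in bp.
#' @return List with `ks_distance`, `mode_offset_bp`, `true_mode_bp`.
#' @export
compare_to_paired_end <- function(fld, fragments) {
  stopifnot(inherits(fld, "fragment_length_distribution"))
  if (!length(fragments)) stop("fragments must be non-empty")
  fragments <- as.numeric(fragments)
  grid <- fld$pmf$length_bp
  cdf_est <- cumsum(fld$pmf$probability)
  cdf_true <- ecdf(fragments)(grid)
  ks <- max(abs(cdf_est - cdf_true))
  tabs <- table(fragments)
  true_mode <- as.numeric(names(tabs))[which.max(tabs)]
  list(ks_distance = ks,
       mode_offset_bp = fld$mode - true_mode,
       true_mode_bp = true_mode)
}
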