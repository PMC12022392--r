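# Spectral descriptors: Savitzky-Golay smoothing, single-peak analysis,
# signal power and Teager-Kaiser energy statistics, with correlation-based
# feature selection.

#' The 12 spectral feature names, in canonical order
#' @export
drs_feature_names <- c(
  "peak_amplitude", "peak_location", "width_half_height", "prominence",
  "width_half_prominence", "signal_power", "kte_skewness", "kte_variance",
  "kte_kurtosis", "kte_mean", "kte_rms", "kte_sd")

#' Column indices for the named feature subsets
#'
#' `"all"` is the full 12-feature set, `"peaks"` the five peak-analysis
#' features, `"power_kte"` the signal power plus six energy statistics.
#' The `"cfs"` subset is data-dependent; see [cfs_select()].
#'
#' @param set Subset name.
#' @return Integer indices into [drs_feature_names].
#' @export
feature_subset <- function(set = c("all", "peaks", "power_kte")) {
  set <- match.arg(set)
  switch(set, all = 1:12, peaks = 1:5, power_kte = 6:12)
}

#' Reflectance spectrum container
#'
#' @param wavelength_nm Uniformly spaced wavelengths (nm), length >= 7.
#' @param reflectance Non-negative reflectance values, same length.
#' @return An object of class `drs_spectrum`.
#' @export
drs_spectrum <- function(wavelength_nm, reflectance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength_nm) != length(reflectance))
    stop("wavelength and reflectance must have the same length")
  if (length(wavelength_nm) < 7)
    stop("a spectrum needs at least 7 samples")
  d <- diff(wavelength_nm)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * d[1])
    stop("wavelengths must be uniformly spaced and increasing")
  if (any(reflectance < 0))
    stop("reflectance must be non-negative")
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance),
            class = "drs_spectrum")
}

as_drs_spectrum <- function(x) {
  if (inherits(x, "drs_spectrum")) return(x)
  if (is.data.frame(x)) {
    wl <- x[[grep("wavelength", names(x))[1]]]
    rf <- if ("reflectance" %in% names(x)) x$reflectance
          else if ("total_reflectance" %in% names(x)) x$total_reflectance
          else x[[2]]
    return(drs_spectrum(wl, rf))
  }
  if (inherits(x, "spectrum_result"))
    return(drs_spectrum(x$wavelengths, x$total_reflectance))
  stop("cannot interpret input as a spectrum")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing; preserves the spectrum length and
#' reproduces polynomials up to the filter order exactly.
#'
#' @param spectrum A [drs_spectrum()] (or coercible data frame).
#' @param window Odd window length in samples (default 11).
#' @param polyorder Polynomial order, less than `window` (default 3).
#' @return The smoothed [drs_spectrum()].
#' @export
smooth_spectrum <- function(spectrum, window = 11, polyorder = 3) {
  spectrum <- as_drs_spectrum(spectrum)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > length(spectrum$reflectance))
    stop("window exceeds the spectrum length")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  sm <- signal::sgolayfilt(spectrum$reflectance, p = polyorder, n = window)
  drs_spectrum(spectrum$wavelength_nm, pmax(sm, 0))
}

# local maxima (strict neighbors resolve plateaus to their first sample);
# a tiny relative tolerance keeps numerically flat spectra degenerate
.local_maxima <- function(x) {
  n <- length(x)
  eps <- 1e-10 * max(abs(x), 1e-300)
  which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] + eps && x[i] >= x[i + 1] - eps, logical(1))) + 1L
}

# topographic prominence of peak i: height above the higher of the two
# minima separating it from higher ground (or the record edge)
.prominence <- function(x, i) {
  h <- x[i]
  left <- x[seq_len(i - 1)]
  higher_l <- which(left > h)
  lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1):i])
  right <- x[i:length(x)]
  higher_r <- which(right > h)
  rmin <- min(right[1:(if (length(higher_r)) min(higher_r) else length(right))])
  h - max(lmin, rmin)
}

# width of the peak at a reference level, by linear interpolation of the
# crossings nearest the peak (clipped at the record edges)
.width_at <- function(wl, x, i, level) {
  n <- length(x)
  xl <- wl[1]
  for (j in seq(i - 1, 1)) {
    if (x[j] <= level) {
      xl <- wl[j] + (wl[j + 1] - wl[j]) * (level - x[j]) / (x[j + 1] - x[j])
      break
    }
  }
  xr <- wl[n]
  for (j in seq(i + 1, n)) {
    if (x[j] <= level) {
      xr <- wl[j - 1] + (wl[j] - wl[j - 1]) * (x[j - 1] - level) / (x[j - 1] - x[j])
      break
    }
  }
  xr - xl
}

#' Peak-analysis features
#'
#' Locates the most prominent interior peak of a (smoothed) spectrum and
#' returns its amplitude, location (nm), full width at half height,
#' topographic prominence and full width at half prominence. A spectrum
#' without an interior local maximum yields all-zero features with a
#' warning (degenerate, not an error).
#'
#' @param spectrum A [drs_spectrum()].
#' @return Named numeric vector of length 5.
#' @export
peak_features <- function(spectrum) {
  spectrum <- as_drs_spectrum(spectrum)
  x <- spectrum$reflectance
  wl <- spectrum$wavelength_nm
  cand <- .local_maxima(x)
  out <- c(peak_amplitude = 0, peak_location = 0, width_half_height = 0,
           prominence = 0, width_half_prominence = 0)
  if (!length(cand)) {
    warning("no interior peak found; returning degenerate all-zero peak features")
    return(out)
  }
  prom <- vapply(cand, function(i) .prominence(x, i), numeric(1))
  i <- cand[which.max(prom)]
  p <- max(prom)
  out["peak_amplitude"] <- x[i]
  out["peak_location"] <- wl[i]
  out["width_half_height"] <- .width_at(wl, x, i, x[i] / 2)
  out["prominence"] <- p
  out["width_half_prominence"] <- .width_at(wl, x, i, x[i] - p / 2)
  out
}

#' Mean signal power
#'
#' Mean of the squared samples (the square of the RMS level).
#'
#' @param x Numeric vector (or a [drs_spectrum()], whose reflectance is used).
#' @return Scalar power.
#' @export
signal_power <- function(x) {
  if (inherits(x, "drs_spectrum")) x <- x$reflectance
  if (!length(x)) stop("empty signal")
  mean(x^2)
}

#' Teager-Kaiser energy profile
#'
#' The nonlinear energy operator `x(n)^2 - x(n-1) x(n+1)` evaluated at the
#' interior samples (length `N - 2`; endpoints are dropped, no padding).
#'
#' @param x Numeric vector of length >= 3 (or a [drs_spectrum()]).
#' @return Energy profile of length `length(x) - 2`.
#' @export
kte_profile <- function(x) {
  if (inherits(x, "drs_spectrum")) x <- x$reflectance
  n <- length(x)
  if (n < 3) stop("the energy operator needs at least 3 samples")
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' Statistics of an energy profile
#'
#' Skewness, variance, kurtosis, mean, RMS and standard deviation.
#' Variance and SD use the n-1 denominator; skewness and kurtosis are the
#' standardized third and fourth central moments (population moments,
#' kurtosis not excess: a Gaussian gives 3). A zero-variance profile has
#' skewness and kurtosis 0 by convention.
#'
#' @param profile Numeric vector of length >= 2.
#' @return Named numeric vector `kte_skewness`, `kte_variance`,
#'   `kte_kurtosis`, `kte_mean`, `kte_rms`, `kte_sd`.
#' @export
kte_stats <- function(profile) {
  if (length(profile) < 2) stop("profile must have at least 2 values")
  m <- mean(profile)
  d <- profile - m
  m2 <- mean(d^2)
  skew <- if (m2 > 0) mean(d^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(d^4) / m2^2 else 0
  c(kte_skewness = skew,
    kte_variance = stats::var(profile),
    kte_kurtosis = kurt,
    kte_mean = m,
    kte_rms = sqrt(mean(profile^2)),
    kte_sd = stats::sd(profile))
}

#' Assemble the 12-feature descriptor of a spectrum
#'
#' Smooths the spectrum, then concatenates the five peak-analysis features,
#' the signal power and the six Teager-Kaiser energy statistics, in the
#' fixed order of [drs_feature_names].
#'
#' @inheritParams smooth_spectrum
#' @return Named numeric vector of length 12.
#' @export
assemble_features <- function(spectrum, window = 11, polyorder = 3) {
  sm <- smooth_spectrum(spectrum, window, polyorder)
  out <- c(peak_features(sm),
           signal_power = signal_power(sm$reflectance),
           kte_stats(kte_profile(sm$reflectance)))
  stopifnot(identical(names(out), drs_feature_names))
  out
}

# absolute Pearson correlation, 0 for a constant column by convention
.abs_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  abs(stats::cor(a, b))
}

#' Correlation-based feature selection (greedy forward CFS)
#'
#' Selects `k` features maximizing the CFS merit
#' `m * r_cf / sqrt(m + m (m - 1) * r_ff)`, where `r_cf` is the mean
#' absolute feature-target Pearson correlation (averaged over all target
#' columns) and `r_ff` the mean absolute inter-feature correlation of the
#' subset of size `m`. Deterministic, with ties broken toward the lower
#' column index; constant columns have correlation 0 by convention.
#'
#' @param x Feature matrix (samples x features).
#' @param y Target matrix or vector.
#' @param k Number of features to select.
#' @return Integer vector of selected column indices, in selection order.
#' @export
cfs_select <- function(x, y, k = 6) {
  x <- as.matrix(x); y <- as.matrix(y)
  p <- ncol(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (k > p) stop("k cannot exceed the number of features")
  rcf <- vapply(seq_len(p), function(j)
    mean(vapply(seq_len(ncol(y)), function(t) .abs_cor(x[, j], y[, t]),
                numeric(1))), numeric(1))
  rff <- matrix(1, p, p)
  for (a in seq_len(p - 1)) for (b in (a + 1):p)
    rff[a, b] <- rff[b, a] <- .abs_cor(x[, a], x[, b])
  merit <- function(sel) {
    m <- length(sel)
    mean_ff <- if (m > 1) mean(rff[sel, sel][upper.tri(diag(m))]) else 0
    m * mean(rcf[sel]) / sqrt(m + m * (m - 1) * mean_ff)
  }
  sel <- integer(0)
  for (step in seq_len(k)) {
    rest <- setdiff(seq_len(p), sel)
    score <- vapply(rest, function(j) merit(c(sel, j)), numeric(1))
    sel <- c(sel, rest[which.max(score)])
  }
  sel
}
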