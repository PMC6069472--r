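#' Zero-phase Butterworth smoothing of a temporal signal
#'
#' Applies a first-order low-pass Butterworth filter with a 1 Hz cutoff
#' forward and backward, so the smoothed signal has no phase lag (peak-time
#' descriptors must not inherit filter delay). The effective magnitude
#' response is the squared first-order response. Filter coefficients come
#' from [signal::butter()]; the zero-phase pass is applied here with
#' steady-state initial conditions and odd edge extension, so a constant
#' signal is reproduced exactly (unit DC gain) and edge transients are
#' suppressed.
#'
#' @param x Numeric samples (length >= 4).
#' @param fs Sampling rate in Hz; must exceed 2 Hz so the 1 Hz cutoff lies
#'   below Nyquist.
#' @param cutoff Cutoff frequency in Hz (default 1).
#' @return Smoothed samples, same length as `x`.
#' @export
smooth_signal <- function(x, fs, cutoff = 1) {
  if (!is.numeric(fs) || fs <= 2 * cutoff) {
    stop("fs must exceed ", 2 * cutoff, " Hz so the ", cutoff,
         " Hz cutoff lies below Nyquist")
  }
  n <- length(x)
  if (n < 4L) stop("smoothing needs at least 4 samples")
  bt <- signal::butter(1, cutoff / (fs / 2), type = "low")
  b <- bt$b; a <- bt$a
  # odd extension at both ends (reflect values about the end sample)
  pad <- min(n - 1L, max(12L, ceiling(fs)))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(left, x, right)
  y <- iir_steady(b, a, xe)
  y <- rev(iir_steady(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# Direct-form IIR with steady-state (DC) initialization: starting the
# recursion as if the signal had been at its first value forever.
iir_steady <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  xprev <- x[1]
  yprev <- x[1] * sum(b) / sum(a)  # DC steady state
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + b[2] * xprev - a[2] * yprev
    xprev <- x[i]
    yprev <- y[i]
  }
  y
}

#' Numerical derivative of a sampled signal
#'
#' Central finite differences scaled by the sampling rate; one-sided
#' differences at the two ends. Exact for linear signals at interior
#' points. Applied once for the velocity signal and twice for the
#' acceleration signal.
#'
#' @param s Numeric samples (length >= 2).
#' @param fs Sampling rate in Hz.
#' @return Derivative samples, same length as `s`.
#' @export
differentiate <- function(s, fs) {
  n <- length(s)
  if (n < 2L) stop("differentiation needs at least 2 samples")
  v <- numeric(n)
  if (n > 2L) {
    v[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) * fs / 2
  }
  v[1] <- (s[2] - s[1]) * fs
  v[n] <- (s[n] - s[n - 1]) * fs
  v
}

#' Build a temporal signal with its smoothed version and derivatives
#'
#' Packages a raw frame-level signal `x` with its Butterworth-smoothed
#' version `s`, first derivative `v` (speed) and second derivative `a`
#' (acceleration), the three components from which the 16 temporal
#' descriptors are extracted.
#'
#' @param x Raw samples.
#' @param fs Sampling rate in Hz.
#' @param name Signal name.
#' @return An object of class `temporal_signal` with fields `name`, `x`,
#'   `s`, `v`, `a`, `fs`.
#' @export
temporal_signal <- function(x, fs, name = "signal") {
  s <- smooth_signal(x, fs)
  v <- differentiate(s, fs)
  a <- differentiate(v, fs)
  structure(list(name = name, x = x, s = s, v = v, a = a, fs = fs),
            class = "temporal_signal")
}

#' Names of the 16 temporal descriptors, in output order
#'
#' The descriptor blocks of every feature vector follow this fixed order,
#' grouped as: state (max, min, mean, median), variability (range, sd,
#' IQR, inter-decile range, MAD), peak (time of first maximum), duration
#' (seconds above the mean; seconds above the mean-minimum midpoint),
#' segment (number of maximal runs above each of those thresholds), and
#' area (AREA = area between the signal and its minimum; AREA divided by
#' the max-min range).
#'
#' @return Character vector of length 16.
#' @export
descriptor_names <- function() {
  c("max", "min", "mean", "median",
    "range", "sd", "iqr", "idr", "mad",
    "t_peak",
    "dur_mean", "dur_mid",
    "seg_mean", "seg_mid",
    "area", "area_quot")
}

#' The 16 temporal descriptors of one signal component
#'
#' Conventions (fixed so that feature vectors are reproducible): quantiles
#' use linear interpolation; the MAD is the raw median absolute deviation
#' (no consistency scaling); above-threshold tests are strict (`>`);
#' durations are counts of above-threshold samples divided by `fs`
#' (seconds); segments are maximal runs of above-threshold samples
#' (counts); the peak time is the 0-based index of the first maximum
#' divided by `fs`; AREA is the rectangle-rule integral of `x - min(x)`;
#' its quotient by `max - min` is defined as 0 for a flat signal.
#'
#' @param x Samples of one component (s, v or a).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 16 (see [descriptor_names()]).
#' @export
describe <- function(x, fs) {
  if (!length(x)) stop("cannot describe an empty signal")
  stopifnot(all(is.finite(x)), fs > 0)
  mx <- max(x); mn <- min(x); mu <- mean(x)
  qs <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  mid <- (mu + mn) / 2
  above <- function(thr) x > thr
  runs <- function(keep) {
    r <- rle(keep)
    sum(r$values)
  }
  am <- above(mu); amid <- above(mid)
  out <- c(
    max = mx, min = mn, mean = mu, median = stats::median(x),
    range = mx - mn,
    sd = stats::sd(x),
    iqr = qs[3] - qs[2],
    idr = qs[4] - qs[1],
    mad = stats::median(abs(x - stats::median(x))),
    t_peak = (which.max(x) - 1) / fs,
    dur_mean = sum(am) / fs,
    dur_mid = sum(amid) / fs,
    seg_mean = runs(am),
    seg_mid = runs(amid),
    area = sum(x - mn) / fs,
    area_quot = if (mx > mn) (sum(x - mn) / fs) / (mx - mn) else 0
  )
  if (length(x) == 1L) out["sd"] <- 0
  out
}

#' Assemble a feature stream from named temporal signals
#'
#' For each signal, the 16 descriptors are computed on each of its three
#' components (s, v, a) and concatenated in fixed
#' (signal, component, descriptor) order: 48 values per signal. The 11
#' deformation signals give the 528-dimensional DG_DisFace stream, the 8
#' pose signals the 384-dimensional DG_DisPose stream, and the 31 patch
#' gradient signals the 1488-dimensional DA_Gradient stream.
#'
#' @param signals Named list of [temporal_signal()] objects (or raw numeric
#'   vectors, which are wrapped with `fs`).
#' @param fs Sampling rate, required when raw vectors are supplied.
#' @return Named numeric vector of length `48 * length(signals)`, names
#'   `"<signal>.<component>.<descriptor>"`.
#' @export
build_stream <- function(signals, fs = NULL) {
  if (!length(signals)) stop("no signals supplied")
  fs <- fs %||% attr(signals, "fs")
  signals <- lapply(seq_along(signals), function(i) {
    sig <- signals[[i]]
    if (inherits(sig, "temporal_signal")) sig
    else {
      if (is.null(fs)) stop("fs must be supplied with raw signals")
      temporal_signal(sig, fs, name = names(signals)[i] %||% paste0("sig", i))
    }
  })
  lens <- vapply(signals, function(s) length(s$x), integer(1))
  fss <- vapply(signals, `[[`, numeric(1), "fs")
  if (length(unique(lens)) != 1L || length(unique(fss)) != 1L) {
    stop("all signals must share one length and sampling rate")
  }
  out <- unlist(lapply(signals, function(sig) {
    comp <- lapply(c(s = "s", v = "v", a = "a"), function(k) {
      d <- describe(sig[[k]], sig$fs)
      names(d) <- paste(sig$name, k, descriptor_names(), sep = ".")
      d
    })
    unlist(comp, use.names = TRUE)
  }), use.names = TRUE)
  names(out) <- sub("^[sva]\\.", "", names(out))
  out
}
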