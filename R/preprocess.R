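#' Downsample a dual recording
#'
#' Zero-phase anti-alias low-pass (forward-backward Butterworth, order 8,
#' cutoff at 80% of the target Nyquist) followed by integer decimation.
#' Zero-phase filtering preserves the relative timing between channels,
#' which phase-synchrony metrics depend on.
#'
#' @param rec a [dual_recording()].
#' @param target_rate new sampling rate (Hz); must divide the current rate.
#' @return Downsampled [dual_recording()].
#' @export
eeg_downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "dual_recording"))
  fs <- rec$sampling_rate
  if (target_rate > fs) {
    stop("target_rate (", target_rate, ") exceeds the sampling rate (", fs, ")")
  }
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-8) {
    stop("target_rate must divide the sampling rate (", fs, " / ",
         target_rate, " is not an integer)")
  }
  factor <- round(factor)
  if (factor == 1L) {
    return(rec)
  }
  aa <- signal::butter(8, 0.8 / factor, type = "low")
  keep <- seq(1, n_samples(rec), by = factor)
  blocks <- lapply(rec$signals, function(m) {
    out <- t(apply(m, 1, function(x) signal::filtfilt(aa, x)))
    out[, keep, drop = FALSE]
  })
  dual_recording(blocks[[1]], blocks[[2]], sampling_rate = target_rate,
                 channel_labels = rec$channel_labels, band = rec$band,
                 band_tag = rec$band_tag, bad_channels = rec$bad_channels)
}

#' Band-pass filter a dual recording (zero-phase)
#'
#' Forward-backward (two-pass) Butterworth band-pass. The two-pass scheme
#' cancels the filter's group delay, so no spurious phase lag is introduced
#' between channels or participants. When `(low, high)` matches a named
#' band in [eeg_bands] the recording is tagged with that band name.
#'
#' @param rec a [dual_recording()].
#' @param low,high band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered [dual_recording()] with `band` and `band_tag` set.
#' @export
eeg_bandpass <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "dual_recording"))
  fs <- rec$sampling_rate
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("need 0 < low < high < sampling_rate/2 (got ", low, ", ", high,
         " at ", fs, " Hz)")
  }
  bp <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  blocks <- lapply(rec$signals, function(m) {
    t(apply(m, 1, function(x) signal::filtfilt(bp, x)))
  })
  dual_recording(blocks[[1]], blocks[[2]], sampling_rate = fs,
                 channel_labels = rec$channel_labels,
                 band = c(low, high), band_tag = match_band_tag(low, high),
                 bad_channels = rec$bad_channels)
}

#' Interpolate bad channels from good ones
#'
#' Each channel listed in `rec$bad_channels` is replaced by a weighted
#' average of the `n_neighbors` nearest good channels of the same
#' participant, with weights proportional to the inverse great-circle
#' (angular) distance between electrode positions on the unit sphere.
#' Weights are normalized to sum to one, so a spatially constant field is
#' reproduced exactly; restricting to a local neighborhood keeps the
#' estimate from shrinking toward the whole-scalp mean on gradient fields.
#' The weighting function is isolated here so a spherical-spline scheme
#' can be swapped in.
#'
#' @param rec a [dual_recording()] with `bad_channels` set.
#' @param montage electrode positions as returned by [hb_montage()];
#'   must cover all channel labels.
#' @param power exponent on the inverse distance (default 1).
#' @param n_neighbors number of nearest good channels averaged (default 3;
#'   all good channels if fewer remain).
#' @return A [dual_recording()] with bad channels reconstructed and the
#'   bad-channel lists cleared; good channels are untouched.
#' @export
interpolate_bad_channels <- function(rec, montage = hb_montage(rec$channel_labels),
                                     power = 1, n_neighbors = 3) {
  stopifnot(inherits(rec, "dual_recording"))
  if (all(lengths(rec$bad_channels) == 0)) {
    return(rec)
  }
  pos <- as.matrix(montage[match(rec$channel_labels, montage$label),
                           c("x", "y", "z")])
  if (anyNA(pos)) stop("montage does not cover all channel labels")
  u <- pos / sqrt(rowSums(pos^2))           # unit-sphere directions
  gc_dist <- function(i, j) acos(pmin(1, pmax(-1, sum(u[i, ] * u[j, ]))))
  blocks <- rec$signals
  for (p in 1:2) {
    bad <- rec$bad_channels[[p]]
    if (length(bad) == 0) next
    bad_idx <- match(bad, rec$channel_labels)
    if (anyNA(bad_idx)) stop("unknown bad channel label for participant ", p)
    good_idx <- setdiff(seq_along(rec$channel_labels), bad_idx)
    if (length(good_idx) == 0) {
      stop("all channels are bad for participant ", p,
           "; recording is unrecoverable")
    }
    for (b in bad_idx) {
      d <- vapply(good_idx, function(g) gc_dist(b, g), numeric(1))
      nbr <- order(d)[seq_len(min(n_neighbors, length(good_idx)))]
      w <- 1 / pmax(d[nbr], 1e-6)^power
      w <- w / sum(w)
      blocks[[p]][b, ] <- drop(w %*% blocks[[p]][good_idx[nbr], ,
                                                 drop = FALSE])
    }
  }
  dual_recording(blocks[[1]], blocks[[2]], sampling_rate = rec$sampling_rate,
                 channel_labels = rec$channel_labels, band = rec$band,
                 band_tag = rec$band_tag)
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Doubles positive-frequency coefficients, zeroes negative ones (DC and
#' Nyquist kept), and inverse-transforms; `Arg()` of the result is the
#' instantaneous phase, `Mod()` the envelope.
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited dual recording
#'
#' Computes per-channel analytic signals and phases, and flags
#' `trim_samples` edge samples for exclusion from all synchrony sums
#' (filter and Hilbert edge effects concentrate there). Broadband input is
#' refused: an instantaneous phase is only meaningful for narrow-band
#' signals.
#'
#' @param rec a band-limited [dual_recording()] (i.e. after
#'   [eeg_bandpass()]).
#' @param trim_seconds seconds trimmed at each edge; default
#'   `max(1, 3 / low)` where `low` is the band's lower edge.
#' @return An object of class `phase_set`: lists `phases` and `analytic`
#'   (two channels x samples matrices each), `band_tag`, `band`,
#'   `sampling_rate`, `trim_samples`.
#' @export
hilbert_phase <- function(rec, trim_seconds = NULL) {
  stopifnot(inherits(rec, "dual_recording"))
  if (rec$band_tag %in% c("none", "broadband") || is.null(rec$band)) {
    stop("hilbert_phase needs band-limited input; run eeg_bandpass first")
  }
  amp_sd <- vapply(rec$signals, function(m) min(apply(m, 1, stats::sd)),
                   numeric(1))
  if (any(amp_sd == 0)) {
    stop("degenerate input: at least one channel is constant")
  }
  if (is.null(trim_seconds)) {
    trim_seconds <- max(1, 3 / rec$band[1])
  }
  trim <- round(trim_seconds * rec$sampling_rate)
  if (2 * trim >= n_samples(rec)) {
    stop("recording shorter than twice the edge trim (",
         trim_seconds, " s per edge)")
  }
  analytic <- lapply(rec$signals, function(m) {
    t(apply(m, 1, analytic_signal))
  })
  phases <- lapply(analytic, Arg)
  for (p in 1:2) {
    rownames(analytic[[p]]) <- rownames(phases[[p]]) <- rec$channel_labels
  }
  structure(
    list(phases = phases, analytic = analytic,
         band_tag = rec$band_tag, band = rec$band,
         sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels,
         trim_samples = trim),
    class = "phase_set"
  )
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf(
    "<phase_set> %d channels x %d samples per participant, band %s, trim %d samples/edge\n",
    nrow(x$phases[[1]]), ncol(x$phases[[1]]), x$band_tag, x$trim_samples
  ))
  invisible(x)
}

# Sample indices retained after edge trimming.
kept_samples <- function(ps) {
  n <- ncol(ps$phases[[1]])
  (ps$trim_samples + 1):(n - ps$trim_samples)
}
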