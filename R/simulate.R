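#' Simulation configuration for a coupled dual-EEG pair
#'
#' Parameters of the Kuramoto-style generator behind
#' [generate_coupled_pair()]. Each channel is a phase oscillator whose
#' natural frequency is drawn uniformly within `carrier_band`; sine
#' coupling pulls it toward the mean field of its own participant's
#' channels (strength `k_intra_*`, rad/s) and of the partner's channels
#' (strength `k_inter`, rad/s). Observed signals are `cos(phase)` plus
#' 1/f-shaped additive noise.
#'
#' @param n_channels channels per participant (default 29).
#' @param sampling_rate Hz (default 500).
#' @param duration emitted length in seconds (after burn-in removal).
#' @param carrier_band `"theta"`, `"alpha"`, `"beta"`, or a numeric
#'   `c(low, high)` in Hz.
#' @param k_intra_1,k_intra_2 intra-brain coupling strengths (rad/s, >= 0).
#' @param k_inter inter-brain coupling strength (rad/s, >= 0).
#' @param noise_sd standard deviation of the additive 1/f-like noise,
#'   relative to the unit-amplitude oscillation (>= 0).
#' @param phase_diffusion per-channel phase-diffusion coefficient
#'   (rad/sqrt(s)); white frequency jitter that decorrelates uncoupled
#'   channels.
#' @param burn_in seconds simulated and discarded before the emitted block,
#'   so coupling has equilibrated (default 1).
#' @param seed root RNG seed; per-channel substreams are derived from it so
#'   that changing `n_channels` does not reshuffle other channels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 29, sampling_rate = 500, duration = 60,
                       carrier_band = "alpha",
                       k_intra_1 = 1, k_intra_2 = 1, k_inter = 0,
                       noise_sd = 0.5, phase_diffusion = 0.5,
                       burn_in = 1, seed = 1) {
  if (!is.numeric(duration) || duration <= 0 ||
      !is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("duration and sampling_rate must be positive")
  }
  if (is.character(carrier_band)) {
    if (!carrier_band %in% names(eeg_bands)) {
      stop("unknown carrier_band: ", carrier_band)
    }
    band <- eeg_bands[[carrier_band]]
    tag <- carrier_band
  } else {
    band <- as.numeric(carrier_band)
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
      stop("numeric carrier_band must be c(low, high) with 0 < low < high")
    }
    tag <- match_band_tag(band[1], band[2])
  }
  ks <- c(k_intra_1, k_intra_2, k_inter)
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop("coupling strengths must be finite and non-negative")
  }
  if (noise_sd < 0 || phase_diffusion < 0) {
    stop("noise_sd and phase_diffusion must be non-negative")
  }
  n_samp <- duration * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-8) {
    stop("duration x sampling_rate must be an integer sample count")
  }
  structure(
    list(n_channels = n_channels, sampling_rate = sampling_rate,
         duration = duration, carrier_band = band, band_tag = tag,
         k_intra_1 = k_intra_1, k_intra_2 = k_intra_2, k_inter = k_inter,
         noise_sd = noise_sd, phase_diffusion = phase_diffusion,
         burn_in = burn_in, seed = seed),
    class = "sim_config"
  )
}

# 1/f-amplitude noise: white Gaussian noise reshaped in the frequency
# domain with a 1/sqrt(f) amplitude envelope (power ~ 1/f), DC removed,
# standardized to unit variance. Not contractual; any spectrally plausible
# background would do.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # guard DC
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  W <- W / sqrt(f)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a coupled dual-EEG recording
#'
#' Euler-integrates `2 * n_channels` phase oscillators with Kuramoto sine
#' coupling to the within-participant and cross-participant mean fields,
#' plus white frequency jitter, then emits `cos(phase)` with additive
#' 1/f-like noise. The first `burn_in` seconds are discarded. Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A [dual_recording()] with `band_tag = "none"` (raw signals; the
#'   oscillation sits inside `carrier_band` but the noise is broadband).
#' @export
generate_coupled_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  dt <- 1 / fs
  nch <- config$n_channels
  ntot <- 2L * nch
  n_burn <- round(config$burn_in * fs)
  n_out <- round(config$duration * fs)
  n_steps <- n_burn + n_out

  # Per-channel substreams: natural frequency, initial phase, frequency
  # jitter increments, observation noise.
  omega <- numeric(ntot)
  phi0 <- numeric(ntot)
  jit <- matrix(0, ntot, n_steps)
  obs_noise <- matrix(0, ntot, n_out)
  for (ch in seq_len(ntot)) {
    # Carriers are drawn inside the band with a 10%-of-bandwidth margin per
    # edge so each oscillator's (diffusion-broadened) spectral line lies
    # within the band, not just its center.
    margin <- 0.1 * diff(config$carrier_band)
    with_seed(derive_seed(config$seed, ch), {
      freq <- stats::runif(1, config$carrier_band[1] + margin,
                           config$carrier_band[2] - margin)
      omega[ch] <- 2 * pi * freq
      phi0[ch] <- stats::runif(1, -pi, pi)
      jit[ch, ] <- stats::rnorm(n_steps)
      if (config$noise_sd > 0) obs_noise[ch, ] <- pink_noise(n_out)
    })
  }

  idx1 <- seq_len(nch)
  idx2 <- nch + seq_len(nch)
  k_intra <- c(rep(config$k_intra_1, nch), rep(config$k_intra_2, nch))
  theta <- phi0
  sig <- matrix(0, ntot, n_out)
  sq_dt_d <- sqrt(dt) * config$phase_diffusion
  for (t in seq_len(n_steps)) {
    z <- exp(1i * theta)
    z1 <- mean(z[idx1])
    z2 <- mean(z[idx2])
    own <- c(rep(z1, nch), rep(z2, nch))
    other <- c(rep(z2, nch), rep(z1, nch))
    drift <- omega +
      k_intra * Im(own * Conj(z)) +
      config$k_inter * Im(other * Conj(z))
    theta <- theta + dt * drift + sq_dt_d * jit[, t]
    if (t > n_burn) sig[, t - n_burn] <- cos(theta)
  }
  if (config$noise_sd > 0) sig <- sig + config$noise_sd * obs_noise

  labels <- if (nch <= length(channels_29)) channels_29[seq_len(nch)] else NULL
  dual_recording(sig[idx1, , drop = FALSE], sig[idx2, , drop = FALSE],
                 sampling_rate = fs, channel_labels = labels)
}

#' Tap-sequence simulation configuration
#'
#' @param requested_iti target inter-tap interval of participant 1, seconds
#'   (0.5 emulates the slow condition, 0.25 the fast one).
#' @param jitter_sd Gaussian timing jitter, seconds (>= 0).
#' @param n_taps_per_participant taps per participant (default 150).
#' @param phase_offset_fraction fraction of each participant-1 interval at
#'   which participant 2 taps; 0.5 is perfect anti-phase. In (0, 1).
#' @param seed RNG seed.
#' @return An object of class `tap_sim_config`.
#' @export
tap_sim_config <- function(requested_iti = 0.5, jitter_sd = 0.02,
                           n_taps_per_participant = 150,
                           phase_offset_fraction = 0.5, seed = 1) {
  if (n_taps_per_participant < 2) {
    stop("n_taps_per_participant must be at least 2")
  }
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  if (phase_offset_fraction <= 0 || phase_offset_fraction >= 1) {
    stop("phase_offset_fraction must lie strictly between 0 and 1")
  }
  if (requested_iti <= 0) stop("requested_iti must be positive")
  structure(
    list(requested_iti = requested_iti, jitter_sd = jitter_sd,
         n_taps = n_taps_per_participant,
         phase_offset_fraction = phase_offset_fraction, seed = seed),
    class = "tap_sim_config"
  )
}

#' Generate an alternating (anti-phase) dyadic tap sequence
#'
#' Participant 1 taps at cumulative sums of `requested_iti` plus Gaussian
#' jitter; participant 2 taps at `phase_offset_fraction` of each of
#' participant 1's intervals, plus independent jitter (the final tap
#' extrapolates beyond participant 1's last onset so both participants
#' produce `n_taps_per_participant` taps). Times are strictly increasing.
#'
#' @param config a [tap_sim_config()].
#' @param condition condition label stored on both records.
#' @return List with [tap_record()] elements `p1` and `p2`.
#' @export
generate_tap_series <- function(config, condition = "free") {
  stopifnot(inherits(config, "tap_sim_config"))
  with_seed(config$seed, {
    n <- config$n_taps
    iti <- config$requested_iti + stats::rnorm(n - 1, 0, config$jitter_sd)
    iti <- pmax(iti, 0.05 * config$requested_iti)  # keep strictly increasing
    t1 <- c(0, cumsum(iti))
    frac <- config$phase_offset_fraction
    t2 <- t1[-n] + frac * diff(t1) + stats::rnorm(n - 1, 0, config$jitter_sd)
    t2 <- c(t2, t1[n] + frac * config$requested_iti +
              stats::rnorm(1, 0, config$jitter_sd))
    t2 <- sort(t2)
    t2 <- make_strict(t2)
    list(
      p1 = tap_record(t1, participant_id = "p1", condition = condition),
      p2 = tap_record(t2, participant_id = "p2", condition = condition)
    )
  })
}

# Nudge ties upward so onset times are strictly increasing.
make_strict <- function(x, eps = 1e-9) {
  for (i in seq_along(x)[-1]) {
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  }
  x
}
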