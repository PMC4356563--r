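#' Sensor noise model
#'
#' Describes the additive sensor noise used by the simulators: a mixture of
#' spatially structured brain noise (random dipolar fields inside the head,
#' temporally smoothed) and spatially white sensor noise. After mixing, every
#' channel is rescaled to the requested standard deviation, so
#' `spatial_correlation` controls the share of variance carried by the
#' correlated component without changing per-channel power.
#'
#' @param spatial_correlation Fraction of noise variance from the spatially
#'   correlated dipolar component, in `[0, 1]`.
#' @param eeg_sd_uV,meg_sd_fT Target per-channel noise SD.
#' @param n_noise_dipoles Number of random noise dipoles for the correlated
#'   component.
#' @param ar Temporal AR(1) coefficient of the noise dipole time courses.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(spatial_correlation = 0.3,
                        eeg_sd_uV = 2.5, meg_sd_fT = 350,
                        n_noise_dipoles = 60L, ar = 0.95) {
  if (eeg_sd_uV < 0 || meg_sd_fT < 0)
    stop("noise SDs must be non-negative (configuration error)")
  if (spatial_correlation < 0 || spatial_correlation > 1)
    stop("spatial_correlation must be in [0, 1]")
  structure(list(spatial_correlation = spatial_correlation,
                 eeg_sd_uV = eeg_sd_uV, meg_sd_fT = meg_sd_fT,
                 n_noise_dipoles = as.integer(n_noise_dipoles), ar = ar),
            class = "noise_model")
}

# Draw a channels x samples noise matrix for one modality. `leadfield` supplies
# the spatial structure of the correlated component; the per-channel SD of the
# result equals sd_target exactly in-sample (up to channels that receive no
# correlated signal, which fall back to white noise).
.draw_noise <- function(nm, leadfield, n_samples, sd_target) {
  nc <- nrow(leadfield$gain)
  if (sd_target == 0) return(matrix(0, nc, n_samples))
  white <- matrix(stats::rnorm(nc * n_samples), nc, n_samples)
  rho <- nm$spatial_correlation
  if (rho > 0) {
    nd <- nm$n_noise_dipoles
    idx <- sample.int(leadfield$n_sources, min(nd, leadfield$n_sources))
    mom <- matrix(stats::rnorm(3 * length(idx)), length(idx), 3)
    topo <- leadfield$Gx[, idx, drop = FALSE] * rep(mom[, 1], each = nc) +
      leadfield$Gy[, idx, drop = FALSE] * rep(mom[, 2], each = nc) +
      leadfield$Gz[, idx, drop = FALSE] * rep(mom[, 3], each = nc)
    tc <- matrix(stats::rnorm(length(idx) * n_samples), length(idx), n_samples)
    if (nm$ar > 0)
      tc <- t(apply(tc, 1, function(z) as.numeric(stats::filter(z, nm$ar,
                                                                 "recursive"))))
    corr <- topo %*% tc
    csd <- apply(corr, 1, stats::sd)
    csd[csd == 0] <- 1
    corr <- corr / csd
    wsd <- apply(white, 1, stats::sd)
    noise <- sqrt(rho) * corr + sqrt(1 - rho) * white / wsd
  } else {
    noise <- white / apply(white, 1, stats::sd)
  }
  nsd <- apply(noise, 1, stats::sd)
  nsd[nsd == 0] <- 1
  noise / nsd * sd_target
}

# Biphasic spike template: smooth 20 ms rise, 30 ms fall, followed by a
# shallow slow after-wave. Unit peak amplitude; sampled at sfreq.
.spike_waveform <- function(sfreq) {
  dt <- 1000 / sfreq
  t <- seq(0, 160, by = dt)
  w <- numeric(length(t))
  rise <- t <= 20
  w[rise] <- sin(pi / 2 * t[rise] / 20)^2
  fall <- t > 20 & t <= 50
  w[fall] <- cos(pi / 2 * (t[fall] - 20) / 30)^2
  slow <- t > 50
  w[slow] <- -0.3 * sin(pi * (t[slow] - 50) / 110)^2
  list(t_ms = t, w = w, peak_offset = which.max(w) - 1L)
}

.new_recording <- function(data, sfreq, channels, ground_truth = NULL,
                           leadfields = NULL) {
  structure(list(data = data, sfreq = sfreq, channels = channels,
                 ground_truth = ground_truth, leadfields = leadfields),
            class = "emeg_recording")
}

#' @export
print.emeg_recording <- function(x, ...) {
  cat(sprintf("EEG/MEG recording: %d channels (%d EEG, %d MEG), %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), sum(x$channels$modality == "EEG"),
              sum(x$channels$modality == "MEG"),
              ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d events\n", nrow(x$ground_truth)))
  invisible(x)
}

.channel_table <- function(phantom) {
  data.frame(
    name = c(phantom$eeg$names, phantom$meg$names),
    modality = c(rep("EEG", nrow(phantom$eeg$positions)),
                 rep("MEG", nrow(phantom$meg$positions))),
    hemisphere = c(phantom$eeg$hemisphere, phantom$meg$hemisphere),
    stringsAsFactors = FALSE)
}

#' Simulate a continuous spike run
#'
#' Generates a continuous EEG+MEG recording containing `n_spikes` interictal
#' spikes with stochastic origins inside the irritative zone. Each spike
#' starts in the deep patch; after the zone's propagation delay the lateral
#' patch ramps up and carries the (larger) late component, so the sensor-level
#' spike peak reflects propagated lateral activity while spike onset reflects
#' the deep origin. Single-spike amplitudes follow the zone's log-normal law.
#'
#' @param phantom An [make_phantom()] result.
#' @param zone An irritative-zone object; defaults to `phantom$zone`.
#' @param n_spikes Number of spikes to embed.
#' @param noise A [noise_model()].
#' @param duration_s Recording length; default allots 0.8 s per spike plus
#'   lead-in/out.
#' @param sfreq Sampling rate in Hz.
#' @param lateral_gain Amplitude of the propagated lateral component relative
#'   to the deep component.
#' @param leadfields Optional precomputed list with elements `eeg` and `meg`
#'   ([build_leadfield()] results) to avoid recomputation.
#' @param seed Integer RNG seed.
#' @return An `emeg_recording` whose `ground_truth` lists one row per spike:
#'   onset sample, deep and lateral origin indices, amplitude (nAm) and the
#'   sample of the nominal sensor-level peak.
#' @export
simulate_spike_run <- function(phantom, zone = phantom$zone, n_spikes = 200L,
                               noise = noise_model(), duration_s = NULL,
                               sfreq = 250, lateral_gain = 2.0,
                               leadfields = NULL, seed = 1L) {
  if (n_spikes < 1L) stop("n_spikes must be >= 1")
  wf <- .spike_waveform(sfreq)
  epoch_len_s <- max(wf$t_ms) / 1000 + 0.45
  if (is.null(duration_s)) duration_s <- n_spikes * 0.8 + 2 * epoch_len_s
  n_samp <- round(duration_s * sfreq)
  gap <- floor((n_samp - 2 * length(wf$w)) / n_spikes)
  if (gap < length(wf$w) + round(0.25 * sfreq))
    stop("duration too short for the requested number of spikes (configuration error)")
  set.seed(as.integer(seed))

  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = build_leadfield(phantom$source_space, phantom$eeg, phantom$head),
      meg = build_leadfield(phantom$source_space, phantom$meg, phantom$head))
  }
  pos <- phantom$source_space$positions

  pick_origin <- function(patch, seed_pt) {
    d <- sqrt(colSums((t(pos[patch, , drop = FALSE]) - seed_pt)^2))
    cand <- patch[d <= zone$origin_jitter_mm]
    if (length(cand) == 0L) cand <- patch[which.min(d)]
    cand[sample.int(length(cand), 1L)]
  }

  onsets <- round(length(wf$w) + (seq_len(n_spikes) - 1) * gap +
                    stats::runif(n_spikes, 0, 0.2 * sfreq))
  amp <- stats::rlnorm(n_spikes, meanlog = log(zone$amplitude_median_nAm),
                       sdlog = zone$amplitude_sdlog)
  deep_origin <- vapply(seq_len(n_spikes), function(i)
    pick_origin(zone$deep_patch, zone$deep_seed), integer(1))
  lat_origin <- vapply(seq_len(n_spikes), function(i)
    pick_origin(zone$lateral_patch, zone$lateral_seed), integer(1))

  delay_samp <- round(zone$propagation_delay_ms / 1000 * sfreq)
  nw <- length(wf$w)
  nc_eeg <- nrow(leadfields$eeg$gain)
  nc_meg <- nrow(leadfields$meg$gain)
  data <- matrix(0, nc_eeg + nc_meg, n_samp)
  normals <- phantom$source_space$normals
  peak_sample <- integer(n_spikes)

  for (i in seq_len(n_spikes)) {
    o <- onsets[i]
    idx_deep <- o:(o + nw - 1L)
    idx_lat <- idx_deep + delay_samp
    # source currents along the nominal cortical orientations
    m_deep <- amp[i] * normals[deep_origin[i], ]
    m_lat <- lateral_gain * amp[i] * normals[lat_origin[i], ]
    add_spike <- function(lf, rows) {
      g_d <- lf$Gx[, deep_origin[i]] * m_deep[1] +
        lf$Gy[, deep_origin[i]] * m_deep[2] +
        lf$Gz[, deep_origin[i]] * m_deep[3]
      g_l <- lf$Gx[, lat_origin[i]] * m_lat[1] +
        lf$Gy[, lat_origin[i]] * m_lat[2] +
        lf$Gz[, lat_origin[i]] * m_lat[3]
      data[rows, idx_deep] <<- data[rows, idx_deep] + outer(g_d, wf$w)
      data[rows, idx_lat] <<- data[rows, idx_lat] + outer(g_l, wf$w)
    }
    add_spike(leadfields$eeg, seq_len(nc_eeg))
    add_spike(leadfields$meg, nc_eeg + seq_len(nc_meg))
    peak_sample[i] <- o + delay_samp + wf$peak_offset
  }

  data[seq_len(nc_eeg), ] <- data[seq_len(nc_eeg), ] +
    .draw_noise(noise, leadfields$eeg, n_samp, noise$eeg_sd_uV)
  data[nc_eeg + seq_len(nc_meg), ] <- data[nc_eeg + seq_len(nc_meg), ] +
    .draw_noise(noise, leadfields$meg, n_samp, noise$meg_sd_fT)

  gt <- data.frame(spike = seq_len(n_spikes), onset_sample = onsets,
                   peak_sample = peak_sample,
                   deep_origin = deep_origin, lateral_origin = lat_origin,
                   amplitude_nAm = amp)
  .new_recording(data, sfreq, .channel_table(phantom), ground_truth = gt,
                 leadfields = leadfields)
}

#' Simulate a somatosensory calibration run
#'
#' Generates a stimulus-locked run for skull-conductivity calibration: a fixed
#' cortical source (the early somatosensory component) activates with a short
#' monophasic waveform at a fixed latency after each stimulus, superimposed on
#' sensor noise.
#'
#' @param phantom An [make_phantom()] result.
#' @param n20_index Source-space index of the calibration source.
#' @param n20_moment Length-3 dipole moment in nAm.
#' @param n_trials Number of stimuli.
#' @param latency_ms Component latency after the stimulus.
#' @param noise A [noise_model()].
#' @param sfreq Sampling rate in Hz.
#' @param leadfields Optional precomputed leadfields (as in
#'   [simulate_spike_run()]).
#' @param seed Integer RNG seed.
#' @return An `emeg_recording`; `ground_truth` holds one row per stimulus with
#'   the stimulus sample and the component-peak sample.
#' @export
simulate_sep_run <- function(phantom, n20_index, n20_moment = c(0, 20, 5),
                             n_trials = 200L, latency_ms = 20,
                             noise = noise_model(), sfreq = 1000,
                             leadfields = NULL, seed = 1L) {
  pos <- phantom$source_space$positions
  if (n20_index < 1L || n20_index > nrow(pos))
    stop("calibration source outside the source space (geometry error)")
  set.seed(as.integer(seed))
  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = build_leadfield(phantom$source_space, phantom$eeg, phantom$head),
      meg = build_leadfield(phantom$source_space, phantom$meg, phantom$head))
  }
  dt <- 1000 / sfreq
  t <- seq(0, 12, by = dt)
  w <- sin(pi * t / 12)^2                       # ~12 ms monophasic component
  nw <- length(w)
  isi <- round(0.25 * sfreq)
  n_samp <- isi * (n_trials + 1L)
  stim <- isi * seq_len(n_trials) - round(0.1 * sfreq)
  lat <- round(latency_ms / 1000 * sfreq)

  nc_eeg <- nrow(leadfields$eeg$gain)
  nc_meg <- nrow(leadfields$meg$gain)
  g_eeg <- leadfields$eeg$Gx[, n20_index] * n20_moment[1] +
    leadfields$eeg$Gy[, n20_index] * n20_moment[2] +
    leadfields$eeg$Gz[, n20_index] * n20_moment[3]
  g_meg <- leadfields$meg$Gx[, n20_index] * n20_moment[1] +
    leadfields$meg$Gy[, n20_index] * n20_moment[2] +
    leadfields$meg$Gz[, n20_index] * n20_moment[3]

  data <- matrix(0, nc_eeg + nc_meg, n_samp)
  for (s in stim) {
    idx <- (s + lat):(s + lat + nw - 1L)
    data[seq_len(nc_eeg), idx] <- data[seq_len(nc_eeg), idx] + outer(g_eeg, w)
    data[nc_eeg + seq_len(nc_meg), idx] <- data[nc_eeg + seq_len(nc_meg), idx] +
      outer(g_meg, w)
  }
  data[seq_len(nc_eeg), ] <- data[seq_len(nc_eeg), ] +
    .draw_noise(noise, leadfields$eeg, n_samp, noise$eeg_sd_uV)
  data[nc_eeg + seq_len(nc_meg), ] <- data[nc_eeg + seq_len(nc_meg), ] +
    .draw_noise(noise, leadfields$meg, n_samp, noise$meg_sd_fT)

  gt <- data.frame(trial = seq_len(n_trials), stim_sample = stim,
                   peak_sample = stim + lat + which.max(w) - 1L,
                   source_index = n20_index)
  .new_recording(data, sfreq, .channel_table(phantom), ground_truth = gt,
                 leadfields = leadfields)
}
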