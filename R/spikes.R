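#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase) to every
#' channel of a recording.
#'
#' @param recording An `emeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < sfreq/2`.
#' @param order Butterworth order (per pass).
#' @return The filtered recording.
#' @export
bandpass <- function(recording, low_hz = 1, high_hz = 100, order = 4L) {
  nyq <- recording$sfreq / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist (configuration error)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- recording
  out$data <- t(apply(recording$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  out
}

#' Average a recording around marked events to form a detection template
#'
#' @param recording An `emeg_recording`.
#' @param event_samples Integer sample indices of the marked events (aligned
#'   to the feature used for matching, typically the spike peak).
#' @param channels Integer or logical index of the channels used for
#'   detection (a small subset over the active region).
#' @param half_window_ms Half-width of the template window in ms.
#' @return An object of class `spike_template`: channel-subset mean epoch.
#' @export
make_template <- function(recording, event_samples, channels,
                          half_window_ms = 100) {
  if (length(event_samples) < 1L) stop("at least one marked event is required")
  hw <- round(half_window_ms / 1000 * recording$sfreq)
  n <- ncol(recording$data)
  event_samples <- event_samples[event_samples - hw >= 1 &
                                   event_samples + hw <= n]
  if (length(event_samples) < 1L)
    stop("no marked event has a full template window inside the recording")
  acc <- 0
  for (s in event_samples)
    acc <- acc + recording$data[channels, (s - hw):(s + hw), drop = FALSE]
  structure(list(data = acc / length(event_samples), channels = channels,
                 sfreq = recording$sfreq, half_window = hw),
            class = "spike_template")
}

#' Detect spikes by normalized template matching
#'
#' Slides the template over the recording's detection channels and computes
#' the centred, normalized cross-correlation; local maxima above the
#' threshold, separated by a refractory lockout, are returned as events. The
#' statistic is invariant to the local signal scale, so spikes of varying
#' amplitude are detected alike.
#'
#' @param recording An `emeg_recording`.
#' @param template A [make_template()] result.
#' @param threshold Correlation threshold in `(0, 1]`.
#' @param refractory_ms Minimum separation between detections in ms.
#' @return Integer vector of event samples (template-centre alignment),
#'   sorted in time, with the achieved correlations as attribute `corr`.
#' @export
detect_spikes <- function(recording, template, threshold = 0.8,
                          refractory_ms = 200) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  tm <- template$data
  if (length(tm) == 0L) stop("empty template (configuration error)")
  X <- recording$data[template$channels, , drop = FALSE]
  L <- ncol(tm); C <- nrow(tm); n <- ncol(X)
  if (L >= n) stop("template longer than recording")
  Tc <- tm - mean(tm)
  tnorm <- sqrt(sum(Tc^2))
  if (tnorm == 0) stop("constant template (configuration error)")

  n_lag <- n - L + 1L
  # numerator: sum over channels of sliding cross-correlation with Tc
  num <- numeric(n_lag)
  for (ch in seq_len(C)) {
    cc <- stats::convolve(X[ch, ], Tc[ch, ], type = "filter")
    num <- num + cc
  }
  # sliding window mean and power over the channel-stacked window
  cs1 <- c(0, cumsum(colSums(X)))
  cs2 <- c(0, cumsum(colSums(X^2)))
  s1 <- cs1[(L + 1):(n + 1)] - cs1[seq_len(n_lag)]
  s2 <- cs2[(L + 1):(n + 1)] - cs2[seq_len(n_lag)]
  wnorm2 <- s2 - s1^2 / (L * C)
  wnorm2[wnorm2 < 0] <- 0
  r <- num / (tnorm * sqrt(wnorm2))
  r[!is.finite(r)] <- 0

  lock <- round(refractory_ms / 1000 * recording$sfreq)
  cand <- which(r >= threshold)
  # local maxima within the lockout, accepted greedily by correlation
  cand <- cand[order(r[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (k in cand) {
    if (length(taken) == 0L || all(abs(taken - k) > lock)) taken <- c(taken, k)
  }
  taken <- sort(taken)
  centre <- taken + (L - 1L) %/% 2L
  structure(centre, corr = r[taken])
}

#' Extract peak-aligned epochs
#'
#' Cuts fixed-length epochs around each event and aligns time 0 to the EEG
#' global-field-power maximum near the event (the operational definition of
#' the spike peak).
#'
#' @param recording An `emeg_recording`.
#' @param event_samples Integer event samples (e.g. from [detect_spikes()]).
#' @param window_ms Length-2 epoch window in ms relative to the aligned peak.
#' @param align_halfwidth_ms Search half-width for the GFP peak around each
#'   event; set to 0 to keep the supplied alignment.
#' @return A list of `epoch` objects: each has `data` (channels x samples),
#'   `times_ms`, `sfreq`, `channels`, and the contributing spike id.
#' @export
extract_epochs <- function(recording, event_samples,
                           window_ms = c(-200, 200),
                           align_halfwidth_ms = 40) {
  sf <- recording$sfreq
  pre <- round(abs(window_ms[1]) / 1000 * sf)
  post <- round(window_ms[2] / 1000 * sf)
  hw <- round(align_halfwidth_ms / 1000 * sf)
  eeg_rows <- which(recording$channels$modality == "EEG")
  n <- ncol(recording$data)
  out <- list()
  for (i in seq_along(event_samples)) {
    s <- event_samples[i]
    if (hw > 0) {
      lo <- max(1, s - hw); hi <- min(n, s + hw)
      seg <- recording$data[eeg_rows, lo:hi, drop = FALSE]
      gfp <- apply(seg, 2, stats::sd)
      s <- lo + which.max(gfp) - 1L
    }
    if (s - pre < 1 || s + post > n) next
    ep <- structure(list(
      data = recording$data[, (s - pre):(s + post), drop = FALSE],
      times_ms = seq(-pre, post) / sf * 1000,
      sfreq = sf, channels = recording$channels,
      peak_sample = s, members = i), class = "epoch")
    out[[length(out) + 1L]] <- ep
  }
  out
}

#' SNR of an epoch at a time point
#'
#' The power signal-to-noise ratio used for gating: the channel-mean squared
#' amplitude at the sample nearest `time_ms`, divided by the channel-mean
#' baseline variance over the -200 to -70 ms window.
#'
#' @param epoch An `epoch`.
#' @param time_ms Evaluation instant in ms (0 = aligned spike peak).
#' @param channels Integer/logical channel subset defining the modality.
#' @param baseline_ms Length-2 baseline window in ms.
#' @return An object of class `snr_record`: list with `value`, `time_ms`,
#'   `baseline_ms`, `n_channels`.
#' @export
compute_snr <- function(epoch, time_ms, channels,
                        baseline_ms = c(-200, -70)) {
  if (length(channels) == 0L || (is.logical(channels) && !any(channels)))
    stop("empty channel set (configuration error)")
  it <- which.min(abs(epoch$times_ms - time_ms))
  if (abs(epoch$times_ms[it] - time_ms) > 1000 / epoch$sfreq)
    stop("time point outside the epoch")
  ib <- which(epoch$times_ms >= baseline_ms[1] & epoch$times_ms <= baseline_ms[2])
  if (length(ib) < 2L) stop("baseline window outside the epoch")
  x <- epoch$data[channels, , drop = FALSE]
  sig_pow <- mean(x[, it]^2)
  noise_var <- mean(apply(x[, ib, drop = FALSE], 1, stats::var))
  structure(list(value = sig_pow / noise_var, time_ms = epoch$times_ms[it],
                 baseline_ms = baseline_ms, n_channels = nrow(x)),
            class = "snr_record")
}

#' Bootstrap subaverages of single-spike epochs
#'
#' Builds the subaverage groups: for each group size k > 1, a fixed number of
#' realizations, each averaging k distinct spikes drawn at random without
#' replacement within the realization (spikes may recur across realizations).
#' Group size 1 is the identity list of all single spikes.
#'
#' @param epochs List of `epoch` objects (the single spikes).
#' @param group_sizes Integer vector of subaverage sizes; 1 denotes the
#'   single-spike group.
#' @param n_realizations Number of realizations per group (sizes > 1).
#' @param seed Integer run seed; realization r of group k uses a sub-seed
#'   derived from (seed, k, r) by counter, so outputs are reproducible
#'   realization-by-realization.
#' @return A list of subaverage realizations: each has `group` ("Av<k>"),
#'   `k`, `members` (epoch indices), and `epoch` (the averaged epoch).
#' @export
make_subaverages <- function(epochs, group_sizes = c(1L, seq(5L, 50L, by = 5L)),
                             n_realizations = 200L, seed = 1L) {
  n <- length(epochs)
  if (any(group_sizes > n))
    stop("group size exceeds the number of epochs (configuration error)")
  out <- list()
  for (k in group_sizes) {
    if (k == 1L) {
      for (i in seq_len(n)) {
        out[[length(out) + 1L]] <- list(group = "Av1", k = 1L, members = i,
                                        realization = i, epoch = epochs[[i]])
      }
      next
    }
    for (r in seq_len(n_realizations)) {
      set.seed(as.integer(seed) + 100000L * as.integer(k) + as.integer(r))
      members <- sort(sample.int(n, k, replace = FALSE))
      acc <- epochs[[members[1]]]$data
      for (m in members[-1]) acc <- acc + epochs[[m]]$data
      ep <- epochs[[members[1]]]
      ep$data <- acc / k
      ep$members <- members
      out[[length(out) + 1L]] <- list(group = sprintf("Av%d", k), k = k,
                                      members = members, realization = r,
                                      epoch = ep)
    }
  }
  out
}

#' SNR gate
#'
#' Keeps the realizations whose SNR at the requested time, on the requested
#' channel subset, is strictly greater than the threshold.
#'
#' @param realizations Output of [make_subaverages()].
#' @param channels Channel subset defining the modality.
#' @param time_ms Evaluation instant.
#' @param threshold Gate threshold (strictly-greater comparison).
#' @return The surviving realizations, each annotated with `snr`.
#' @export
snr_gate <- function(realizations, channels, time_ms, threshold = 3) {
  if (threshold <= 0) stop("threshold must be positive")
  keep <- list()
  for (rl in realizations) {
    s <- compute_snr(rl$epoch, time_ms, channels)
    if (s$value > threshold) {
      rl$snr <- s$value
      keep[[length(keep) + 1L]] <- rl
    }
  }
  keep
}
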