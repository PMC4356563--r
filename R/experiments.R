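#' Gated SNR versus subaverage size
#'
#' Simulates one spike run on the phantom, forms subaverages of increasing
#' size and reports the median gated SNR per modality and group — the SNR
#' growth curve. Because single-spike amplitudes vary (log-normal law), the
#' growth is slower than proportional to the number of averaged spikes.
#'
#' @param phantom A [make_phantom()] result.
#' @param leadfields Optional precomputed leadfields (see [run_pipeline()]).
#' @param n_spikes,group_sizes,n_realizations,time_ms,snr_threshold Study
#'   parameters.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return Data frame: modality, k, n_gated (of the realizations drawn),
#'   median_snr (gated realizations only; NA if none survive).
#' @export
experiment_snr_growth <- function(phantom, leadfields = NULL, n_spikes = 100L,
                                  group_sizes = c(1L, 5L, 10L, 25L, 50L),
                                  n_realizations = 60L, time_ms = -23,
                                  snr_threshold = 3, noise = noise_model(),
                                  seed = 1L) {
  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = build_leadfield(phantom$source_space, phantom$eeg, phantom$head),
      meg = build_leadfield(phantom$source_space, phantom$meg, phantom$head))
  }
  rec <- simulate_spike_run(phantom, n_spikes = n_spikes, noise = noise,
                            leadfields = leadfields, seed = seed)
  epochs <- extract_epochs(rec, rec$ground_truth$peak_sample)
  reals <- make_subaverages(epochs, group_sizes = group_sizes,
                            n_realizations = n_realizations, seed = seed)
  eeg_rows <- which(rec$channels$modality == "EEG")
  meg_rows <- which(rec$channels$modality == "MEG")
  ml <- select_meg_left(phantom$meg)
  out <- list()
  for (mod in c("EEG", "MEG")) {
    ch <- if (mod == "EEG") eeg_rows else meg_rows[ml]
    for (k in group_sizes) {
      rk <- Filter(function(r) r$k == k, reals)
      snrs <- vapply(rk, function(r)
        compute_snr(r$epoch, time_ms, ch)$value, numeric(1))
      gated <- snrs[snrs > snr_threshold]
      out[[length(out) + 1L]] <- data.frame(
        modality = mod, k = k, n_drawn = length(rk), n_gated = length(gated),
        median_snr = if (length(gated)) stats::median(gated) else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Noise-bias experiment: single-spike versus large-subaverage centroids
#'
#' For several independent simulation seeds, localizes the gated single-spike
#' (Av1) and large-subaverage (Av-k) realizations and compares the distance
#' of the two cluster centroids from the head centre. Low-SNR single-spike
#' localizations are systematically pulled toward the centre (deeper) by
#' noise; large subaverages are not.
#'
#' @param phantom A [make_phantom()] result.
#' @param leadfields Optional precomputed leadfields.
#' @param n_seeds Number of independent simulated runs.
#' @param k_large Large subaverage size to compare against Av1.
#' @param n_spikes,n_realizations,time_ms Study parameters.
#' @param noise A [noise_model()].
#' @param seed Base seed; run s uses seed + s.
#' @return Data frame with one row per (seed, modality): centroid distance
#'   from the head centre for Av1 and Av-k and the indicator
#'   `av1_deeper` (Av1 centroid strictly closer to the centre).
#' @export
experiment_noise_bias <- function(phantom, leadfields = NULL, n_seeds = 10L,
                                  k_large = 50L, n_spikes = 120L,
                                  n_realizations = 30L, time_ms = -3,
                                  noise = noise_model(), seed = 1L) {
  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = build_leadfield(phantom$source_space, phantom$eeg, phantom$head),
      meg = build_leadfield(phantom$source_space, phantom$meg, phantom$head))
  }
  out <- list()
  for (s in seq_len(n_seeds)) {
    pp <- run_pipeline(phantom = phantom, leadfields = leadfields,
                       n_spikes = n_spikes,
                       group_sizes = c(1L, k_large),
                       n_realizations = n_realizations,
                       times_ms = time_ms, noise = noise,
                       filter = FALSE, detection = FALSE, prune = FALSE,
                       seed = seed + s)
    ctr <- pp$centroids
    for (mod in unique(ctr$modality)) {
      d1 <- ctr$depth_mm[ctr$modality == mod & ctr$group == "Av1"]
      dk <- ctr$depth_mm[ctr$modality == mod &
                           ctr$group == sprintf("Av%d", k_large)]
      if (length(d1) == 1L && length(dk) == 1L)
        out[[length(out) + 1L]] <- data.frame(
          seed = seed + s, modality = mod, r_av1_mm = d1, r_avk_mm = dk,
          av1_deeper = d1 < dk)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Onset-phase modality comparison for a deep source
#'
#' Emulates the spike-onset analysis: only the deep irritative-zone patch is
#' active, at a subaverage-level SNR near the gate. For each Monte-Carlo
#' draw, the deep-source topography plus noise (scaled as an average of
#' `k_average` epochs) is scanned with EEG alone, left-hemisphere MEG alone
#' (regularized) and fused EMEG, and the distance of the scan result to the
#' true deep patch is recorded.
#'
#' @param phantom A [make_phantom()] result.
#' @param leadfields Optional precomputed leadfields.
#' @param n_seeds Monte-Carlo draws.
#' @param k_average Equivalent subaverage size setting the noise level.
#' @param amplitude_nAm Deep-source amplitude.
#' @param hit_radius_mm Distance defining a localization hit.
#' @param noise A [noise_model()].
#' @param seed Base seed.
#' @return List: `results` (per draw and modality: distance to the deep
#'   patch), `hit_rate` (named vector over EEG/MEG/EMEG), `median_mm`.
#' @export
experiment_onset_dominance <- function(phantom, leadfields = NULL,
                                       n_seeds = 20L, k_average = 10L,
                                       amplitude_nAm = 50,
                                       hit_radius_mm = 15,
                                       noise = noise_model(), seed = 1L) {
  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = build_leadfield(phantom$source_space, phantom$eeg, phantom$head),
      meg = build_leadfield(phantom$source_space, phantom$meg, phantom$head))
  }
  lf_e <- leadfields$eeg
  ml <- select_meg_left(phantom$meg)
  lf_ml <- subset_leadfield(leadfields$meg, ml)
  pos <- phantom$source_space$positions
  patch <- pos[phantom$zone$deep_patch, , drop = FALSE]
  dpatch <- function(p) min(sqrt(rowSums(sweep(patch, 2, p)^2)))
  L <- 120L  # baseline samples used to estimate fusion weights
  res <- list()
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    j <- phantom$zone$deep_patch[sample.int(nrow(patch), 1L)]
    m <- amplitude_nAm * phantom$source_space$normals[j, ]
    ye0 <- lf_e$Gx[, j] * m[1] + lf_e$Gy[, j] * m[2] + lf_e$Gz[, j] * m[3]
    ym0 <- lf_ml$Gx[, j] * m[1] + lf_ml$Gy[, j] * m[2] + lf_ml$Gz[, j] * m[3]
    ne <- .draw_noise(noise, lf_e, L + 1L, noise$eeg_sd_uV / sqrt(k_average))
    nmg <- .draw_noise(noise, leadfields$meg, L + 1L,
                       noise$meg_sd_fT / sqrt(k_average))[ml, , drop = FALSE]
    ye <- ye0 + ne[, L + 1L]; ym <- ym0 + nmg[, L + 1L]
    sde <- apply(ne[, seq_len(L)], 1, stats::sd)
    sdm <- apply(nmg[, seq_len(L)], 1, stats::sd)
    d_eeg <- dpatch(deviation_scan(ye, lf_e)$location)
    d_meg <- dpatch(deviation_scan(ym, lf_ml,
                                   regularization = "tikhonov")$location)
    lf_f <- structure(list(
      Gx = rbind(lf_e$Gx / sde, lf_ml$Gx / sdm),
      Gy = rbind(lf_e$Gy / sde, lf_ml$Gy / sdm),
      Gz = rbind(lf_e$Gz / sde, lf_ml$Gz / sdm),
      kind = "EMEG", n_sources = lf_e$n_sources,
      source_positions = pos), class = "leadfield")
    d_emeg <- dpatch(deviation_scan(c(ye / sde, ym / sdm), lf_f)$location)
    res[[s]] <- data.frame(draw = s, EEG = d_eeg, MEG = d_meg, EMEG = d_emeg)
  }
  res <- do.call(rbind, res)
  hit <- c(EEG = mean(res$EEG <= hit_radius_mm),
           MEG = mean(res$MEG <= hit_radius_mm),
           EMEG = mean(res$EMEG <= hit_radius_mm))
  med <- c(EEG = stats::median(res$EEG), MEG = stats::median(res$MEG),
           EMEG = stats::median(res$EMEG))
  list(results = res, hit_rate = hit, median_mm = med,
       hit_radius_mm = hit_radius_mm, k_average = k_average)
}
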