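test_that("noise generator hits the requested per-channel SD and correlation regime", {
  lf <- tiny_leadfields()$eeg
  nm <- noise_model(spatial_correlation = 0.5, eeg_sd_uV = 2)
  set.seed(5)
  nz <- emegscan:::.draw_noise(nm, lf, 10000, 2)
  sds <- apply(nz, 1, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.1))
  # white-only configuration: mean absolute inter-channel correlation small
  nmw <- noise_model(spatial_correlation = 0)
  set.seed(6)
  nw <- emegscan:::.draw_noise(nmw, lf, 10000, 1)
  cc <- cor(t(nw))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
  # correlated configuration raises inter-channel correlation
  set.seed(6)
  nc <- emegscan:::.draw_noise(noise_model(spatial_correlation = 0.8), lf,
                               5000, 1)
  cc2 <- cor(t(nc))
  expect_gt(mean(abs(cc2[upper.tri(cc2)])), 0.2)
})

test_that("zero-SD noise is exactly zero and negative SD is rejected", {
  lf <- tiny_leadfields()$eeg
  expect_equal(emegscan:::.draw_noise(noise_model(), lf, 100, 0),
               matrix(0, nrow(lf$gain), 100))
  expect_error(noise_model(eeg_sd_uV = -1), "non-negative")
  expect_error(noise_model(spatial_correlation = 1.5), "0, 1")
})

test_that("noise stream is reproducible under a fixed seed", {
  lf <- tiny_leadfields()$eeg
  set.seed(9); a <- emegscan:::.draw_noise(noise_model(), lf, 500, 1)
  set.seed(9); b <- emegscan:::.draw_noise(noise_model(), lf, 500, 1)
  expect_identical(a, b)
})

test_that("spike run embeds exactly the requested ground-truth events", {
  ph <- tiny_phantom()
  rec <- simulate_spike_run(ph, n_spikes = 15, leadfields = tiny_leadfields(),
                            seed = 7)
  expect_equal(nrow(rec$ground_truth), 15L)
  expect_true(all(rec$ground_truth$amplitude_nAm > 0))
  expect_true(all(rec$ground_truth$onset_sample >= 1 &
                    rec$ground_truth$peak_sample <= ncol(rec$data)))
  expect_true(all(rec$ground_truth$deep_origin %in% ph$zone$deep_patch))
  expect_true(all(rec$ground_truth$lateral_origin %in% ph$zone$lateral_patch))
})

test_that("noise-free sensor data equal the leadfield applied to the true currents", {
  ph <- tiny_phantom()
  lfs <- tiny_leadfields()
  nil <- noise_model(eeg_sd_uV = 0, meg_sd_fT = 0)
  rec <- simulate_spike_run(ph, n_spikes = 3, noise = nil, leadfields = lfs,
                            lateral_gain = 2, seed = 11)
  gt <- rec$ground_truth
  wf <- emegscan:::.spike_waveform(rec$sfreq)
  delay <- round(ph$zone$propagation_delay_ms / 1000 * rec$sfreq)
  nrm <- ph$source_space$normals
  n_eeg <- nrow(ph$eeg$positions)
  for (i in seq_len(3)) {
    s <- gt$onset_sample[i] + delay + wf$peak_offset  # lateral peak sample
    w_deep <- wf$w[delay + wf$peak_offset + 1L]
    mom <- matrix(0, nrow(ph$source_space$positions), 3)
    mom[gt$deep_origin[i], ] <- gt$amplitude_nAm[i] * w_deep * nrm[gt$deep_origin[i], ]
    mom[gt$lateral_origin[i], ] <- mom[gt$lateral_origin[i], ] +
      2 * gt$amplitude_nAm[i] * 1 * nrm[gt$lateral_origin[i], ]
    expect_equal(rec$data[seq_len(n_eeg), s], apply_leadfield(lfs$eeg, mom),
                 tolerance = 1e-12)
    expect_equal(rec$data[-seq_len(n_eeg), s], apply_leadfield(lfs$meg, mom),
                 tolerance = 1e-12)
  }
})

test_that("lateral patch stays silent during the propagation delay", {
  ph <- tiny_phantom()
  lfs <- tiny_leadfields()
  nil <- noise_model(eeg_sd_uV = 0, meg_sd_fT = 0)
  rec <- simulate_spike_run(ph, n_spikes = 4, noise = nil, leadfields = lfs,
                            seed = 13)
  gt <- rec$ground_truth
  delay <- round(ph$zone$propagation_delay_ms / 1000 * rec$sfreq)
  nrm <- ph$source_space$normals
  wf <- emegscan:::.spike_waveform(rec$sfreq)
  n_eeg <- nrow(ph$eeg$positions)
  for (i in seq_len(4)) {
    # within the delay window the data are explained by the deep source alone
    for (off in c(0L, delay - 1L)) {
      s <- gt$onset_sample[i] + off
      mom <- matrix(0, nrow(ph$source_space$positions), 3)
      mom[gt$deep_origin[i], ] <- gt$amplitude_nAm[i] * wf$w[off + 1L] *
        nrm[gt$deep_origin[i], ]
      expect_equal(rec$data[seq_len(n_eeg), s], apply_leadfield(lfs$eeg, mom),
                   tolerance = 1e-12)
    }
  }
})

test_that("spike run is deterministic and rejects impossible configurations", {
  ph <- tiny_phantom()
  lfs <- tiny_leadfields()
  a <- simulate_spike_run(ph, n_spikes = 5, leadfields = lfs, seed = 3)
  b <- simulate_spike_run(ph, n_spikes = 5, leadfields = lfs, seed = 3)
  expect_identical(a$data, b$data)
  expect_error(simulate_spike_run(ph, n_spikes = 100, duration_s = 5,
                                  leadfields = lfs, seed = 1),
               "duration too short")
})

test_that("somatosensory run averages to the noise-free topography", {
  ph <- tiny_phantom()
  lfs <- tiny_leadfields()
  j <- which.min(colSums((t(ph$source_space$positions) - c(30, -20, 55))^2))
  mom <- 60 * ph$source_space$normals[j, ]
  sep <- simulate_sep_run(ph, j, n20_moment = mom, n_trials = 500,
                          noise = noise_model(), sfreq = 500,
                          leadfields = lfs, seed = 21)
  pk <- sep$ground_truth$peak_sample
  avg <- rowMeans(vapply(pk, function(s) sep$data[, s],
                         numeric(nrow(sep$data))))
  n_eeg <- nrow(ph$eeg$positions)
  clean_eeg <- lfs$eeg$Gx[, j] * mom[1] + lfs$eeg$Gy[, j] * mom[2] +
    lfs$eeg$Gz[, j] * mom[3]
  clean_meg <- lfs$meg$Gx[, j] * mom[1] + lfs$meg$Gy[, j] * mom[2] +
    lfs$meg$Gz[, j] * mom[3]
  expect_gt(cor(avg[seq_len(n_eeg)], clean_eeg), 0.99)
  expect_gt(cor(avg[-seq_len(n_eeg)], clean_meg), 0.99)
})

test_that("trial averaging shrinks the residual noise like one over root n", {
  ph <- tiny_phantom()
  lfs <- tiny_leadfields()
  j <- 5L
  resid_sd <- vapply(c(25L, 400L), function(nt) {
    sep <- simulate_sep_run(ph, j, n20_moment = c(0, 0, 0), n_trials = nt,
                            noise = noise_model(spatial_correlation = 0,
                                                meg_sd_fT = 2.5),
                            sfreq = 500, leadfields = lfs, seed = 31)
    pk <- sep$ground_truth$peak_sample
    avg <- rowMeans(vapply(pk, function(s) sep$data[, s],
                           numeric(nrow(sep$data))))
    sqrt(mean(avg^2))  # rms over all channels (equal noise SD on both blocks)
  }, numeric(1))
  # 16x the trials -> ~4x smaller residual rms
  expect_equal(resid_sd[1] / resid_sd[2], 4, tolerance = 0.3)
})

test_that("zero-amplitude somatosensory source leaves pure noise with near-zero mean", {
  ph <- tiny_phantom()
  sep <- simulate_sep_run(ph, 5L, n20_moment = c(0, 0, 0), n_trials = 200,
                          sfreq = 500, leadfields = tiny_leadfields(),
                          seed = 41)
  pk <- sep$ground_truth$peak_sample
  avg <- rowMeans(vapply(pk, function(s) sep$data[, s],
                         numeric(nrow(sep$data))))
  raw_sd <- sd(sep$data[1, ])
  expect_lt(max(abs(avg[seq_len(nrow(ph$eeg$positions))])),
            raw_sd)  # shrunk well below single-sample noise
  # identical noise-free component, different noise under different seeds
  sep2 <- simulate_sep_run(ph, 5L, n20_moment = c(0, 0, 0), n_trials = 10,
                           sfreq = 500, leadfields = tiny_leadfields(),
                           seed = 42)
  sep3 <- simulate_sep_run(ph, 5L, n20_moment = c(0, 0, 0), n_trials = 10,
                           sfreq = 500, leadfields = tiny_leadfields(),
                           seed = 43)
  expect_false(identical(sep2$data, sep3$data))
})

test_that("somatosensory source outside the source space is rejected", {
  ph <- tiny_phantom()
  expect_error(simulate_sep_run(ph, nrow(ph$source_space$positions) + 1L,
                                leadfields = tiny_leadfields(), seed = 1),
               "geometry")
})
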