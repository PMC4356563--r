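test_that("band-pass keeps the passband and attenuates outside it", {
  sf <- 250
  t <- seq(0, 100, by = 1 / sf)
  # 50 Hz tone inside the 1-100 Hz band
  rec <- new_test_recording(rbind(sin(2 * pi * 50 * t)), sfreq = sf)
  out <- bandpass(rec, 1, 100)
  mid <- seq(2000, length(t) - 2000)  # avoid filter edges
  gain50 <- max(abs(out$data[1, mid])) / max(abs(rec$data[1, mid]))
  expect_lt(abs(gain50 - 1), 0.05)
  # 0.1 Hz tone far below the band: >= 20 dB down
  rec_lo <- new_test_recording(rbind(sin(2 * pi * 0.1 * t)), sfreq = sf)
  out_lo <- bandpass(rec_lo, 1, 100)
  gain_lo <- max(abs(out_lo$data[1, mid])) / max(abs(rec_lo$data[1, mid]))
  expect_lt(20 * log10(gain_lo), -20)
  # zero in, zero out
  z <- new_test_recording(matrix(0, 2, 1000), sfreq = sf)
  expect_equal(bandpass(z, 1, 100)$data, matrix(0, 2, 1000))
  expect_error(bandpass(z, 1, 200), "Nyquist")
  expect_error(bandpass(z, 0, 100), "Nyquist")
})

test_that("band-pass is zero-phase for an in-band tone", {
  sf <- 250
  t <- seq(0, 40, by = 1 / sf)
  x <- sin(2 * pi * 10 * t)
  out <- bandpass(new_test_recording(rbind(x), sfreq = sf), 1, 100)
  mid <- seq(2000, length(t) - 2000)
  lagmax <- which.max(ccf(out$data[1, mid], x[mid], lag.max = 5,
                          plot = FALSE)$acf) - 6
  expect_equal(lagmax, 0)
})

.embed_template <- function(tpl, times, n_ch, n_samp, scale = 1) {
  x <- matrix(0, n_ch, n_samp)
  L <- ncol(tpl)
  for (i in seq_along(times)) {
    idx <- times[i]:(times[i] + L - 1L)
    x[, idx] <- x[, idx] + scale[(i - 1) %% length(scale) + 1] * tpl
  }
  x
}

test_that("template matching recovers verbatim insertions exactly", {
  set.seed(31)
  tpl_data <- matrix(rnorm(4 * 51), 4, 51)
  starts <- seq(500, 9500, by = 1000)[1:10]
  rec <- new_test_recording(.embed_template(tpl_data, starts, 4, 10500),
                            sfreq = 250)
  tmpl <- structure(list(data = tpl_data, channels = 1:4, sfreq = 250,
                         half_window = 25), class = "spike_template")
  ev <- detect_spikes(rec, tmpl, threshold = 0.9)
  expect_length(ev, 10)
  centres <- starts + 25
  expect_true(all(abs(sort(ev) - centres) <= 1))
})

test_that("template matching is invariant to spike amplitude scaling", {
  set.seed(32)
  tpl_data <- matrix(rnorm(4 * 51), 4, 51)
  starts <- seq(500, 7500, by = 1000)[1:8]
  scales <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 0.6)
  rec <- new_test_recording(.embed_template(tpl_data, starts, 4, 8500,
                                            scale = scales), sfreq = 250)
  tmpl <- structure(list(data = tpl_data, channels = 1:4, sfreq = 250,
                         half_window = 25), class = "spike_template")
  ev <- detect_spikes(rec, tmpl, threshold = 0.8)
  expect_length(ev, 8)
})

test_that("white noise yields no detections at a stringent threshold", {
  set.seed(33)
  rec <- new_test_recording(matrix(rnorm(80 * 10000), 80, 10000), sfreq = 250)
  tpl_data <- matrix(rnorm(80 * 51), 80, 51)
  tmpl <- structure(list(data = tpl_data, channels = 1:80, sfreq = 250,
                         half_window = 25), class = "spike_template")
  expect_length(detect_spikes(rec, tmpl, threshold = 0.99), 0)
})

test_that("template construction averages the marked epochs", {
  set.seed(34)
  spike <- matrix(rnorm(3 * 41), 3, 41)
  starts <- c(300, 700, 1100, 1500, 1900, 2300, 2700, 3100, 3500, 3900)
  rec <- new_test_recording(.embed_template(spike, starts, 3, 4400),
                            sfreq = 250)
  centres <- starts + 20
  tm <- make_template(rec, centres, channels = 1:3, half_window_ms = 80)
  expect_equal(tm$data, spike, tolerance = 1e-12)   # identical spikes
  tm1 <- make_template(rec, centres[1], channels = 1:3, half_window_ms = 80)
  expect_equal(tm1$data, spike, tolerance = 1e-12)  # single mark
  expect_error(make_template(rec, integer(0), 1:3), "at least one")
})

test_that("template noise shrinks with the number of averaged seeds", {
  set.seed(35)
  sf <- 250
  spike <- matrix(0, 2, 51)
  n_rep <- 1000
  ratio <- replicate(20, {
    noise <- matrix(rnorm(2 * 6000), 2, 6000)
    rec <- new_test_recording(noise, sfreq = sf)
    centres <- seq(300, by = 500, length.out = 10)
    tm <- make_template(rec, centres, channels = 1:2, half_window_ms = 100)
    sd(tm$data) / sd(noise)
  })
  expect_equal(mean(ratio), 1 / sqrt(10), tolerance = 0.1)
})

test_that("SNR follows its defining power ratio", {
  sf <- 250
  n <- 101
  dat <- matrix(0, 4, n)
  ep <- new_test_epoch(dat, sfreq = sf)
  ib <- which(ep$times_ms >= -200 & ep$times_ms <= -70)
  set.seed(36)
  base <- matrix(rnorm(4 * length(ib)), 4, length(ib))
  dat[, ib] <- base
  it <- which.min(abs(ep$times_ms - 0))
  # amplitude at t equal to each channel's baseline SD -> SNR == 1
  dat[, it] <- apply(base, 1, sd)
  ep <- new_test_epoch(dat, sfreq = sf)
  s1 <- compute_snr(ep, 0, 1:4)
  expect_equal(s1$value,
               mean(apply(base, 1, sd)^2) / mean(apply(base, 1, var)),
               tolerance = 1e-12)
  # zero signal -> SNR 0
  dat0 <- dat; dat0[, it] <- 0
  expect_equal(compute_snr(new_test_epoch(dat0, sf), 0, 1:4)$value, 0)
  # doubling the instantaneous amplitude quadruples the SNR
  dat2 <- dat; dat2[, it] <- 2 * dat[, it]
  expect_equal(compute_snr(new_test_epoch(dat2, sf), 0, 1:4)$value,
               4 * s1$value, tolerance = 1e-12)
  expect_error(compute_snr(ep, 0, integer(0)), "empty channel set")
  expect_error(compute_snr(ep, 900, 1:4), "outside")
})

test_that("subaverage bookkeeping follows the drawing rules", {
  set.seed(37)
  epochs <- lapply(1:30, function(i)
    new_test_epoch(matrix(rnorm(2 * 101), 2, 101)))
  reals <- make_subaverages(epochs, group_sizes = c(1L, 5L, 10L),
                            n_realizations = 50L, seed = 4)
  av1 <- Filter(function(r) r$k == 1L, reals)
  expect_length(av1, 30)
  expect_equal(sort(vapply(av1, function(r) r$members, integer(1))), 1:30)
  for (k in c(5L, 10L)) {
    avk <- Filter(function(r) r$k == k, reals)
    expect_length(avk, 50)
    for (r in avk) {
      expect_length(r$members, k)
      expect_false(anyDuplicated(r$members) > 0)
      # averaged data equal the member mean exactly
      acc <- Reduce(`+`, lapply(r$members, function(m) epochs[[m]]$data))
      expect_equal(r$epoch$data, acc / k, tolerance = 1e-15)
    }
  }
  # byte-identical under a fixed seed
  reals2 <- make_subaverages(epochs, group_sizes = c(1L, 5L, 10L),
                             n_realizations = 50L, seed = 4)
  expect_identical(reals, reals2)
  expect_error(make_subaverages(epochs, group_sizes = 31L), "exceeds")
})

test_that("identical epochs average to themselves in every realization", {
  ep <- new_test_epoch(matrix(rnorm(2 * 101), 2, 101))
  epochs <- rep(list(ep), 12)
  reals <- make_subaverages(epochs, group_sizes = c(1L, 5L),
                            n_realizations = 10L, seed = 1)
  for (r in reals) expect_equal(r$epoch$data, ep$data, tolerance = 1e-14)
})

test_that("SNR gate applies a strictly-greater comparison", {
  sf <- 250
  mk <- function(snr_target) {
    dat <- matrix(0, 2, 101)
    ep <- new_test_epoch(dat, sf)
    ib <- which(ep$times_ms >= -200 & ep$times_ms <= -70)
    dat[1, ib] <- rep(c(-1, 1), length.out = length(ib))
    dat[2, ib] <- rep(c(1, -1), length.out = length(ib))
    v <- mean(apply(dat[, ib, drop = FALSE], 1, var))
    it <- which.min(abs(ep$times_ms - 0))
    dat[, it] <- sqrt(snr_target * v)
    list(group = "Av1", k = 1L, members = 1L, realization = 1L,
         epoch = new_test_epoch(dat, sf))
  }
  reals <- lapply(c(1, 2, 4, 8), mk)
  kept <- snr_gate(reals, 1:2, 0, threshold = 3)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) r$snr, numeric(1)), c(4, 8),
               tolerance = 1e-10)
  # SNR exactly at the threshold is excluded
  expect_length(snr_gate(list(mk(3)), 1:2, 0, threshold = 3), 0)
  # all above -> identity
  expect_length(snr_gate(reals, 1:2, 0, threshold = 0.5), 4)
  expect_error(snr_gate(reals, 1:2, 0, threshold = -1), "positive")
})

test_that("averaging k identical-signal epochs scales the power SNR by about k", {
  set.seed(38)
  sf <- 250
  sig <- matrix(0, 1, 101)
  ep0 <- new_test_epoch(sig, sf)
  it <- which.min(abs(ep0$times_ms - 0))
  sig[, it] <- 5
  k <- 8L
  snr1 <- numeric(1000); snrk <- numeric(1000)
  for (r in 1:1000) {
    mk_ep <- function() new_test_epoch(sig + matrix(rnorm(101), 1, 101), sf)
    e1 <- mk_ep()
    snr1[r] <- compute_snr(e1, 0, 1)$value
    avg <- Reduce(`+`, lapply(seq_len(k), function(i) mk_ep()$data)) / k
    snrk[r] <- compute_snr(new_test_epoch(avg, sf), 0, 1)$value
  }
  expect_equal(mean(snrk) / mean(snr1), k, tolerance = 0.15)
})

test_that("varying spike amplitudes break the proportional SNR growth", {
  set.seed(39)
  sf <- 250
  it0 <- 51L
  k <- 8L
  mk_ep <- function(a) {
    sig <- matrix(0, 1, 101); sig[, it0] <- a
    new_test_epoch(sig + matrix(rnorm(101), 1, 101), sf)
  }
  snr1 <- numeric(500); snrk <- numeric(500)
  for (r in 1:500) {
    amps <- rlnorm(k, meanlog = log(2), sdlog = 0.8)
    eps <- lapply(amps, mk_ep)
    snr1[r] <- compute_snr(eps[[1]], 0, 1)$value
    avg <- Reduce(`+`, lapply(eps, function(e) e$data)) / k
    snrk[r] <- compute_snr(new_test_epoch(avg, sf), 0, 1)$value
  }
  # the mean-of-amplitudes effect pushes the growth well below k
  expect_lt(mean(snrk) / mean(snr1), 0.85 * k)
})
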