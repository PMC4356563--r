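# Shared fixtures, built lazily and memoised across test files.
.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small phantom for fast unit tests.
tiny_phantom <- function() .memo("tiny_ph",
  make_phantom(n_eeg = 40L, n_meg = 80L, spacing_mm = 14,
               patch_radius_mm = 14, seed = 42L))

tiny_leadfields <- function() .memo("tiny_lf", {
  ph <- tiny_phantom()
  list(eeg = build_leadfield(ph$source_space, ph$eeg, ph$head),
       meg = build_leadfield(ph$source_space, ph$meg, ph$head))
})

# Study-scale phantom (full sensor counts) for the acceptance suite.
std_phantom <- function() .memo("std_ph", make_phantom(spacing_mm = 10, seed = 1L))

std_leadfields <- function() .memo("std_lf", {
  ph <- std_phantom()
  list(eeg = build_leadfield(ph$source_space, ph$eeg, ph$head),
       meg = build_leadfield(ph$source_space, ph$meg, ph$head))
})

# Raw recording object without running a simulator.
new_test_recording <- function(data, sfreq = 250,
                               modality = rep("EEG", nrow(data))) {
  structure(list(
    data = data, sfreq = sfreq,
    channels = data.frame(name = sprintf("CH%03d", seq_len(nrow(data))),
                          modality = modality,
                          hemisphere = "left",
                          stringsAsFactors = FALSE),
    ground_truth = NULL), class = "emeg_recording")
}

# Epoch object from a plain matrix, time 0 at the window centre.
new_test_epoch <- function(data, sfreq = 250) {
  n <- ncol(data)
  ctr <- (n - 1) %/% 2
  structure(list(data = data,
                 times_ms = (seq_len(n) - 1 - ctr) / sfreq * 1000,
                 sfreq = sfreq, channels = NULL, members = 1L),
            class = "epoch")
}

# Independent homogeneous-sphere EEG oracle: closed form derived from the
# Legendre generating function (no series truncation). Average-referenced.
hom_sphere_potential <- function(dip_pos, m_nAm, electrodes, sigma, R_mm) {
  R <- R_mm * 1e-3
  b <- sqrt(sum(dip_pos^2)) * 1e-3
  m <- m_nAm * 1e-9
  bhat <- if (b > 0) dip_pos / sqrt(sum(dip_pos^2)) else c(0, 0, 1)
  el <- rbind(electrodes)
  ehat <- el / sqrt(rowSums(el^2))
  u <- pmin(1, pmax(-1, as.numeric(ehat %*% bhat)))
  x <- b / R
  D <- sqrt(1 - 2 * x * u + x^2)
  S1 <- 2 * (u - x) / D^3 + (1 - D) / (x * D)
  S2 <- 2 / D^3 + (1 + D) / (D * (1 - x * u + D))
  mr <- sum(m * bhat)
  mt <- m - mr * bhat
  v <- (mr * S1 + as.numeric(ehat %*% mt) * S2) / (4 * pi * sigma * R^2)
  (v - mean(v)) * 1e6
}
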