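#' @keywords internal
.unit_rows <- function(m) m / sqrt(rowSums(m^2))

# Deterministic quasi-uniform points on a spherical cap z/r >= zmin,
# Fibonacci lattice.
.fibonacci_cap <- function(n, radius, zmin = -1) {
  i <- seq_len(n) - 0.5
  z <- zmin + (1 - zmin) * i / n
  z <- rev(z)                      # start near vertex for stable ordering
  phi_g <- pi * (3 - sqrt(5))      # golden angle
  th <- phi_g * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = radius * rho * cos(th),
        y = radius * rho * sin(th),
        z = radius * z)
}

.hemisphere_label <- function(x, eps = 1e-9) {
  ifelse(x < -eps, "left", ifelse(x > eps, "right", "midline"))
}

#' Build the digital phantom
#'
#' Constructs the full synthetic measurement geometry: a cortical-band source
#' space on a cubic grid, EEG electrodes on the scalp shell, MEG magnetometers
#' on a helmet sphere outside the scalp, a stereo-EEG contact table with
#' activity labels, and a two-patch irritative-zone specification (a deep
#' mesial onset patch and a lateral temporal-pole propagation patch).
#'
#' All coordinates are head-centred RAS in millimetres with the origin at the
#' sphere centre; the left hemisphere is x < 0.
#'
#' @param head A [head_model()].
#' @param n_eeg,n_meg Number of EEG electrodes (on the scalp shell) and MEG
#'   sensors (radially oriented point magnetometers on a helmet sphere
#'   `meg_offset_mm` outside the scalp).
#' @param spacing_mm Source grid spacing in mm.
#' @param source_band_mm Length-2, inner/outer radius of the source shell band
#'   in mm; must stay strictly inside the innermost head shell.
#' @param meg_offset_mm Helmet sphere clearance above the scalp in mm.
#' @param deep_seed,lateral_seed Length-3 seed points (mm) of the two
#'   irritative-zone patches; the deep seed must be farther from the scalp
#'   than the lateral one.
#' @param patch_radius_mm Patch radius around each seed in mm.
#' @param propagation_delay_ms Deep-to-lateral propagation delay.
#' @param origin_jitter_mm Per-spike stochastic spread of the spike origin
#'   around the patch seed.
#' @param amplitude_median_nAm,amplitude_sdlog Log-normal single-spike
#'   amplitude law (median in nAm, log-scale SD).
#' @param n_inactive_contacts Number of additional inactive sEEG contacts.
#' @param seed Integer RNG seed; the phantom is a pure function of its
#'   arguments.
#' @return An object of class `emeg_phantom` with elements `head`,
#'   `source_space`, `eeg`, `meg`, `contacts`, `zone`.
#' @export
make_phantom <- function(head = head_model(),
                         n_eeg = 80L, n_meg = 275L,
                         spacing_mm = 8,
                         source_band_mm = c(35, 76),
                         meg_offset_mm = 25,
                         deep_seed = c(-32, 8, -14),
                         lateral_seed = c(-64, 28, -18),
                         patch_radius_mm = 12,
                         propagation_delay_ms = 30,
                         origin_jitter_mm = 6,
                         amplitude_median_nAm = 50,
                         amplitude_sdlog = 0.4,
                         n_inactive_contacts = 10L,
                         seed = 1L) {
  stopifnot(inherits(head, "head_model"))
  if (source_band_mm[2] >= head$radii_mm[1])
    stop("source band must lie strictly inside the innermost shell")
  if (spacing_mm <= 0) stop("spacing must be positive")
  set.seed(as.integer(seed))

  ## source space: cubic grid restricted to the shell band
  r_out <- source_band_mm[2]
  ax <- seq(-r_out, r_out, by = spacing_mm)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rr <- sqrt(rowSums(g^2))
  keep <- rr >= source_band_mm[1] & rr <= r_out
  pos <- g[keep, , drop = FALSE]
  rownames(pos) <- NULL
  # nominal cortical orientation: radial direction blended with a smooth
  # pseudo-random tangential component (real cortex is neither purely radial
  # nor random; the blend keeps both EEG- and MEG-visible moment components)
  rad <- .unit_rows(pos)
  rnd <- matrix(stats::rnorm(3 * nrow(pos)), ncol = 3)
  rnd <- rnd - rad * rowSums(rnd * rad)       # tangential part
  rnd <- .unit_rows(rnd)
  normals <- .unit_rows(0.7 * rad + 0.714 * rnd)
  source_space <- structure(list(positions = pos, normals = normals,
                                 spacing_mm = spacing_mm,
                                 band_mm = source_band_mm),
                            class = "source_space")

  ## sensors
  eeg_pos <- .fibonacci_cap(n_eeg, head$radii_mm[4], zmin = -0.35)
  eeg <- structure(list(kind = "EEG", positions = eeg_pos, orientations = NULL,
                        names = sprintf("EEG%03d", seq_len(n_eeg)),
                        hemisphere = .hemisphere_label(eeg_pos[, 1])),
                   class = "sensor_array")
  meg_pos <- .fibonacci_cap(n_meg, head$radii_mm[4] + meg_offset_mm, zmin = -0.2)
  meg <- structure(list(kind = "MEG", positions = meg_pos,
                        orientations = .unit_rows(meg_pos),
                        names = sprintf("MEG%03d", seq_len(n_meg)),
                        hemisphere = .hemisphere_label(meg_pos[, 1])),
                   class = "sensor_array")

  ## irritative zone: deep (seizure-onset analogue) and lateral
  ## (temporal-pole analogue) patches
  d_deep <- sqrt(colSums((t(pos) - deep_seed)^2))
  d_lat <- sqrt(colSums((t(pos) - lateral_seed)^2))
  deep_patch <- which(d_deep <= patch_radius_mm)
  lateral_patch <- setdiff(which(d_lat <= patch_radius_mm), deep_patch)
  if (length(deep_patch) == 0L || length(lateral_patch) == 0L)
    stop("patch request yields no sources; enlarge patch_radius_mm or refine spacing")
  scalp_r <- head$radii_mm[4]
  depth_deep <- scalp_r - mean(sqrt(rowSums(pos[deep_patch, , drop = FALSE]^2)))
  depth_lat <- scalp_r - mean(sqrt(rowSums(pos[lateral_patch, , drop = FALSE]^2)))
  if (depth_deep <= depth_lat)
    stop("deep patch is not deeper than lateral patch; adjust seeds")
  zone <- structure(list(deep_patch = deep_patch, lateral_patch = lateral_patch,
                         deep_seed = deep_seed, lateral_seed = lateral_seed,
                         propagation_delay_ms = propagation_delay_ms,
                         origin_jitter_mm = origin_jitter_mm,
                         amplitude_median_nAm = amplitude_median_nAm,
                         amplitude_sdlog = amplitude_sdlog),
                    class = "irritative_zone")

  contacts <- .make_contacts(pos, deep_seed, lateral_seed,
                             n_inactive = n_inactive_contacts,
                             r_max = source_band_mm[2])

  structure(list(head = head, source_space = source_space,
                 eeg = eeg, meg = meg, contacts = contacts, zone = zone,
                 seed = as.integer(seed)),
            class = "emeg_phantom")
}

# sEEG contact table: 5 depth electrodes carrying the 24 interictal contacts
# (8 of them, on electrodes A and HA, also ictal) plus inactive electrodes
# farther from the irritative zone. Electrodes are straight contact rows
# entering from lateral-left, mimicking clinical implantation.
.make_contacts <- function(src_pos, deep_seed, lateral_seed, n_inactive,
                           r_max) {
  electrode <- function(name, tip, dir, n, pitch = 4, label) {
    dir <- dir / sqrt(sum(dir^2))
    p <- t(sapply(seq_len(n) - 1, function(k) tip + k * pitch * dir))
    data.frame(electrode_name = name, contact_number = seq_len(n),
               x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3],
               label = label, stringsAsFactors = FALSE)
  }
  out_dir <- c(-1, 0.25, -0.15)  # mesial-to-lateral exit direction
  tab <- rbind(
    # amygdala analogue: contacts 1-3 ictal, 4-5 interictal
    electrode("A",  deep_seed + c(0, 4, 2),  out_dir, 5,
              label = c(rep("ictal", 3), rep("interictal", 2))),
    # hippocampus-anterior analogue: 1-5 ictal, 6-10 interictal
    electrode("HA", deep_seed + c(0, -4, -4), out_dir, 10,
              label = c(rep("ictal", 5), rep("interictal", 5))),
    # hippocampus-posterior analogue: interictal
    electrode("HP", deep_seed + c(2, -16, -6), out_dir, 4, label = "interictal"),
    # temporal-anterior analogue near the lateral patch: interictal
    electrode("TA", lateral_seed + c(6, 6, 2), c(-1, 0.4, 0), 3,
              label = "interictal"),
    # entorhinal analogue between the patches: interictal
    electrode("E",  (deep_seed + lateral_seed) / 2 + c(0, 0, -6), out_dir, 2,
              label = "interictal")
  )
  if (n_inactive > 0L) {
    n_in <- ceiling(n_inactive / 2)
    tab <- rbind(tab,
      electrode("F", c(-30, 52, 10), c(-1, 0.6, 0.3), n_in, label = "inactive"),
      electrode("P", c(-34, -40, 18), c(-1, -0.4, 0.4),
                n_inactive - n_in, label = "inactive"))
  }
  rr <- sqrt(tab$x_mm^2 + tab$y_mm^2 + tab$z_mm^2)
  if (any(rr >= r_max + 3))
    tab <- tab[rr < r_max + 3, ]
  rownames(tab) <- NULL
  class(tab) <- c("seeg_contacts", "data.frame")
  tab
}

#' @export
print.emeg_phantom <- function(x, ...) {
  cat("Digital EEG/MEG phantom\n")
  print(x$head)
  cat(sprintf("  source space: %d positions, %.3g mm spacing, band %g-%g mm\n",
              nrow(x$source_space$positions), x$source_space$spacing_mm,
              x$source_space$band_mm[1], x$source_space$band_mm[2]))
  cat(sprintf("  sensors: %d EEG, %d MEG (%d left-hemisphere MEG)\n",
              nrow(x$eeg$positions), nrow(x$meg$positions),
              sum(x$meg$hemisphere == "left")))
  cat(sprintf("  sEEG contacts: %d (%d interictal-measuring, of which %d ictal)\n",
              nrow(x$contacts),
              sum(x$contacts$label != "inactive"),
              sum(x$contacts$label == "ictal")))
  cat(sprintf("  irritative zone: %d deep + %d lateral sources, delay %g ms\n",
              length(x$zone$deep_patch), length(x$zone$lateral_patch),
              x$zone$propagation_delay_ms))
  invisible(x)
}

#' @export
plot.emeg_phantom <- function(x, ...) {
  pos <- x$source_space$positions
  graphics::plot(pos[, 1], pos[, 3], pch = ".", col = "grey70", asp = 1,
                 xlab = "x (mm)", ylab = "z (mm)",
                 main = "Phantom geometry (coronal projection)", ...)
  graphics::points(x$eeg$positions[, 1], x$eeg$positions[, 3], pch = 1, col = "blue")
  graphics::points(x$meg$positions[, 1], x$meg$positions[, 3], pch = 2, col = "darkgreen")
  cc <- x$contacts
  cols <- c(ictal = "red", interictal = "orange", inactive = "grey40")
  graphics::points(cc$x_mm, cc$z_mm, pch = 19, col = cols[cc$label])
  invisible(x)
}

#' Contact positions as a matrix
#' @param contacts A `seeg_contacts` table.
#' @return n x 3 matrix of positions in mm.
#' @export
contact_positions <- function(contacts) {
  as.matrix(contacts[, c("x_mm", "y_mm", "z_mm")])
}
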