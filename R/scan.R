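# Vectorized per-source 3x3 machinery ---------------------------------------
# For every source i the local gain G_i (m x 3) yields the normal matrix
# N_i = G_i' W^2 G_i and the projection h_i = G_i' W^2 y. The scan needs, per
# source, u = (N + lambda I)^{-1} h and the explained power 2 h'u - u' N u
# (which reduces to h'u when lambda = 0). All six N entries are held as
# vectors over sources and the 3x3 inverse is the vectorized adjugate.

.gram_entries <- function(lf, w = NULL) {
  Gx <- lf$Gx; Gy <- lf$Gy; Gz <- lf$Gz
  if (!is.null(w)) {
    Gx <- Gx * w; Gy <- Gy * w; Gz <- Gz * w
  }
  list(
    xx = colSums(Gx * Gx), yy = colSums(Gy * Gy), zz = colSums(Gz * Gz),
    xy = colSums(Gx * Gy), xz = colSums(Gx * Gz), yz = colSums(Gy * Gz),
    Gx = Gx, Gy = Gy, Gz = Gz)
}

# Solve (N + lambda I) u = h per source, vectorized; returns u components and
# a rank-deficiency flag per source (handled by eigenvalue pseudo-inverse).
.solve3 <- function(N, lam, h1, h2, h3, pinv_tol = 1e-10) {
  a <- N$xx + lam; b <- N$xy; c3 <- N$xz
  d <- N$yy + lam; e <- N$yz; f <- N$zz + lam
  A11 <- d * f - e * e; A12 <- c3 * e - b * f; A13 <- b * e - c3 * d
  A22 <- a * f - c3 * c3; A23 <- b * c3 - a * e
  A33 <- a * d - b * b
  det <- a * A11 + b * A12 + c3 * A13
  scale <- pmax(a, d, f)
  # the determinant of an exactly singular normal matrix computes to about
  # eps * scale^3, so the rank flag must sit well above that floor; flagged
  # sources are re-solved with an eigenvalue pseudo-inverse at pinv_tol
  bad <- !is.finite(det) | abs(det) <= 1e-8 * scale^3
  det[bad] <- 1
  u1 <- (A11 * h1 + A12 * h2 + A13 * h3) / det
  u2 <- (A12 * h1 + A22 * h2 + A23 * h3) / det
  u3 <- (A13 * h1 + A23 * h2 + A33 * h3) / det
  if (any(bad)) {
    for (i in which(bad)) {
      M <- matrix(c(a[i], b[i], c3[i], b[i], d[i], e[i], c3[i], e[i], f[i]), 3, 3)
      eg <- eigen(M, symmetric = TRUE)
      keep <- eg$values > pinv_tol * max(eg$values, 0)
      inv <- if (any(keep))
        eg$vectors[, keep, drop = FALSE] %*%
          (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
      else matrix(0, 3, 3)
      u <- inv %*% c(h1[i], h2[i], h3[i])
      u1[i] <- u[1]; u2[i] <- u[2]; u3[i] <- u[3]
    }
  }
  list(u1 = u1, u2 = u2, u3 = u3, deficient = bad)
}

#' Single-dipole deviation scan
#'
#' Fits, independently at every source-space position, a single dipole moment
#' to the data vector by (optionally Tikhonov-regularized) least squares on
#' the local three-column gain, and reports the goodness of fit
#' `GOF = 1 - ||y - G m||^2 / ||y||^2` for every position. The scan result is
#' the position with the highest GOF (lowest index on ties); its moment is
#' re-solved without regularization.
#'
#' @param data Numeric sensor data vector (one time point), matching the
#'   leadfield's row order.
#' @param leadfield A [build_leadfield()] result, or a fused leadfield from
#'   [emeg_fuse()].
#' @param regularization `"none"` or `"tikhonov"`; the latter adds
#'   `lambda_rel * trace(N_i)` to the local normal matrix (used for MEG to
#'   stabilize the near-silent quasi-radial direction).
#' @param lambda_rel Relative Tikhonov weight.
#' @param weights Optional per-channel weights applied to data and leadfield
#'   rows (used internally by the fused scan).
#' @param modality,time_ms,snr Optional annotations carried into the result.
#' @return An object of class `deviation_scan` with `gof_map`, `best_index`,
#'   `location`, `moment` (nAm), `gof`, `residual_variance`, `orientation`,
#'   `strength`, and annotations.
#' @export
deviation_scan <- function(data, leadfield,
                           regularization = c("none", "tikhonov"),
                           lambda_rel = 1e-3, weights = NULL,
                           modality = leadfield$kind, time_ms = NA_real_,
                           snr = NA_real_) {
  regularization <- match.arg(regularization)
  y <- as.numeric(data)
  if (!is.null(weights)) y <- y * weights
  ynorm2 <- sum(y^2)
  if (ynorm2 == 0) stop("zero data vector: GOF undefined")
  N <- .gram_entries(leadfield, weights)
  h1 <- as.numeric(crossprod(N$Gx, y))
  h2 <- as.numeric(crossprod(N$Gy, y))
  h3 <- as.numeric(crossprod(N$Gz, y))
  lam <- if (regularization == "tikhonov")
    lambda_rel * (N$xx + N$yy + N$zz) else 0
  sol <- .solve3(N, lam, h1, h2, h3)
  expl <- 2 * (h1 * sol$u1 + h2 * sol$u2 + h3 * sol$u3) -
    (N$xx * sol$u1^2 + N$yy * sol$u2^2 + N$zz * sol$u3^2 +
       2 * (N$xy * sol$u1 * sol$u2 + N$xz * sol$u1 * sol$u3 +
              N$yz * sol$u2 * sol$u3))
  gof_map <- expl / ynorm2
  best <- which.max(gof_map)           # ties: lowest index
  # winning moment re-solved without regularization (at the winner only)
  Nb <- lapply(N[c("xx", "yy", "zz", "xy", "xz", "yz")], `[`, best)
  fin <- .solve3(Nb, 0, h1[best], h2[best], h3[best])
  moment <- c(fin$u1, fin$u2, fin$u3)
  strength <- sqrt(sum(moment^2))
  structure(list(
    gof_map = gof_map,
    best_index = best,
    location = leadfield$source_positions[best, ],
    moment = moment,
    orientation = if (strength > 0) moment / strength else c(NA, NA, NA),
    strength = strength,
    gof = gof_map[best],
    residual_variance = 1 - gof_map[best],
    rank_deficient = which(sol$deficient),
    regularization = regularization, lambda_rel = lambda_rel,
    modality = modality, time_ms = time_ms, snr = snr,
    n_sources = leadfield$n_sources), class = "deviation_scan")
}

#' @export
print.deviation_scan <- function(x, ...) {
  cat(sprintf("Deviation scan (%s%s): best source %d of %d\n",
              x$modality,
              if (is.finite(x$time_ms)) sprintf(", t = %g ms", x$time_ms) else "",
              x$best_index, x$n_sources))
  cat(sprintf("  location (mm): %s\n", paste(round(x$location, 1), collapse = ", ")))
  cat(sprintf("  GOF %.4f (residual variance %.4f), strength %.3g nAm\n",
              x$gof, x$residual_variance, x$strength))
  invisible(x)
}

#' @export
summary.deviation_scan <- function(object, ...) {
  cat(sprintf("Deviation scan over %d sources (%s regularization)\n",
              object$n_sources, object$regularization))
  print(object)
  q <- stats::quantile(object$gof_map, c(0, 0.5, 0.9, 1))
  cat("  GOF map quantiles (0/50/90/100%):",
      paste(signif(q, 3), collapse = " "), "\n")
  if (length(object$rank_deficient))
    cat(sprintf("  %d rank-deficient local fits (pseudo-inverse used)\n",
                length(object$rank_deficient)))
  invisible(object)
}

#' @export
coef.deviation_scan <- function(object, ...) object$moment

#' @export
plot.deviation_scan <- function(x, source_positions = NULL, ...) {
  graphics::plot(x$gof_map, type = "h", col = "grey60",
                 xlab = "source index", ylab = "GOF",
                 main = sprintf("Deviation scan GOF map (%s)", x$modality), ...)
  graphics::points(x$best_index, x$gof, col = "red", pch = 19)
  invisible(x)
}

#' Left-hemisphere MEG channel subset
#'
#' Channels with sensor x-coordinate strictly negative (head-frame RAS left);
#' midline sensors (x = 0) are excluded.
#'
#' @param sensors A `sensor_array`.
#' @return Integer channel indices; warns if empty.
#' @export
select_meg_left <- function(sensors) {
  idx <- which(sensors$positions[, 1] < 0)
  if (length(idx) == 0L) warning("no left-hemisphere sensors found")
  idx
}

#' Fuse EEG and MEG into a unitless common space
#'
#' Divides every channel (data row and leadfield row) by that channel's
#' baseline noise SD, making both modalities dimensionless with unit baseline
#' variance, then stacks EEG rows above the selected MEG rows. Scanning the
#' fused data weighs each channel by its amplitude SNR.
#'
#' @param eeg_epoch,meg_epoch `epoch` objects restricted to one modality each
#'   (channels x samples matrices with `times_ms`).
#' @param eeg_leadfield,meg_leadfield Matching leadfields; the MEG leadfield
#'   must already be restricted to the same channel subset as `meg_epoch`.
#' @param baseline_ms Baseline window for the noise SD.
#' @return A list of class `fused_emeg`: `data` (fused channels x samples),
#'   `times_ms`, `leadfield` (a fused leadfield usable by
#'   [deviation_scan()]), `weights`, `dropped` (zero-SD channels).
#' @export
emeg_fuse <- function(eeg_epoch, meg_epoch, eeg_leadfield, meg_leadfield,
                      baseline_ms = c(-200, -70)) {
  if (!isTRUE(all.equal(eeg_epoch$times_ms, meg_epoch$times_ms)))
    stop("EEG and MEG epochs must share a common time base")
  ib <- which(eeg_epoch$times_ms >= baseline_ms[1] &
                eeg_epoch$times_ms <= baseline_ms[2])
  if (length(ib) < 2L) stop("baseline window outside the epochs")
  sd_eeg <- apply(eeg_epoch$data[, ib, drop = FALSE], 1, stats::sd)
  sd_meg <- apply(meg_epoch$data[, ib, drop = FALSE], 1, stats::sd)
  drop_e <- which(sd_eeg == 0); drop_m <- which(sd_meg == 0)
  if (length(drop_e) || length(drop_m))
    warning(sprintf("dropping %d channel(s) with zero baseline SD",
                    length(drop_e) + length(drop_m)))
  ke <- setdiff(seq_along(sd_eeg), drop_e)
  km <- setdiff(seq_along(sd_meg), drop_m)
  w <- c(1 / sd_eeg[ke], 1 / sd_meg[km])
  data <- rbind(eeg_epoch$data[ke, , drop = FALSE] / sd_eeg[ke],
                meg_epoch$data[km, , drop = FALSE] / sd_meg[km])
  lf <- list(
    Gx = rbind(eeg_leadfield$Gx[ke, , drop = FALSE] / sd_eeg[ke],
               meg_leadfield$Gx[km, , drop = FALSE] / sd_meg[km]),
    Gy = rbind(eeg_leadfield$Gy[ke, , drop = FALSE] / sd_eeg[ke],
               meg_leadfield$Gy[km, , drop = FALSE] / sd_meg[km]),
    Gz = rbind(eeg_leadfield$Gz[ke, , drop = FALSE] / sd_eeg[ke],
               meg_leadfield$Gz[km, , drop = FALSE] / sd_meg[km]),
    kind = "EMEG",
    n_sources = eeg_leadfield$n_sources,
    source_positions = eeg_leadfield$source_positions)
  lf$gain <- NULL
  class(lf) <- "leadfield"
  structure(list(data = data, times_ms = eeg_epoch$times_ms, leadfield = lf,
                 weights = w, dropped = list(eeg = drop_e, meg = drop_m)),
            class = "fused_emeg")
}

#' Restrict a leadfield to a channel subset
#' @param leadfield A `leadfield`.
#' @param channels Integer/logical row subset.
#' @return The restricted leadfield.
#' @export
subset_leadfield <- function(leadfield, channels) {
  leadfield$Gx <- leadfield$Gx[channels, , drop = FALSE]
  leadfield$Gy <- leadfield$Gy[channels, , drop = FALSE]
  leadfield$Gz <- leadfield$Gz[channels, , drop = FALSE]
  if (!is.null(leadfield$gain))
    leadfield$gain <- leadfield$gain[channels, , drop = FALSE]
  if (!is.null(leadfield$channel_names))
    leadfield$channel_names <- leadfield$channel_names[channels]
  leadfield
}

#' Skull conductivity calibration from somatosensory responses
#'
#' Calibration loop: (1) the averaged somatosensory MEG topography is
#' deviation-scanned once — the MEG forward solution does not depend on
#' conductivity, so this fixes the source location; (2) for each candidate
#' skull conductivity the EEG gain at that fixed location is recomputed and
#' the EEG GOF of the averaged somatosensory potential is evaluated; (3) the
#' candidate with the highest EEG GOF is returned.
#'
#' @param sep_eeg Averaged EEG topography at the component latency (numeric
#'   vector over EEG channels).
#' @param sef_meg Averaged MEG topography at the same latency (numeric vector
#'   over the MEG channels of `meg_leadfield`).
#' @param phantom The [make_phantom()] geometry.
#' @param sigma_grid Strictly increasing candidate skull conductivities (S/m).
#' @param eeg_leadfield,meg_leadfield Leadfields under the phantom's nominal
#'   head model (the MEG one is conductivity-independent; the EEG one is only
#'   used for consistency checks).
#' @return An object of class `skull_calibration`: `sigma_grid`, `score`
#'   (EEG GOF per candidate), `best_sigma`, `meg_scan` (the location-fixing
#'   scan), `location_index`.
#' @export
calibrate_skull <- function(sep_eeg, sef_meg, phantom, sigma_grid,
                            meg_leadfield, eeg_leadfield = NULL) {
  if (length(sigma_grid) == 0L) stop("empty conductivity grid (configuration error)")
  if (is.unsorted(sigma_grid, strictly = TRUE))
    stop("sigma_grid must be strictly increasing")
  meg_scan <- deviation_scan(sef_meg, meg_leadfield,
                             regularization = "tikhonov",
                             modality = "MEG")
  if (meg_scan$gof < 0.5)
    warning(sprintf("MEG calibration scan GOF %.2f < 0.5: calibration unreliable",
                    meg_scan$gof))
  loc_idx <- meg_scan$best_index
  src <- phantom$source_space$positions[loc_idx, , drop = FALSE]
  y <- as.numeric(sep_eeg)
  ynorm2 <- sum(y^2)
  if (ynorm2 == 0) stop("zero EEG data vector: GOF undefined")
  score <- vapply(sigma_grid, function(sig) {
    hd <- head_model(radii_mm = phantom$head$radii_mm,
                     conductivities = replace(phantom$head$conductivities, 3, sig))
    G <- cbind(eeg_sphere_potential(src[1, ], c(1, 0, 0), phantom$eeg$positions, hd),
               eeg_sphere_potential(src[1, ], c(0, 1, 0), phantom$eeg$positions, hd),
               eeg_sphere_potential(src[1, ], c(0, 0, 1), phantom$eeg$positions, hd))
    m <- qr.solve(G, y)
    1 - sum((y - G %*% m)^2) / ynorm2
  }, numeric(1))
  best <- which.max(score)
  structure(list(sigma_grid = sigma_grid, score = score,
                 best_sigma = sigma_grid[best], best_index = best,
                 meg_scan = meg_scan, location_index = loc_idx),
            class = "skull_calibration")
}

#' @export
print.skull_calibration <- function(x, ...) {
  cat("Skull conductivity calibration\n")
  cat(sprintf("  location fixed by MEG scan at source %d (GOF %.3f)\n",
              x$location_index, x$meg_scan$gof))
  cat(sprintf("  best sigma_skull = %g S/m (EEG GOF %.4f) on a %d-point grid\n",
              x$best_sigma, x$score[x$best_index], length(x$sigma_grid)))
  invisible(x)
}

#' @export
plot.skull_calibration <- function(x, ...) {
  graphics::plot(x$sigma_grid, x$score, type = "b", log = "x",
                 xlab = "skull conductivity (S/m)", ylab = "EEG GOF",
                 main = "Skull conductivity calibration", ...)
  graphics::abline(v = x$best_sigma, lty = 2, col = "red")
  invisible(x)
}
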