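#' Four-shell head model specification
#'
#' Defines the concentric-sphere volume conductor used by the analytic EEG and
#' MEG forward solutions: four shells (brain, CSF, skull, scalp) with strictly
#' increasing radii and per-shell isotropic conductivities.
#'
#' @param radii_mm Numeric length-4, outer radius of each shell in mm, ordered
#'   brain < CSF < skull < scalp. Defaults 79/82/87/92 mm.
#' @param conductivities Numeric length-4, conductivity of each shell in S/m
#'   (brain, CSF, skull, scalp). Defaults 0.33, 1.79, 0.0024, 0.43; the skull
#'   value is the quantity targeted by [calibrate_skull()].
#' @return An object of class `head_model`.
#' @export
head_model <- function(radii_mm = c(brain = 79, csf = 82, skull = 87, scalp = 92),
                       conductivities = c(brain = 0.33, csf = 1.79,
                                          skull = 0.0024, scalp = 0.43)) {
  radii_mm <- as.numeric(radii_mm)
  conductivities <- as.numeric(conductivities)
  if (length(radii_mm) != 4L || length(conductivities) != 4L)
    stop("head_model requires exactly four shells")
  if (any(diff(radii_mm) <= 0))
    stop("shell radii must be strictly increasing")
  if (any(!is.finite(radii_mm)) || any(radii_mm <= 0))
    stop("shell radii must be positive and finite")
  if (any(!is.finite(conductivities)) || any(conductivities <= 0))
    stop("conductivities must be positive and finite")
  structure(list(radii_mm = radii_mm, conductivities = conductivities),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("4-shell spherical head model\n")
  cat(sprintf("  radii (mm):          %s\n", paste(x$radii_mm, collapse = " / ")))
  cat(sprintf("  conductivity (S/m):  %s\n",
              paste(signif(x$conductivities, 4), collapse = " / ")))
  invisible(x)
}

# Radial transfer coefficients for the 4-shell series, one per Legendre degree.
# Scaled variables s = r/R_scalp keep powers s^n and s^-(n+1) in range for
# n up to the 200-term cap. For each degree the 7 unknown shell coefficients
# (A1; A2,B2; A3,B3; A4,B4) are solved from interface continuity of potential
# and radial current plus the insulating outer boundary, with the primary
# (source) coefficient in shell 1 normalized to 1. The returned value is the
# scalp-surface potential coefficient; it equals (2n+1)/n when all
# conductivities coincide.
.shell_transfer <- function(head, n_max = 200L) {
  s <- head$radii_mm / head$radii_mm[4]
  sig <- head$conductivities
  phi <- numeric(n_max)
  for (n in seq_len(n_max)) {
    A <- matrix(0, 7, 7)
    b <- numeric(7)
    # unknown order: A1, A2, B2, A3, B3, A4, B4
    for (k in 1:3) {
      sk <- s[k]
      pw_n <- sk^n; pw_m <- sk^(-(n + 1))
      dn <- n * sk^(n - 1); dm <- -(n + 1) * sk^(-(n + 2))
      r1 <- 2 * k - 1; r2 <- 2 * k
      ia <- if (k == 1) 1L else 2L * (k - 1L)          # index of A_k
      ib <- if (k == 1) NA_integer_ else 2L * k - 1L   # index of B_k
      ja <- 2L * k; jb <- 2L * k + 1L                  # indices of A_{k+1}, B_{k+1}
      # potential continuity
      A[r1, ia] <- pw_n
      if (!is.na(ib)) A[r1, ib] <- pw_m
      A[r1, ja] <- -pw_n; A[r1, jb] <- -pw_m
      # radial current continuity
      A[r2, ia] <- sig[k] * dn
      if (!is.na(ib)) A[r2, ib] <- sig[k] * dm
      A[r2, ja] <- -sig[k + 1] * dn; A[r2, jb] <- -sig[k + 1] * dm
      if (k == 1) {  # primary source term B1 = 1 moved to the RHS
        b[r1] <- -pw_m
        b[r2] <- -sig[1] * dm
      }
    }
    # insulating scalp boundary at s = 1
    A[7, 6] <- n; A[7, 7] <- -(n + 1)
    # equilibrate rows and columns (per-shell nondimensionalization) so the
    # s^n / s^-(n+1) spread does not degrade the solve at high degree
    dr <- 1 / apply(abs(A), 1, max)
    A <- A * dr; b <- b * dr
    dc <- 1 / apply(abs(A), 2, max)
    A <- sweep(A, 2, dc, "*")
    sol <- solve(A, b) * dc
    phi[n] <- sol[6] + sol[7]
  }
  phi
}

.transfer_cache <- new.env(parent = emptyenv())

.get_transfer <- function(head, n_max = 200L) {
  key <- paste(format(c(head$radii_mm, head$conductivities), digits = 15),
               collapse = "|")
  hit <- .transfer_cache[[key]]
  if (!is.null(hit) && length(hit) >= n_max) return(hit[seq_len(n_max)])
  phi <- .shell_transfer(head, n_max)
  .transfer_cache[[key]] <- phi
  phi
}

#' EEG scalp potential of a current dipole in the 4-shell sphere
#'
#' Exact concentric-sphere series solution (Legendre expansion), truncated
#' adaptively when the next term falls below 1e-10 of the accumulated maximum
#' (hard cap 200 degrees). The result is average-referenced across electrodes.
#'
#' @param dip_pos Numeric length-3, dipole position in mm (head frame, origin
#'   at sphere centre). Must lie strictly inside the innermost shell.
#' @param dip_moment Numeric length-3, dipole moment in nAm.
#' @param electrodes Matrix n x 3 of electrode positions in mm, on the scalp
#'   shell.
#' @param head A [head_model()].
#' @param tol Relative series truncation tolerance.
#' @return Numeric vector of average-referenced potentials in microvolts.
#' @export
eeg_sphere_potential <- function(dip_pos, dip_moment, electrodes, head,
                                 tol = 1e-10) {
  electrodes <- rbind(electrodes)
  b_mm <- sqrt(sum(dip_pos^2))
  if (b_mm >= head$radii_mm[1])
    stop("dipole lies outside the innermost shell (geometry error)")
  R <- head$radii_mm[4] * 1e-3          # scalp radius, m
  bm <- b_mm * 1e-3                     # dipole eccentricity, m
  sigma1 <- head$conductivities[1]
  m <- as.numeric(dip_moment) * 1e-9    # Am
  n_max <- 200L
  phi <- .get_transfer(head, n_max)

  bhat <- if (b_mm > 1e-9) dip_pos / b_mm else c(0, 0, 1)
  rn <- sqrt(rowSums(electrodes^2))
  ehat <- electrodes / rn
  u <- pmin(1, pmax(-1, as.numeric(ehat %*% bhat)))
  x <- bm / R

  # Running Legendre recurrences: P_n(u) and P_n'(u).
  ne <- nrow(electrodes)
  S1 <- numeric(ne); S2 <- numeric(ne)
  Pnm1 <- rep(1, ne); Pn <- u            # P_0, P_1
  dPnm1 <- rep(0, ne); dPn <- rep(1, ne) # P_0', P_1'
  xpow <- 1                              # x^(n-1)
  for (n in seq_len(n_max)) {
    t1 <- phi[n] * xpow * n * Pn
    t2 <- phi[n] * xpow * dPn
    S1 <- S1 + t1
    S2 <- S2 + t2
    scale_now <- max(abs(S1), abs(S2), 1e-300)
    if (max(abs(t1), abs(t2)) < tol * scale_now) break
    # advance to degree n+1
    Pnp1 <- ((2 * n + 1) * u * Pn - n * Pnm1) / (n + 1)
    dPnp1 <- dPnm1 + (2 * n + 1) * Pn
    Pnm1 <- Pn; Pn <- Pnp1
    dPnm1 <- dPn; dPn <- dPnp1
    xpow <- xpow * x
  }
  mr <- sum(m * bhat)
  mt <- m - mr * bhat
  ang <- mr * S1 + (ehat %*% mt)[, 1] * S2
  v <- ang / (4 * pi * sigma1 * R^2)    # volts
  v <- v - mean(v)
  v * 1e6
}

#' MEG field of a current dipole in a spherically symmetric conductor
#'
#' Closed-form magnetic field of a dipole inside a spherically symmetric
#' volume conductor (Sarvas solution), projected on each sensor's orientation.
#' The result is independent of the conductivity profile; radial dipoles are
#' magnetically silent.
#'
#' @param dip_pos Numeric length-3, dipole position in mm.
#' @param dip_moment Numeric length-3, dipole moment in nAm.
#' @param sensors Matrix n x 3 of sensor positions in mm, strictly outside the
#'   scalp shell.
#' @param orientations Matrix n x 3 of unit sensing directions.
#' @param head Optional [head_model()]; used only for the geometry checks.
#' @return Numeric vector of fields in femtotesla along the sensor
#'   orientations.
#' @export
meg_sphere_field <- function(dip_pos, dip_moment, sensors, orientations,
                             head = NULL) {
  sensors <- rbind(sensors)
  orientations <- rbind(orientations)
  if (!is.null(head)) {
    if (sqrt(sum(dip_pos^2)) >= head$radii_mm[1])
      stop("dipole lies outside the innermost shell (geometry error)")
    if (any(sqrt(rowSums(sensors^2)) <= head$radii_mm[4]))
      stop("MEG sensor inside the scalp shell (geometry error)")
  }
  r0 <- as.numeric(dip_pos) * 1e-3
  q <- as.numeric(dip_moment) * 1e-9
  r <- sensors * 1e-3
  mu0_4pi <- 1e-7

  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (sum(qxr0^2) == 0) return(rep(0, nrow(sensors)))

  a <- sweep(r, 2, r0)                   # r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  adotr <- rowSums(a * r)
  # F = a (r a + r^2 - r0.r)
  FF <- an * (rn * an + rn^2 - as.numeric(r %*% r0))
  c1 <- an^2 / rn + adotr / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + adotr / an
  gradF <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
  qxr0_dot_r <- r %*% qxr0
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * FF - gradF * as.numeric(qxr0_dot_r)) *
    (mu0_4pi / FF^2)
  rowSums(B * orientations) * 1e15
}

#' Assemble a leadfield matrix
#'
#' Evaluates the analytic forward solution for unit dipoles along the three
#' cardinal axes at every source position. EEG gains are average-referenced
#' (columns sum to zero over sensors); MEG gains do not depend on the
#' conductivity profile.
#'
#' @param source_space A `source_space` object (see [make_phantom()]) or a
#'   matrix n x 3 of source positions in mm.
#' @param sensors A `sensor_array` object (see [make_phantom()]).
#' @param head A [head_model()].
#' @return An object of class `leadfield`: list with `gain`
#'   (n_sensors x 3*n_sources, source-major column blocks), per-axis matrices
#'   `Gx`, `Gy`, `Gz`, and provenance fields. Units are uV/nAm (EEG) or
#'   fT/nAm (MEG).
#' @export
build_leadfield <- function(source_space, sensors, head) {
  pos <- if (is.matrix(source_space)) source_space else source_space$positions
  kind <- sensors$kind
  ns <- nrow(pos)
  nc <- nrow(sensors$positions)
  Gx <- matrix(0, nc, ns); Gy <- matrix(0, nc, ns); Gz <- matrix(0, nc, ns)
  for (i in seq_len(ns)) {
    res <- tryCatch({
      if (kind == "EEG") {
        cbind(eeg_sphere_potential(pos[i, ], c(1, 0, 0), sensors$positions, head),
              eeg_sphere_potential(pos[i, ], c(0, 1, 0), sensors$positions, head),
              eeg_sphere_potential(pos[i, ], c(0, 0, 1), sensors$positions, head))
      } else {
        cbind(meg_sphere_field(pos[i, ], c(1, 0, 0), sensors$positions,
                               sensors$orientations, head),
              meg_sphere_field(pos[i, ], c(0, 1, 0), sensors$positions,
                               sensors$orientations, head),
              meg_sphere_field(pos[i, ], c(0, 0, 1), sensors$positions,
                               sensors$orientations, head))
      }
    }, error = function(e) stop(sprintf("source %d: %s", i, conditionMessage(e)),
                                call. = FALSE))
    Gx[, i] <- res[, 1]; Gy[, i] <- res[, 2]; Gz[, i] <- res[, 3]
  }
  gain <- matrix(0, nc, 3L * ns)
  gain[, seq(1, 3 * ns, 3)] <- Gx
  gain[, seq(2, 3 * ns, 3)] <- Gy
  gain[, seq(3, 3 * ns, 3)] <- Gz
  structure(list(gain = gain, Gx = Gx, Gy = Gy, Gz = Gz,
                 kind = kind, n_sources = ns,
                 source_positions = pos,
                 channel_names = sensors$names,
                 head = head),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("%s leadfield: %d sensors x %d sources (x3 axes), units %s/nAm\n",
              x$kind, nrow(x$gain), x$n_sources,
              if (x$kind == "EEG") "uV" else "fT"))
  invisible(x)
}

#' Predict sensor data from source currents
#'
#' Applies the linear forward map: `data = gain %*% moments`.
#'
#' @param leadfield A [build_leadfield()] result.
#' @param moments Either a numeric vector of length 3*n_sources or an
#'   n_sources x 3 matrix of dipole moments in nAm.
#' @return Numeric vector of predicted sensor data.
#' @export
apply_leadfield <- function(leadfield, moments) {
  if (is.matrix(moments)) moments <- as.numeric(t(moments))
  as.numeric(leadfield$gain %*% moments)
}
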