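.as_loc_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x[, c("x_mm", "y_mm", "z_mm")]))
  stop("expected a matrix or dipole table of locations")
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Centroid dipole of a cluster
#'
#' The arithmetic mean of member locations plus the renormalized mean of the
#' member unit orientations; orientations are sign-aligned to the first
#' member before averaging (a dipole and its negation describe the same
#' source).
#'
#' @param locations n x 3 matrix of member locations (mm), or a dipole table
#'   with `x_mm`, `y_mm`, `z_mm` columns.
#' @param orientations Optional n x 3 matrix of member unit orientations.
#' @return List of class `centroid_dipole`: `location`, `orientation` (NULL
#'   if not supplied; NA with a warning if the aligned mean cancels to zero),
#'   `n`.
#' @export
centroid <- function(locations, orientations = NULL) {
  loc <- .as_loc_matrix(locations)
  if (nrow(loc) == 0L) stop("empty cluster (input error)")
  ctr <- colMeans(loc)
  ori <- NULL
  if (!is.null(orientations)) {
    ok <- stats::complete.cases(orientations) &
      rowSums(orientations^2) > 0
    orientations <- orientations[ok, , drop = FALSE]
    if (nrow(orientations) == 0L) {
      warning("no member carries a defined orientation")
      return(structure(list(location = ctr,
                            orientation = c(NA_real_, NA_real_, NA_real_),
                            n = nrow(loc)), class = "centroid_dipole"))
    }
    o <- orientations / sqrt(rowSums(orientations^2))
    sgn <- sign(as.numeric(o %*% o[1, ]))
    sgn[sgn == 0] <- 1
    om <- colMeans(o * sgn)
    nrm <- sqrt(sum(om^2))
    if (nrm < 1e-12) {
      warning("member orientations cancel; centroid orientation undefined")
      ori <- c(NA_real_, NA_real_, NA_real_)
    } else ori <- om / nrm
  }
  structure(list(location = ctr, orientation = ori, n = nrow(loc)),
            class = "centroid_dipole")
}

#' @export
print.centroid_dipole <- function(x, ...) {
  cat(sprintf("Centroid dipole of %d members at (%s) mm\n", x$n,
              paste(round(x$location, 2), collapse = ", ")))
  if (!is.null(x$orientation))
    cat(sprintf("  orientation: (%s)\n",
                paste(round(x$orientation, 3), collapse = ", ")))
  invisible(x)
}

#' Mean + 2 SD outlier pruning
#'
#' Single-pass cluster pruning: distances of all members to the cluster
#' centroid are computed once; members whose distance strictly exceeds
#' `mean + 2 * SD` (population SD) are removed. The rule is not iterated by
#' default.
#'
#' @param locations n x 3 matrix (or dipole table) of member locations in mm.
#' @param iterate If `TRUE`, repeat the pass until no member is removed
#'   (non-default variant).
#' @return List: `kept` (row indices), `removed`, `threshold_mm`,
#'   `distances_mm` (first-pass distances).
#' @export
prune_outliers <- function(locations, iterate = FALSE) {
  loc <- .as_loc_matrix(locations)
  n <- nrow(loc)
  if (n < 2L) {
    warning("cluster smaller than 2: returned unchanged")
    return(list(kept = seq_len(n), removed = integer(0),
                threshold_mm = NA_real_,
                distances_mm = rep(0, n)))
  }
  pass <- function(idx) {
    ctr <- colMeans(loc[idx, , drop = FALSE])
    d <- sqrt(colSums((t(loc[idx, , drop = FALSE]) - ctr)^2))
    thr <- mean(d) + 2 * .pop_sd(d)
    list(keep = idx[d <= thr], d = d, thr = thr)
  }
  p <- pass(seq_len(n))
  kept <- p$keep
  if (iterate) {
    repeat {
      if (length(kept) < 2L) break
      p2 <- pass(kept)
      if (length(p2$keep) == length(kept)) break
      kept <- p2$keep
    }
  }
  list(kept = kept, removed = setdiff(seq_len(n), kept),
       threshold_mm = p$thr, distances_mm = p$d)
}

#' Scatter of a cluster
#'
#' Mean and population SD of member-to-centroid distances.
#'
#' @inheritParams prune_outliers
#' @return List `mean_mm`, `sd_mm`, `distances_mm`.
#' @export
cluster_scatter <- function(locations) {
  loc <- .as_loc_matrix(locations)
  ctr <- colMeans(loc)
  d <- sqrt(colSums((t(loc) - ctr)^2))
  list(mean_mm = mean(d), sd_mm = .pop_sd(d), distances_mm = d)
}

#' Square Distance Index at one contact
#'
#' `SDI = (100 / N) * sum_j 1 / (d_j^2 + 1)` over the N gated dipoles, with
#' `d_j` the Euclidean dipole-to-contact distance in mm. The `+ 1` makes a
#' perfect colocalization (`d = 0` for all dipoles) score exactly 100.
#'
#' @param dipole_locations N x 3 matrix (or dipole table) of dipole locations
#'   in mm.
#' @param contact Length-3 contact position in mm.
#' @return The SDI value; `NA_real_` (undefined, not zero) for N = 0.
#' @export
sdi <- function(dipole_locations, contact) {
  loc <- .as_loc_matrix(dipole_locations)
  n <- nrow(loc)
  if (n == 0L) return(NA_real_)
  d2 <- colSums((t(loc) - as.numeric(contact))^2)
  100 / n * sum(1 / (d2 + 1))
}

#' Within-radius coverage of sEEG contacts
#'
#' For every contact, the count and fraction of dipoles within the radius
#' (closed ball by default), and the number of contacts reached by at least
#' one dipole.
#'
#' @param dipole_locations N x 3 matrix (or dipole table) of dipole locations.
#' @param contacts A `seeg_contacts` table or an m x 3 position matrix.
#' @param radius_mm Coverage radius.
#' @param strict If `TRUE`, use the open ball (distance strictly below the
#'   radius).
#' @return Data frame with one row per contact: `contact`, `label` (if
#'   available), `n_within`, `fraction_within`; attribute `n_covered` gives
#'   the number of contacts with at least one dipole within the radius.
#' @export
coverage <- function(dipole_locations, contacts, radius_mm = 10,
                     strict = FALSE) {
  if (radius_mm <= 0) stop("radius must be positive")
  loc <- .as_loc_matrix(dipole_locations)
  if (is.data.frame(contacts)) {
    cpos <- contact_positions(contacts)
    ids <- paste0(contacts$electrode_name, contacts$contact_number)
    labels <- contacts$label
  } else {
    cpos <- rbind(contacts)
    ids <- sprintf("contact%d", seq_len(nrow(cpos)))
    labels <- rep(NA_character_, nrow(cpos))
  }
  n <- nrow(loc)
  cnt <- vapply(seq_len(nrow(cpos)), function(i) {
    d <- sqrt(colSums((t(loc) - cpos[i, ])^2))
    if (strict) sum(d < radius_mm) else sum(d <= radius_mm)
  }, numeric(1))
  out <- data.frame(contact = ids, label = labels, n_within = cnt,
                    fraction_within = if (n > 0) cnt / n else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "n_covered") <- sum(cnt >= 1)
  out
}

#' Per-contact SDI table
#'
#' Evaluates [sdi()] and [coverage()] for every contact in a table.
#'
#' @inheritParams coverage
#' @return Data frame of class `sdi_table` with columns `contact`, `label`,
#'   `sdi`, `n_within`, `fraction_within`.
#' @export
sdi_table <- function(dipole_locations, contacts, radius_mm = 10,
                      strict = FALSE) {
  loc <- .as_loc_matrix(dipole_locations)
  cov <- coverage(loc, contacts, radius_mm = radius_mm, strict = strict)
  cpos <- if (is.data.frame(contacts)) contact_positions(contacts)
  else rbind(contacts)
  cov$sdi <- vapply(seq_len(nrow(cpos)), function(i) sdi(loc, cpos[i, ]),
                    numeric(1))
  cov <- cov[, c("contact", "label", "sdi", "n_within", "fraction_within")]
  class(cov) <- c("sdi_table", "data.frame")
  cov
}

#' Summary of an SDI table over contacts
#'
#' Mean and population SD of the SDI over contacts with a defined value. A
#' complete and even depiction of the irritative zone has a high mean and a
#' low SD.
#'
#' @param x An [sdi_table()] result or numeric vector of SDI values.
#' @return List `mean`, `sd`, `n_contacts`.
#' @export
summarize_sdi <- function(x) {
  v <- if (is.data.frame(x)) x$sdi else as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no contact has a defined SDI")
  list(mean = mean(v), sd = .pop_sd(v), n_contacts = length(v))
}
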