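#' End-to-end synthetic pipeline
#'
#' Runs the full analysis on the digital phantom: simulate a spike run,
#' band-pass filter, build the detection template from the first marked
#' spikes, detect and epoch spikes, draw bootstrap subaverages, gate by SNR,
#' deviation-scan every surviving realization for EEG, left-hemisphere MEG
#' (regularized) and fused EMEG, and score the resulting dipole clusters
#' against the phantom's sEEG contacts.
#'
#' @param phantom A [make_phantom()] result; `NULL` builds the default
#'   phantom from `seed`.
#' @param n_spikes Number of simulated spikes.
#' @param group_sizes Subaverage group sizes (1 = single spikes).
#' @param n_realizations Realizations per subaverage group.
#' @param times_ms Analysis instants relative to the aligned spike peak.
#' @param snr_threshold SNR gate.
#' @param noise A [noise_model()].
#' @param filter Band-pass the simulated run (1-100 Hz) before analysis.
#' @param detect_threshold Template-matching correlation threshold.
#' @param n_template_spikes Number of marked spikes averaged into the
#'   detection template.
#' @param radius_mm Coverage radius for the contact statistics.
#' @param prune Compute the contact statistics on pruned clusters as well.
#' @param detection Run template detection (`TRUE`) or epoch directly at the
#'   simulated ground-truth peaks (`FALSE`; emulates reviewer-marked spikes
#'   and isolates the averaging/scanning stages from detector recall).
#' @param leadfields Optional precomputed list `list(eeg = , meg = )` of
#'   [build_leadfield()] results for the phantom, reused across runs.
#' @param seed Integer run seed (phantom, simulation and subaverage draws).
#' @param out_dir Optional directory; when given, dipole, SDI, coverage and
#'   provenance files are written there as CSV/JSON-like text.
#' @return A list of class `emeg_pipeline`: `phantom`, `recording` (without
#'   the bulky raw data), `dipoles` (one row per gated scan), `stats`
#'   (summary per modality/time/group from [reproduce_s1()]),
#'   `stats_pruned`, `centroids`, `config`.
#' @export
run_pipeline <- function(phantom = NULL,
                         n_spikes = 200L,
                         group_sizes = c(1L, seq(5L, 50L, by = 5L)),
                         n_realizations = 200L,
                         times_ms = c(-33, -23, -13, -3),
                         snr_threshold = 3,
                         noise = noise_model(),
                         filter = TRUE,
                         detect_threshold = 0.45,
                         n_template_spikes = 10L,
                         radius_mm = 10,
                         prune = TRUE,
                         detection = TRUE,
                         leadfields = NULL,
                         seed = 1L,
                         out_dir = NULL) {
  config <- list(n_spikes = n_spikes, group_sizes = group_sizes,
                 n_realizations = n_realizations, times_ms = times_ms,
                 snr_threshold = snr_threshold, filter = filter,
                 detect_threshold = detect_threshold,
                 radius_mm = radius_mm, prune = prune, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(phantom)) phantom <- stage("phantom", make_phantom(seed = seed))

  if (is.null(leadfields)) {
    leadfields <- list(
      eeg = stage("leadfield", build_leadfield(phantom$source_space,
                                               phantom$eeg, phantom$head)),
      meg = stage("leadfield", build_leadfield(phantom$source_space,
                                               phantom$meg, phantom$head)))
  }
  lf_eeg <- leadfields$eeg
  lf_meg <- leadfields$meg
  meg_left <- select_meg_left(phantom$meg)
  lf_meg_left <- subset_leadfield(lf_meg, meg_left)

  rec <- stage("simulate", simulate_spike_run(
    phantom, n_spikes = n_spikes, noise = noise,
    leadfields = list(eeg = lf_eeg, meg = lf_meg), seed = seed))
  if (filter) rec <- stage("filter", bandpass(rec, 1, 100))

  eeg_rows <- which(rec$channels$modality == "EEG")
  meg_rows <- which(rec$channels$modality == "MEG")

  if (detection) {
    ## template from the first marked spikes on the EEG channels closest to
    ## the lateral (high-SNR) patch
    d_lat <- sqrt(colSums((t(phantom$eeg$positions) - phantom$zone$lateral_seed)^2))
    det_ch <- eeg_rows[order(d_lat)[seq_len(8)]]
    marked <- rec$ground_truth$peak_sample[seq_len(min(n_template_spikes, n_spikes))]
    tmpl <- stage("template", make_template(rec, marked, det_ch))
    events <- stage("detect", detect_spikes(rec, tmpl,
                                            threshold = detect_threshold))
  } else {
    events <- rec$ground_truth$peak_sample
  }
  epochs <- stage("epoch", extract_epochs(rec, events))
  if (length(epochs) < max(group_sizes))
    stop(sprintf("pipeline stage 'epoch': only %d epochs for max group size %d",
                 length(epochs), max(group_sizes)))
  reals <- stage("subaverage", make_subaverages(
    epochs, group_sizes = group_sizes, n_realizations = n_realizations,
    seed = seed))

  ## scans per modality and time point
  dip <- list()
  for (t_ms in times_ms) {
    for (mod in c("EEG", "MEG", "EMEG")) {
      gated <- stage("gate", switch(mod,
        EEG = snr_gate(reals, eeg_rows, t_ms, snr_threshold),
        MEG = snr_gate(reals, meg_rows[meg_left], t_ms, snr_threshold),
        EMEG = .gate_emeg(reals, eeg_rows, meg_rows[meg_left], lf_eeg,
                          lf_meg_left, t_ms, snr_threshold)))
      for (rl in gated) {
        sc <- stage("scan", .scan_realization(rl, mod, t_ms, eeg_rows,
                                              meg_rows[meg_left],
                                              lf_eeg, lf_meg_left))
        dip[[length(dip) + 1L]] <- data.frame(
          modality = mod, group = rl$group, time_ms = t_ms,
          realization = rl$realization, snr = rl$snr,
          residual_variance = sc$residual_variance,
          x_mm = sc$location[1], y_mm = sc$location[2], z_mm = sc$location[3],
          nx = sc$orientation[1], ny = sc$orientation[2],
          nz = sc$orientation[3], strength = sc$strength,
          best_index = sc$best_index, gof = sc$gof)
      }
    }
  }
  dipoles <- if (length(dip)) do.call(rbind, dip) else
    data.frame(modality = character(0))

  stats <- stats_pruned <- NULL
  centroids <- NULL
  if (nrow(dipoles) > 0L) {
    stats <- reproduce_s1(dipoles, phantom$contacts,
                          snr_threshold = 0,  # rows are already gated
                          radius_mm = radius_mm, prune = FALSE)
    if (prune)
      stats_pruned <- reproduce_s1(dipoles, phantom$contacts,
                                   snr_threshold = 0, radius_mm = radius_mm,
                                   prune = TRUE)
    centroids <- .pipeline_centroids(dipoles)
  }

  rec_light <- rec; rec_light$data <- NULL; rec_light$leadfields <- NULL
  out <- structure(list(phantom = phantom, recording = rec_light,
                        n_detected = length(epochs),
                        dipoles = dipoles, stats = stats,
                        stats_pruned = stats_pruned, centroids = centroids,
                        config = config), class = "emeg_pipeline")
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

.emeg_fuse_realization <- function(rl, eeg_rows, meg_rows_left, lf_eeg,
                                   lf_meg_left) {
  ep_e <- rl$epoch; ep_e$data <- rl$epoch$data[eeg_rows, , drop = FALSE]
  ep_m <- rl$epoch; ep_m$data <- rl$epoch$data[meg_rows_left, , drop = FALSE]
  emeg_fuse(ep_e, ep_m, lf_eeg, lf_meg_left)
}

.gate_emeg <- function(reals, eeg_rows, meg_rows_left, lf_eeg, lf_meg_left,
                       t_ms, threshold) {
  keep <- list()
  for (rl in reals) {
    fu <- .emeg_fuse_realization(rl, eeg_rows, meg_rows_left, lf_eeg,
                                 lf_meg_left)
    ep <- list(data = fu$data, times_ms = fu$times_ms,
               sfreq = rl$epoch$sfreq, channels = NULL)
    class(ep) <- "epoch"
    s <- compute_snr(ep, t_ms, seq_len(nrow(fu$data)))
    if (s$value > threshold) {
      rl$snr <- s$value
      rl$fused <- fu
      keep[[length(keep) + 1L]] <- rl
    }
  }
  keep
}

.scan_realization <- function(rl, mod, t_ms, eeg_rows, meg_rows_left,
                              lf_eeg, lf_meg_left) {
  it <- which.min(abs(rl$epoch$times_ms - t_ms))
  if (mod == "EEG") {
    deviation_scan(rl$epoch$data[eeg_rows, it], lf_eeg,
                   modality = "EEG", time_ms = t_ms, snr = rl$snr)
  } else if (mod == "MEG") {
    deviation_scan(rl$epoch$data[meg_rows_left, it], lf_meg_left,
                   regularization = "tikhonov",
                   modality = "MEG", time_ms = t_ms, snr = rl$snr)
  } else {
    fu <- rl$fused
    if (is.null(fu))
      fu <- .emeg_fuse_realization(rl, eeg_rows, meg_rows_left, lf_eeg,
                                   lf_meg_left)
    deviation_scan(fu$data[, it], fu$leadfield,
                   modality = "EMEG", time_ms = t_ms, snr = rl$snr)
  }
}

.pipeline_centroids <- function(dipoles) {
  cells <- unique(dipoles[, c("modality", "time_ms", "group")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows <- dipoles[dipoles$modality == cell$modality &
                      dipoles$time_ms == cell$time_ms &
                      dipoles$group == cell$group, , drop = FALSE]
    ctr <- centroid(rows, orientations = as.matrix(rows[, c("nx", "ny", "nz")]))
    sca <- cluster_scatter(rows)
    out[[i]] <- data.frame(cell, n = nrow(rows),
                           x_mm = ctr$location[1], y_mm = ctr$location[2],
                           z_mm = ctr$location[3],
                           depth_mm = sqrt(sum(ctr$location^2)),
                           scatter_mean_mm = sca$mean_mm,
                           scatter_sd_mm = sca$sd_mm)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.write_bundle <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dip <- x$dipoles
  if (nrow(dip)) write_dipole_table(dip, file.path(out_dir, "dipoles.csv"))
  write_contact_table(x$phantom$contacts, file.path(out_dir, "contacts.csv"))
  if (!is.null(x$stats))
    utils::write.csv(x$stats$summary, file.path(out_dir, "stats_summary.csv"),
                     row.names = FALSE)
  if (!is.null(x$stats_pruned))
    utils::write.csv(x$stats_pruned$summary,
                     file.path(out_dir, "stats_summary_pruned.csv"),
                     row.names = FALSE)
  if (!is.null(x$centroids))
    utils::write.csv(x$centroids, file.path(out_dir, "centroids.csv"),
                     row.names = FALSE)
  prov <- c(sprintf("seed: %d", x$config$seed),
            sprintf("config: %s", paste(deparse(x$config), collapse = " ")))
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.emeg_pipeline <- function(x, ...) {
  cat("EEG/MEG phantom pipeline run\n")
  cat(sprintf("  %d spikes simulated, %d detected/epoched\n",
              x$config$n_spikes, x$n_detected))
  cat(sprintf("  %d gated deviation scans across %d time point(s)\n",
              nrow(x$dipoles), length(x$config$times_ms)))
  if (!is.null(x$stats)) {
    cat("  contact statistics (gate-only):\n")
    print(utils::head(x$stats$summary, 12))
  }
  invisible(x)
}
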