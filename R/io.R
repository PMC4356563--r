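.dipole_cols <- c("modality", "group", "time_ms", "snr", "residual_variance",
                  "x_mm", "y_mm", "z_mm", "nx", "ny", "nz", "strength")

#' Write a dipole result table
#'
#' Deterministic column order (`modality, group, time_ms, snr,
#' residual_variance, x_mm, y_mm, z_mm, nx, ny, nz, strength`), CSV dialect.
#'
#' @param rows Data frame of dipole results.
#' @param path Output path.
#' @export
write_dipole_table <- function(rows, path) {
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(stats::setNames(
      replicate(length(.dipole_cols), numeric(0), simplify = FALSE),
      .dipole_cols))
  }
  missing <- setdiff(.dipole_cols, names(rows))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(rows[, .dipole_cols], path, row.names = FALSE)
  invisible(path)
}

.check_numeric_cells <- function(df, cols, what) {
  for (cl in cols) {
    raw <- df[[cl]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "")
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at row %d ('%s')",
                   what, cl, bad[1], raw[bad[1]]))
    df[[cl]] <- num
  }
  df
}

#' Read a dipole result table
#'
#' Accepts the CSV dialect written by [write_dipole_table()] or a multi-page
#' spreadsheet (one page per modality: EMEG, EEG, MEG in that order, matched
#' by sheet name first, position as fallback). Every row is validated;
#' malformed cells are reported with their row and column.
#'
#' @param path File path (`.csv` or `.xlsx`).
#' @param page Modality page to read: `"EMEG"`, `"EEG"` or `"MEG"`; `NULL`
#'   returns all rows of a CSV.
#' @return Data frame of dipole results.
#' @export
read_dipole_table <- function(path, page = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the readxl package")
    if (is.null(page)) stop("page must be given for spreadsheet input")
    sheets <- readxl::excel_sheets(path)
    hit <- grep(paste0("^", page, "$"), sheets, ignore.case = TRUE)
    if (length(hit) == 0L)
      hit <- match(page, c("EMEG", "EEG", "MEG"))  # positional fallback
    df <- as.data.frame(readxl::read_excel(path, sheet = sheets[hit[1]]))
    if (!"modality" %in% names(df)) df$modality <- page
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  missing <- setdiff(.dipole_cols, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  df <- .check_numeric_cells(df, setdiff(.dipole_cols, c("modality", "group")),
                             basename(path))
  if (any(df$residual_variance < -1e-9 | df$residual_variance > 1 + 1e-9,
          na.rm = TRUE))
    stop("residual_variance outside [0, 1]")
  if (!is.null(page)) df <- df[df$modality == page, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an sEEG contact table
#' @param contacts A `seeg_contacts` data frame.
#' @param path Output path (CSV).
#' @export
write_contact_table <- function(contacts, path) {
  cols <- c("electrode_name", "contact_number", "x_mm", "y_mm", "z_mm", "label")
  utils::write.csv(as.data.frame(contacts)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read an sEEG contact table
#'
#' CSV with columns `electrode_name, contact_number, x_mm, y_mm, z_mm` and
#' optionally `label`; labels can also be supplied via a sidecar CSV
#' (`electrode_name, contact_number, label`) when the coordinate file carries
#' none.
#'
#' @param path Contact coordinate CSV.
#' @param label_path Optional sidecar CSV with activity labels.
#' @return A `seeg_contacts` data frame.
#' @export
read_contact_table <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("electrode_name", "contact_number", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  df <- .check_numeric_cells(df, c("contact_number", "x_mm", "y_mm", "z_mm"),
                             basename(path))
  if (!is.null(label_path)) {
    lab <- utils::read.csv(label_path, stringsAsFactors = FALSE)
    df$label <- NULL
    df <- merge(df, lab[, c("electrode_name", "contact_number", "label")],
                by = c("electrode_name", "contact_number"), all.x = TRUE,
                sort = FALSE)
  }
  if (is.null(df$label)) df$label <- "interictal"
  df$label[is.na(df$label)] <- "inactive"
  bad <- setdiff(unique(df$label), c("ictal", "interictal", "inactive"))
  if (length(bad)) stop("unknown contact label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[, c("electrode_name", "contact_number")]))
    stop("duplicate (electrode_name, contact_number) pair")
  df <- df[, c("electrode_name", "contact_number", "x_mm", "y_mm", "z_mm",
               "label")]
  class(df) <- c("seeg_contacts", "data.frame")
  df
}

#' Validation statistics from deposited dipole and contact tables
#'
#' The exact-reproduction path: reads previously computed deviation-scan
#' dipole tables plus the sEEG contact table and re-derives the validation
#' statistics (per-contact SDI, SDI mean/SD over interictal-measuring
#' contacts, within-radius coverage of interictal and ictal contacts, and
#' gated-survivor counts) for every (modality, time, group) cell present. No
#' forward or inverse computation is involved; the outputs depend only on the
#' table contents and the stated flags.
#'
#' @param dipole_table Data frame from [read_dipole_table()] (all modalities),
#'   or a path.
#' @param contacts A `seeg_contacts` table or a path readable by
#'   [read_contact_table()].
#' @param snr_threshold SNR gate re-applied to the rows (strictly greater).
#' @param radius_mm Coverage radius.
#' @param prune Apply mean+2SD outlier pruning per cell before computing the
#'   statistics (`FALSE` reproduces the gate-only reading).
#' @param strict_coverage Open-ball coverage if `TRUE`.
#' @return List with `summary` (one row per modality/time/group cell: number
#'   of gated dipoles, SDI mean/SD, interictal and ictal coverage counts) and
#'   `per_contact` (the full SDI tables, keyed by cell).
#' @export
reproduce_s1 <- function(dipole_table, contacts, snr_threshold = 3,
                         radius_mm = 10, prune = FALSE,
                         strict_coverage = FALSE) {
  if (is.character(dipole_table)) dipole_table <- read_dipole_table(dipole_table)
  if (is.character(contacts)) contacts <- read_contact_table(contacts)
  active <- contacts[contacts$label != "inactive", , drop = FALSE]
  ictal <- contacts[contacts$label == "ictal", , drop = FALSE]
  cells <- unique(dipole_table[, c("modality", "time_ms", "group")])
  summ <- list(); per_contact <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows <- dipole_table[dipole_table$modality == cell$modality &
                           dipole_table$time_ms == cell$time_ms &
                           dipole_table$group == cell$group, , drop = FALSE]
    rows <- rows[rows$snr > snr_threshold, , drop = FALSE]
    n_gated <- nrow(rows)
    if (prune && n_gated >= 2L) {
      pr <- prune_outliers(rows)
      rows <- rows[pr$kept, , drop = FALSE]
    }
    key <- sprintf("%s_%s_%gms", cell$modality, cell$group, cell$time_ms)
    if (nrow(rows) == 0L) {
      summ[[key]] <- data.frame(cell, n_gated = 0L, n_used = 0L,
                                sdi_mean = NA_real_, sdi_sd = NA_real_,
                                covered_interictal = NA_integer_,
                                n_interictal = nrow(active),
                                covered_ictal = NA_integer_,
                                n_ictal = nrow(ictal))
      next
    }
    st <- sdi_table(rows, active, radius_mm = radius_mm,
                    strict = strict_coverage)
    ss <- summarize_sdi(st)
    cov_i <- coverage(rows, active, radius_mm = radius_mm,
                      strict = strict_coverage)
    cov_z <- coverage(rows, ictal, radius_mm = radius_mm,
                      strict = strict_coverage)
    per_contact[[key]] <- st
    summ[[key]] <- data.frame(cell, n_gated = n_gated, n_used = nrow(rows),
                              sdi_mean = ss$mean, sdi_sd = ss$sd,
                              covered_interictal = attr(cov_i, "n_covered"),
                              n_interictal = nrow(active),
                              covered_ictal = attr(cov_z, "n_covered"),
                              n_ictal = nrow(ictal))
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(summary = summary, per_contact = per_contact,
       flags = list(snr_threshold = snr_threshold, radius_mm = radius_mm,
                    prune = prune, strict_coverage = strict_coverage))
}
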