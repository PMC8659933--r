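# On-disk formats: per-arm ACC CSV streams (line 1 UNIX start timestamp,
# line 2 sampling rate, then one x,y,z integer row per sample), a cohort
# manifest, and processed pairs as two-column CSV with a JSON sidecar.

#' Write one arm's accelerometer stream as ACC CSV
#'
#' @param arm Integer matrix, one x,y,z row per sample.
#' @param t0 UNIX start timestamp (seconds).
#' @param fs Sampling rate, Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acc_csv <- function(arm, t0, fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(format(t0, nsmall = 1, scientific = FALSE),
               format(fs, nsmall = 1)), con)
  utils::write.table(arm, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an ACC CSV stream
#'
#' Validates the two-line header (numeric timestamp and rate) and the
#' integer sample rows; a malformed row is reported with its line number.
#' A declared rate other than 32 Hz is flagged with a warning but the file
#' is read at the declared rate.
#'
#' @param path File path.
#' @return List with integer matrix `arm`, `t0` and `fs`.
#' @export
read_acc_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stopf("%s: truncated file (no samples)", path)
  t0 <- suppressWarnings(as.numeric(lines[1]))
  fs <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(t0) || is.na(fs)) {
    stopf("%s: malformed header (lines 1-2 must be timestamp and rate)", path)
  }
  if (abs(fs - 32) > 1e-9) {
    warnf("%s: declared rate %g Hz differs from the expected 32 Hz", path, fs)
  }
  body <- lines[-(1:2)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stopf("%s: parse error at line %d (expected 3 comma-separated values)",
          path, which(nf != 3)[1] + 2L)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- which(apply(matrix(is.na(vals), ncol = 3, byrow = TRUE), 1, any))[1]
    stopf("%s: parse error at line %d (non-numeric sample)", path, bad + 2L)
  }
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  if (any(abs(m - round(m)) > 1e-9)) {
    stopf("%s: non-integer samples", path)
  }
  list(arm = matrix(as.integer(round(m)), ncol = 3), t0 = t0, fs = fs)
}

#' Write a bilateral recording as two ACC CSV files
#'
#' Files are named `<subject>_left_ACC.csv` and `<subject>_right_ACC.csv`.
#'
#' @param rec A `raw_recording`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    left = file.path(dir, sprintf("%s_left_ACC.csv", rec$subject_id)),
    right = file.path(dir, sprintf("%s_right_ACC.csv", rec$subject_id)))
  write_acc_csv(rec$arm1, rec$t0[["arm1"]], rec$fs, paths[["left"]])
  write_acc_csv(rec$arm2, rec$t0[["arm2"]], rec$fs, paths[["right"]])
  invisible(paths)
}

#' Read a bilateral recording from its two ACC CSV files
#'
#' @param subject_id Subject id (used to locate the files).
#' @param dir Directory containing the files.
#' @param group,paresis_grade,affected_side Subject metadata (usually from
#'   the cohort manifest).
#' @return A `raw_recording`.
#' @export
read_recording <- function(subject_id, dir, group = "control",
                           paresis_grade = 0L, affected_side = "none") {
  lf <- read_acc_csv(file.path(dir, sprintf("%s_left_ACC.csv", subject_id)))
  rt <- read_acc_csv(file.path(dir, sprintf("%s_right_ACC.csv", subject_id)))
  structure(
    list(arm1 = lf$arm, arm2 = rt$arm, fs = lf$fs, counts_per_g = 64,
         t0 = c(arm1 = lf$t0, arm2 = rt$t0),
         subject_id = subject_id, group = group,
         paresis_grade = as.integer(paresis_grade),
         affected_side = affected_side),
    class = "raw_recording")
}

#' Write a simulated cohort to disk
#'
#' Writes every recording's two ACC CSV files plus `manifest.csv` with the
#' subject metadata and file names.
#'
#' @param recs List of `raw_recording` objects (from [simulate_cohort()]).
#' @param dir Output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(recs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(recs, function(rec) {
    paths <- write_recording(rec, dir)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               paresis_grade = rec$paresis_grade,
               affected_side = rec$affected_side,
               file_left = basename(paths[["left"]]),
               file_right = basename(paths[["right"]]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort directory back into recordings
#'
#' @param dir Directory containing `manifest.csv` and the ACC CSV files.
#' @return List of `raw_recording` objects.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("missing manifest: %s", mf)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(manifest$subject_id[i], dir, manifest$group[i],
                   manifest$paresis_grade[i], manifest$affected_side[i])
  })
}

#' Write / read a processed pair (two-column CSV + JSON sidecar)
#'
#' @param pair A `processed_pair`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_processed_pair <- function(pair, path) {
  stopifnot(inherits(pair, "processed_pair"))
  utils::write.csv(data.frame(arm1 = pair$arm1, arm2 = pair$arm2),
                   path, row.names = FALSE)
  side <- pair[c("rate_hz", "shift", "subject_id", "label",
                 "paresis_grade", "affected_side")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_processed_pair
#' @export
read_processed_pair <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_processed_pair(d$arm1, d$arm2, side$rate_hz, side$shift,
                     side$subject_id, side$label,
                     side$paresis_grade %||% NA_integer_,
                     side$affected_side %||% NA_character_)
}
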