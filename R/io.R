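#' Read and write per-subject waveform files
#'
#' A subject on disk is a waveform CSV (columns `time_s`, `area_cm2`,
#' `flow_ml_s`; comma-separated, `.` decimal, mandatory header, UTF-8) plus a
#' JSON metadata sidecar with the same base name (`<id>.json`) carrying
#' `{id, group, sex, age_years, bsa_m2, sbp_mmHg, dbp_mmHg, mbp_mmHg, lvm_g?,
#' diam_transverse_mm?, diam_isthmus_mm?, diam_descending_mm?}`.
#'
#' Validation failures raise classed errors naming the offending field
#' (`coawave_error_column`, `coawave_error_time_grid`, `coawave_error_area`,
#' `coawave_error_bp_ordering`, ...).
#'
#' @param path Path to the waveform CSV.
#' @param sidecar Path to the metadata JSON; defaults to `<path>.json` with
#'   the `.csv` extension replaced.
#' @return A [subject_record()].
#' @export
read_subject_csv <- function(path, sidecar = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("waveform file not found: %s", path),
          class = "coawave_error_io")
  }
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) {
    abort(sprintf("metadata sidecar not found: %s", sidecar),
          class = "coawave_error_io")
  }
  wave <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("id", "group", "bsa_m2", "sbp_mmHg", "dbp_mmHg", "mbp_mmHg")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("metadata sidecar missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "coawave_error_metadata")
  }
  cycle <- aortic_cycle(wave)
  bp <- brachial_bp(meta$sbp_mmHg, meta$dbp_mmHg, meta$mbp_mmHg)
  opt <- function(field) {
    v <- meta[[field]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  subject_record(
    id = meta$id, group = meta$group, bsa = as.numeric(meta$bsa_m2), bp = bp,
    cycle = cycle,
    sex = if (is.null(meta$sex)) NA_character_ else meta$sex,
    age = opt("age_years"), lvm = opt("lvm_g"),
    diam_transverse = opt("diam_transverse_mm"),
    diam_isthmus = opt("diam_isthmus_mm"),
    diam_descending = opt("diam_descending_mm")
  )
}

#' @rdname read_subject_csv
#' @param record A [subject_record()].
#' @param dir Output directory (created if needed).
#' @return `write_subject_csv()` returns the CSV path, invisibly.
#' @export
write_subject_csv <- function(record, dir) {
  stopifnot(inherits(record, "subject_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(record$id, ".csv"))
  json <- file.path(dir, paste0(record$id, ".json"))
  wave <- tibble::tibble(
    time_s = record$cycle$time,
    area_cm2 = record$cycle$area,
    flow_ml_s = record$cycle$flow
  )
  readr::write_csv(wave, csv, progress = FALSE)
  drop_na_scalar <- function(x) x[!vapply(x, function(v) is.na(v[1]), logical(1))]
  meta <- drop_na_scalar(list(
    id = record$id, group = record$group, sex = record$sex,
    age_years = record$age, bsa_m2 = record$bsa,
    sbp_mmHg = record$bp$sbp, dbp_mmHg = record$bp$dbp,
    mbp_mmHg = record$bp$mbp, lvm_g = record$lvm,
    diam_transverse_mm = record$diam_transverse,
    diam_isthmus_mm = record$diam_isthmus,
    diam_descending_mm = record$diam_descending,
    period_s = cycle_period(record$cycle)
  ))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
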