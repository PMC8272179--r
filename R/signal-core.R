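#' Acceleration vector magnitude (AVM)
#'
#' Combines the three accelerometer channels into a single magnitude per
#' sample, `AVM[i] = sqrt(ax[i]^2 + ay[i]^2 + az[i]^2)`, in g units.
#' A sensor at rest, whatever its orientation, reads an AVM of 1 g.
#'
#' @param record An [accel_record()].
#' @return An `avm_series`: list with `values` (numeric, same length as
#'   the record), `fs_hz` and `record_id`.
#' @export
compute_avm <- function(record) {
  stopifnot(inherits(record, "accel_record"))
  v <- sqrt(record$ax^2 + record$ay^2 + record$az^2)
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("compute_avm: non-finite AVM in record '", record$record_id,
         "' at index ", bad[1L])
  }
  avm_series(v, record$fs_hz, record$record_id)
}

#' Construct an AVM series directly
#'
#' Mostly useful in tests and examples where a magnitude trace is
#' specified by hand rather than derived from a tri-axial record.
#'
#' @param values Non-negative numeric vector of AVM samples (g).
#' @param fs_hz Sampling frequency in Hz.
#' @param record_id Identifier of the source record.
#' @return An object of class `avm_series`.
#' @export
avm_series <- function(values, fs_hz, record_id = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("avm_series: non-finite values")
  if (any(values < 0)) stop("avm_series: AVM values must be >= 0")
  stopifnot(is.numeric(fs_hz), length(fs_hz) == 1L, fs_hz > 0)
  structure(list(values = values, fs_hz = as.numeric(fs_hz),
                 record_id = as.character(record_id)),
            class = "avm_series")
}

#' @export
print.avm_series <- function(x, ...) {
  cat(sprintf("<avm_series %s> %d samples @ %g Hz, max %.3f g\n",
              x$record_id, length(x$values), x$fs_hz, max(x$values)))
  invisible(x)
}

#' Record-level quality control
#'
#' Excludes records carrying physically uninterpretable data, most
#' likely caused by sensor error:
#'
#' * any record (fall or ADL) whose maximal AVM exceeds 30 g
#'   (`avm_over_30g`) -- beyond what saturating +/-16 g or +/-8 g
#'   accelerometers can produce on all three axes at once;
#' * any **fall** record whose maximal AVM is below 1.1 g
#'   (`fall_peak_under_1p1g`) -- barely above the 1 g rest level, so no
#'   impact can have been recorded.  ADL records are never excluded by
#'   this rule.
#'
#' Both bounds are strict; a record sitting exactly on a bound is kept.
#'
#' @param records An `accel_dataset` or list of [accel_record()]s
#'   (non-empty).
#' @return A `qc_report`: list with `kept` (record ids, input order
#'   preserved) and `excluded` (data frame `record_id`, `reason`).
#' @export
apply_qc_filters <- function(records) {
  records <- as_record_list(records)
  if (!length(records)) stop("apply_qc_filters: empty record collection")
  ids <- vapply(records, `[[`, character(1), "record_id")
  reasons <- character(0)
  excl_ids <- character(0)
  kept <- character(0)
  for (rec in records) {
    peak <- max(compute_avm(rec)$values)
    if (peak > 30) {
      excl_ids <- c(excl_ids, rec$record_id)
      reasons <- c(reasons, "avm_over_30g")
    } else if (rec$class_label == "fall" && peak < 1.1) {
      excl_ids <- c(excl_ids, rec$record_id)
      reasons <- c(reasons, "fall_peak_under_1p1g")
    } else {
      kept <- c(kept, rec$record_id)
    }
  }
  structure(
    list(kept = kept,
         excluded = data.frame(record_id = excl_ids, reason = reasons,
                               stringsAsFactors = FALSE)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> kept %d, excluded %d\n",
              length(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Write a QC report as CSV
#'
#' One row per input record with columns `record_id, status, reason`.
#'
#' @param report A `qc_report` from [apply_qc_filters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- rbind(
    data.frame(record_id = report$kept, status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(record_id = report$excluded$record_id, status = "excluded",
               reason = report$excluded$reason, stringsAsFactors = FALSE)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Subset a record collection to the QC-kept records
#'
#' @param records An `accel_dataset` or list of [accel_record()]s.
#' @param report Optional precomputed [apply_qc_filters()] result.
#' @return A list of the kept [accel_record()]s, input order preserved.
#' @export
qc_kept_records <- function(records, report = apply_qc_filters(records)) {
  records <- as_record_list(records)
  ids <- vapply(records, `[[`, character(1), "record_id")
  records[ids %in% report$kept]
}
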