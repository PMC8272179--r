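#' Construct a tri-axial acceleration record
#'
#' An `accel_record` holds one labeled recording of a single activity
#' (one fall or one ADL) from a tri-axial accelerometer, with all three
#' channels expressed in g units (1 g = 9.81 m/s^2).
#'
#' @param record_id Unique record identifier.
#' @param ax,ay,az Numeric vectors of equal length: acceleration along
#'   the sensor x/y/z axes, in g.
#' @param fs_hz Sampling frequency in Hz (> 0).
#' @param class_label Either `"fall"` or `"adl"`.
#' @param subject_id Anonymised subject identifier.
#' @param activity_type Free-text activity type (e.g. a template name or
#'   a dataset's activity code); used for per-type error rates.
#'
#' @return An object of class `accel_record`: a list with the arguments
#'   above plus `N`, the number of samples.
#' @export
accel_record <- function(record_id, ax, ay, az, fs_hz,
                         class_label = c("fall", "adl"),
                         subject_id = "S01",
                         activity_type = "unknown") {
  class_label <- match.arg(class_label)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("accel_record '", record_id, "': axis channels have unequal lengths")
  }
  if (n < 2L) {
    stop("accel_record '", record_id, "': need at least 2 samples, got ", n)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("accel_record '", record_id, "': fs_hz must be a positive number")
  }
  bad <- which(!(is.finite(ax) & is.finite(ay) & is.finite(az)))
  if (length(bad)) {
    stop("accel_record '", record_id, "': non-finite sample at index ", bad[1L])
  }
  structure(
    list(record_id = as.character(record_id),
         subject_id = as.character(subject_id),
         activity_type = as.character(activity_type),
         class_label = class_label,
         fs_hz = as.numeric(fs_hz),
         ax = ax, ay = ay, az = az, N = n),
    class = "accel_record"
  )
}

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf("<accel_record %s> %s/%s  %d samples @ %g Hz (%.2f s)\n",
              x$record_id, x$class_label, x$activity_type,
              x$N, x$fs_hz, x$N / x$fs_hz))
  invisible(x)
}

#' Duration of a record in seconds
#' @param record An [accel_record()].
#' @return Length of the record in seconds.
#' @export
record_duration <- function(record) record$N / record$fs_hz

#' Write one record to CSV
#'
#' The on-disk dialect is a plain CSV with header columns
#' `time_s, ax_g, ay_g, az_g`.
#'
#' @param record An [accel_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  df <- data.frame(
    time_s = (seq_len(record$N) - 1L) / record$fs_hz,
    ax_g = record$ax, ay_g = record$ay, az_g = record$az
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one record from CSV
#'
#' Reads the `time_s, ax_g, ay_g, az_g` dialect written by
#' [write_record_csv()].  Metadata not stored in the signal file is
#' supplied by the caller (normally from a manifest row).
#'
#' @param path CSV file path.
#' @inheritParams accel_record
#' @return An [accel_record()].
#' @export
read_record_csv <- function(path, record_id, fs_hz,
                            class_label = c("fall", "adl"),
                            subject_id = "S01", activity_type = "unknown") {
  df <- read.csv(path)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df))) {
    stop("record CSV '", path, "' lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  accel_record(record_id, df$ax_g, df$ay_g, df$az_g, fs_hz,
               class_label = class_label, subject_id = subject_id,
               activity_type = activity_type)
}

#' Write a dataset (records + manifest + config) to a directory
#'
#' One CSV per record plus `manifest.csv` with columns
#' `record_id, subject_id, activity_type, class, fs_hz, path, error_type`
#' (`error_type` is the generator's ground-truth flag for injected
#' sensor-error records) and, when the dataset carries a generator
#' configuration, `config.yaml`.
#'
#' @param dataset An `accel_dataset` as returned by [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "accel_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- dataset$manifest
  man$path <- file.path("records", paste0(man$record_id, ".csv"))
  rec_dir <- file.path(dir, "records")
  if (!dir.exists(rec_dir)) dir.create(rec_dir)
  for (i in seq_along(dataset$records)) {
    write_record_csv(dataset$records[[i]], file.path(dir, man$path[i]))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(dataset$config)) {
    write_generator_config(dataset$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the record CSVs.
#' @return An `accel_dataset` (list with `records` and `manifest`).
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"),
                  colClasses = c(record_id = "character",
                                 subject_id = "character"))
  records <- lapply(seq_len(nrow(man)), function(i) {
    read_record_csv(file.path(dir, man$path[i]),
                    record_id = man$record_id[i], fs_hz = man$fs_hz[i],
                    class_label = man$class[i], subject_id = man$subject_id[i],
                    activity_type = man$activity_type[i])
  })
  names(records) <- man$record_id
  structure(list(records = records, manifest = man, config = NULL),
            class = "accel_dataset")
}

#' @export
print.accel_dataset <- function(x, ...) {
  tab <- table(x$manifest$class)
  cat(sprintf("<accel_dataset> %d records (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Coerce a dataset or plain list of records to a list of accel_record.
as_record_list <- function(records) {
  if (inherits(records, "accel_dataset")) return(records$records)
  if (inherits(records, "accel_record")) return(list(records))
  stopifnot(is.list(records), all(vapply(records, inherits, logical(1),
                                         "accel_record")))
  records
}
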