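#' Read an RR/NN interval series from CSV
#'
#' Three layouts are accepted. `time_s,nn_ms`: one row per interval, with
#' the beat time (s) closing the interval and the interval itself (ms) --
#' the format written by [write_rr()], valid for cleaned series whose
#' intervals are no longer contiguous. `time_s` only: raw beat times;
#' intervals are derived by differencing. `nn_ms` only: intervals; beat
#' times are reconstructed cumulatively from 0.
#'
#' @param path Path to a CSV file.
#' @param animal_id Label attached to the series (defaults to the file stem).
#' @return An [rr_series()] with `cleaned = FALSE`.
#' @export
read_rr <- function(path, animal_id = NULL) {
  if (is.null(animal_id)) {
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) mhrv_error("parse_error", conditionMessage(e))
  )
  if (nrow(df) == 0) {
    mhrv_error("empty_input_error", sprintf("no data rows in %s", path))
  }
  has_t <- "time_s" %in% names(df)
  has_nn <- "nn_ms" %in% names(df) && !all(is.na(df$nn_ms))
  if (has_t) {
    tt <- as.numeric(df$time_s)
    bad <- which(diff(tt) <= 0)
    if (length(bad) > 0) {
      mhrv_error(
        "parse_error",
        sprintf("%s: beat times not strictly increasing at row %d",
                path, bad[1] + 1) # data-row index of the offending time
      )
    }
    if (has_nn) {
      rr_series(beat_times = tt, intervals = as.numeric(df$nn_ms),
                animal_id = animal_id)
    } else {
      rr_series(beat_times = tt, animal_id = animal_id)
    }
  } else if (has_nn) {
    rr_series(intervals = as.numeric(df$nn_ms), animal_id = animal_id)
  } else {
    mhrv_error(
      "parse_error",
      sprintf("%s: expected columns `time_s,nn_ms`, `time_s` or `nn_ms`",
              path)
    )
  }
}

#' Write an RR series to CSV
#'
#' Writes `time_s,nn_ms` rows (one per interval, timestamped at the closing
#' beat). `read_rr()` of the output reproduces the intervals exactly up to
#' double-precision text round-trip.
#'
#' @param rr An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(
    time_s = format(rr$interval_times, digits = 17, scientific = FALSE,
                    trim = TRUE),
    nn_ms = format(rr$intervals, digits = 17, scientific = FALSE, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.manifest_levels <- list(
  age_group = c("young", "old"),
  temperature = c("20C", "30C"),
  state = c("basal", "intrinsic")
)

#' Read and validate a cohort manifest
#'
#' The manifest assigns each recording to one cell of the 2x2x2 study
#' design: age group (young/old), ambient temperature (20C = standard
#' laboratory temperature, 30C = thermoneutrality), and autonomic state
#' (basal, or intrinsic after double autonomic blockade).
#'
#' @param path CSV with columns `animal_id, age_group, temperature, state,
#'   path`.
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Validate a cohort manifest data frame
#'
#' @param df Data frame with the five manifest columns.
#' @return `df` with class `cohort_manifest` prepended.
#' @export
validate_manifest <- function(df) {
  required <- c("animal_id", "age_group", "temperature", "state", "path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    mhrv_error(
      "validation_error",
      sprintf("manifest missing columns: %s",
              paste(missing_cols, collapse = ", "))
    )
  }
  for (col in names(.manifest_levels)) {
    allowed <- .manifest_levels[[col]]
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad) > 0) {
      mhrv_error(
        "validation_error",
        sprintf("manifest column %s has unknown value(s) %s; allowed: %s",
                col, paste(sQuote(bad), collapse = ", "),
                paste(allowed, collapse = ", "))
      )
    }
  }
  key <- paste(df$animal_id, df$temperature, df$state, sep = "|")
  if (anyDuplicated(key)) {
    mhrv_error(
      "validation_error",
      sprintf("duplicate (animal_id, temperature, state) key: %s",
              key[duplicated(key)][1])
    )
  }
  n_ages <- tapply(df$age_group, df$animal_id,
                   function(a) length(unique(a)))
  if (any(n_ages > 1)) {
    mhrv_error(
      "validation_error",
      sprintf("animal %s assigned to more than one age_group",
              names(n_ages)[which(n_ages > 1)[1]])
    )
  }
  class(df) <- c("cohort_manifest", class(df))
  df
}

# column order of the flat per-recording metric table
.hrv_table_columns <- c(
  "animal_id", "age_group", "temperature", "state", "n_beats",
  "mean_nn_ms", "mean_hr_bpm", "sdnn_ms", "cv_pct", "sd1_ms", "sd2_ms",
  "total_ms2", "vlf_ms2", "lf_ms2", "hf_ms2",
  "beta", "mse", "dfa_alpha", "hurst", "incomplete"
)

#' Flatten HRV records to a per-recording metric table
#'
#' @param records A list of `hrv_record` objects (see [analyze_recording()]).
#' @return A data frame, one row per recording, with one column per metric.
#' @export
hrv_table <- function(records) {
  if (inherits(records, "hrv_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "hrv_record"))
    td <- rec$time
    bp <- rec$bands
    nl <- rec$nonlinear
    data.frame(
      animal_id = rec$key[["animal_id"]],
      age_group = rec$key[["age_group"]],
      temperature = rec$key[["temperature"]],
      state = rec$key[["state"]],
      n_beats = if (is.null(td)) NA_integer_ else td$n_beats,
      mean_nn_ms = if (is.null(td)) NA_real_ else td$mean_nn,
      mean_hr_bpm = if (is.null(td)) NA_real_ else td$mean_hr,
      sdnn_ms = if (is.null(td)) NA_real_ else td$sdnn,
      cv_pct = if (is.null(td)) NA_real_ else td$cv,
      sd1_ms = if (is.null(td)) NA_real_ else td$sd1,
      sd2_ms = if (is.null(td)) NA_real_ else td$sd2,
      total_ms2 = if (is.null(bp)) NA_real_ else bp$total,
      vlf_ms2 = if (is.null(bp)) NA_real_ else bp$vlf,
      lf_ms2 = if (is.null(bp)) NA_real_ else bp$lf,
      hf_ms2 = if (is.null(bp)) NA_real_ else bp$hf,
      beta = if (is.null(nl)) NA_real_ else nl$beta,
      mse = if (is.null(nl)) NA_real_ else nl$mse,
      dfa_alpha = if (is.null(nl)) NA_real_ else nl$dfa_alpha,
      hurst = if (is.null(nl)) NA_real_ else nl$hurst,
      incomplete = rec$incomplete,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    df <- as.data.frame(
      setNames(rep(list(logical(0)), length(.hrv_table_columns)),
               .hrv_table_columns)
    )
    return(df)
  }
  do.call(rbind, rows)
}

#' Write a per-recording HRV metric table to CSV
#'
#' Numeric values are written with full double precision so the table
#' round-trips well beyond 6 significant digits.
#'
#' @param records List of `hrv_record` objects, or a data frame already in
#'   table form.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hrv_table <- function(records, path) {
  df <- if (is.data.frame(records)) records else hrv_table(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", format(x, digits = 17, scientific = FALSE,
                                trim = TRUE))
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-recording HRV metric table written by [write_hrv_table()]
#' @param path CSV path.
#' @return Data frame with the metric columns as numerics.
#' @export
read_hrv_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
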