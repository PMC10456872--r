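#' Read a raw multi-channel record from CSV
#'
#' Expects columns `time_s`, `ecg`, `bp`, `rf` with uniformly spaced
#' timestamps.
#'
#' @param file path to the CSV file.
#' @param fs sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param subject_id identifier (defaults to the file name).
#' @return a [physio_record()].
#' @export
read_physio_csv <- function(file, fs = NULL, subject_id = NULL) {
  if (!file.exists(file)) stop("input file not found: ", file)
  df <- read.csv(file, check.names = FALSE)
  need <- c("time_s", "ecg", "bp", "rf")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(fs)) {
    dt <- diff(df$time_s)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("time_s is not uniformly spaced; supply fs explicitly")
    fs <- 1 / dt[1]
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.csv$", "", basename(file))
  physio_record(list(ecg = df$ecg, bp = df$bp, rf = df$rf), fs = fs,
                subject_id = subject_id)
}

#' Write a raw record to CSV
#' @param record a [physio_record()] with channels `ecg`, `bp`, `rf`.
#' @param file output path.
#' @export
write_physio_csv <- function(record, file) {
  stopifnot(inherits(record, "physio_record"))
  n <- length(record$channels[[1]])
  df <- data.frame(time_s = (seq_len(n) - 1) / record$fs,
                   ecg = record$channels$ecg, bp = record$channels$bp,
                   rf = record$channels$rf)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write event series to a tidy CSV
#'
#' Long format with columns `subject_id`, `kind`, `t_s`, `value`; several
#' subjects may share one file.
#'
#' @param series_list named list of [event_series()] objects (any subset
#'   of `bbi`, `sbp`, `dbp`, `tt`).
#' @param subject_id identifier written into every row.
#' @param file output path; rows are appended when `append = TRUE`.
#' @param append append to an existing file without rewriting the header.
#' @export
write_event_series <- function(series_list, subject_id, file,
                               append = FALSE) {
  rows <- do.call(rbind, lapply(series_list, function(s)
    data.frame(subject_id = subject_id, kind = s$kind,
               t_s = s$timestamps, value = s$values,
               stringsAsFactors = FALSE)))
  if (append && file.exists(file)) {
    utils::write.table(rows, file, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  } else {
    write.csv(rows, file, row.names = FALSE)
  }
  invisible(file)
}

#' Read tidy event-series CSV
#'
#' @param file path written by [write_event_series()].
#' @return named list (by subject) of named lists of [event_series()]
#'   (`bbi`, `sbp`, `dbp`, `tt` as present).
#' @export
read_event_series <- function(file) {
  if (!file.exists(file)) stop("input file not found: ", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "kind", "t_s", "value")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  out <- list()
  for (sid in unique(df$subject_id)) {
    sl <- list()
    dsub <- df[df$subject_id == sid, ]
    for (k in unique(dsub$kind)) {
      dk <- dsub[dsub$kind == k, ]
      ord <- order(dk$t_s)
      sl[[tolower(k)]] <- event_series(k, dk$value[ord], dk$t_s[ord])
    }
    out[[sid]] <- sl
  }
  out
}

#' Write a subject x index feature table to CSV
#'
#' @param features data frame from [characterize_cohort()].
#' @param file output path; a JSON schema listing the feature names in
#'   canonical order is written alongside as `<file>.schema.json`.
#' @export
write_feature_table <- function(features, file) {
  write.csv(features, file, row.names = FALSE)
  schema <- list(n_indices = length(feature_schema()),
                 indices = feature_schema())
  jsonlite::write_json(schema, paste0(file, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Read a feature table written by [write_feature_table()]
#' @param file CSV path.
#' @return data frame with feature names preserved verbatim.
#' @export
read_feature_table <- function(file) {
  if (!file.exists(file)) stop("input file not found: ", file)
  read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
}
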