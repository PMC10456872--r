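#' Construct a physiological event series
#'
#' An event series holds one beat- or breath-indexed physiological quantity:
#' beat-to-beat intervals (`BBI`, ms), per-beat systolic or diastolic blood
#' pressure (`SBP`/`DBP`, mmHg), or respiratory cycle durations (`TT`, s).
#' Event-indexed series carry irregular timestamps; resampled series carry a
#' uniform grid rate in `grid_hz`.
#'
#' @param kind one of `"BBI"`, `"SBP"`, `"DBP"`, `"TT"`.
#' @param values numeric vector of finite values; `BBI` and `TT` must be
#'   strictly positive.
#' @param timestamps event times in seconds, strictly increasing, same
#'   length as `values`.
#' @param grid_hz `NULL` for event-indexed series, or the uniform grid rate
#'   (1 or 0.25 Hz) for resampled series.
#' @return an object of class `event_series`.
#' @export
event_series <- function(kind, values, timestamps, grid_hz = NULL) {
  kind <- match.arg(kind, c("BBI", "SBP", "DBP", "TT"))
  values <- as.numeric(values)
  timestamps <- as.numeric(timestamps)
  if (length(values) != length(timestamps))
    stop("values and timestamps must have the same length")
  if (length(values) && !all(is.finite(values)))
    stop("event series values must be finite")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (kind %in% c("BBI", "TT") && length(values) && any(values <= 0))
    stop(kind, " values must be strictly positive")
  if (!is.null(grid_hz)) {
    if (!grid_hz %in% c(1, 0.25))
      stop("grid_hz must be 1 or 0.25")
    if (length(timestamps) > 1 &&
        max(abs(diff(timestamps) - 1 / grid_hz)) > 1e-6)
      stop("resampled series must have uniform spacing 1/grid_hz")
  }
  structure(list(kind = kind, values = values, timestamps = timestamps,
                 grid_hz = grid_hz),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  grid <- if (is.null(x$grid_hz)) "event-indexed" else
    sprintf("%g Hz grid", x$grid_hz)
  cat(sprintf("<event_series %s: %d values, %s, span %.1f s>\n",
              x$kind, length(x$values), grid,
              if (length(x$timestamps)) diff(range(x$timestamps)) else 0))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$values)

#' Construct a raw multi-channel physiological record
#'
#' @param channels named list of equal-length numeric sample vectors,
#'   typically `ecg` (mV), `bp` (mmHg) and `rf` (arbitrary flow units).
#' @param fs sampling rate in Hz.
#' @param subject_id identifier string.
#' @return an object of class `physio_record`.
#' @export
physio_record <- function(channels, fs, subject_id = "subject") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1)
    stop("all channels must have the same length")
  structure(list(channels = lapply(channels, as.numeric), fs = fs,
                 subject_id = subject_id, duration_s = n / fs),
            class = "physio_record")
}

#' @export
print.physio_record <- function(x, ...) {
  cat(sprintf("<physio_record '%s': %s; fs %g Hz, %.1f s>\n",
              x$subject_id, paste(names(x$channels), collapse = ", "),
              x$fs, x$duration_s))
  invisible(x)
}

#' Remove linear trends and 3-SD outliers from raw channels
#'
#' Each channel has its least-squares linear trend subtracted.  Samples
#' deviating from the (detrended) channel mean by at least three standard
#' deviations are treated as artifacts and replaced by linear interpolation
#' between their neighbours, so the uniform sampling grid is preserved.
#'
#' @param record a [physio_record()].
#' @param keep_mean if `TRUE`, the channel mean is added back after
#'   detrending, preserving physical levels (useful for blood pressure,
#'   where systolic/diastolic values are read in mmHg).
#' @return a cleaned `physio_record`; the per-channel number of replaced
#'   samples is attached as attribute `"n_outliers"`.
#' @export
detrend_and_clean <- function(record, keep_mean = FALSE) {
  stopifnot(inherits(record, "physio_record"))
  n_out <- integer(length(record$channels))
  names(n_out) <- names(record$channels)
  out <- record
  for (ch in names(record$channels)) {
    x <- record$channels[[ch]]
    if (length(x) == 0) stop("empty channel '", ch, "'")
    if (sd(x) == 0) stop("degenerate channel '", ch, "'")
    t <- seq_along(x)
    fit <- stats::lm.fit(cbind(1, t), x)
    mu <- mean(x)
    y <- fit$residuals
    s <- sd(y)
    bad <- abs(y - mean(y)) >= 3 * s
    n_out[ch] <- sum(bad)
    if (n_out[ch] > 0.2 * length(x))
      warning(sprintf("channel '%s': %.1f%% of samples flagged as outliers",
                      ch, 100 * n_out[ch] / length(x)))
    if (any(bad)) {
      good <- which(!bad)
      if (length(good) < 2) stop("degenerate channel '", ch, "'")
      y[bad] <- approx(good, y[good], xout = which(bad), rule = 2)$y
    }
    out$channels[[ch]] <- if (keep_mean) y + mu else y
  }
  attr(out, "n_outliers") <- n_out
  out
}

#' Detect R peaks in an ECG channel
#'
#' A Pan-Tompkins-style detector: 5--15 Hz band-pass, squared derivative,
#' 150 ms moving-window integration, fixed-quantile threshold with a 250 ms
#' refractory period, and peak refinement on the band-passed signal.
#'
#' @param ecg numeric ECG sample vector.
#' @param fs sampling rate in Hz, at least 100.
#' @return strictly increasing R-peak times in seconds.  Intervals outside
#'   the physiological range \[0.25, 3\] s are flagged in attribute
#'   `"flagged"` (indices of the offending intervals).
#' @export
detect_rpeaks <- function(ecg, fs) {
  if (fs < 100) stop("fs must be at least 100 Hz")
  if (length(ecg) < 2 * fs) stop("need at least 2 s of ECG")
  if (sd(ecg) == 0) stop("no QRS detected")
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, ecg - mean(ecg))
  sq <- c(diff(x), 0)^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * quantile(integ, 0.99)
  if (thr <= 0) stop("no QRS detected")
  n <- length(integ)
  core <- 2:(n - 1)
  cand <- core[integ[core] > thr & integ[core] >= integ[core - 1] &
               integ[core] >= integ[core + 1]]
  if (length(cand) == 0) stop("no QRS detected")
  # refractory: greedily keep the larger of peaks closer than 250 ms
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) / fs >= 0.25) {
      keep <- c(keep, i)
      last <- i
    } else if (integ[i] > integ[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  # refine to the extremum of the band-passed ECG near each integrated peak
  half <- round(0.1 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(abs(x[lo:hi])) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  times <- (peaks - 1) / fs
  if (length(times) < 2) stop("no QRS detected")
  iv <- diff(times)
  flagged <- which(iv < 0.25 | iv > 3)
  attr(times, "flagged") <- flagged
  times
}

#' Beat-to-beat intervals from R-peak times
#'
#' @param rpeak_times strictly increasing R-peak times in seconds (at
#'   least 3).
#' @return an [event_series()] of kind `BBI` (ms); each interval is stamped
#'   with the time of its closing beat.
#' @export
extract_bbi <- function(rpeak_times) {
  t <- as.numeric(rpeak_times)
  if (length(t) < 3) stop("need at least 3 R peaks")
  if (any(diff(t) <= 0)) stop("R-peak times must be strictly increasing")
  event_series("BBI", diff(t) * 1000, t[-1])
}

#' Per-beat systolic and diastolic pressure from a continuous BP channel
#'
#' For each inter-beat window `[t_i, t_{i+1})` the systolic value is the
#' window maximum and the diastolic value the window minimum.  Windows that
#' contain no samples are skipped with a warning.
#'
#' @param bp numeric blood-pressure sample vector (mmHg).
#' @param fs sampling rate in Hz.
#' @param rpeak_times R-peak times in seconds spanning the BP record.
#' @return a list with elements `sbp` and `dbp`, both [event_series()]
#'   stamped at the opening beat of each window.
#' @export
extract_sbp_dbp <- function(bp, fs, rpeak_times) {
  t <- as.numeric(rpeak_times)
  if (length(t) < 2) stop("need at least 2 R peaks")
  dur <- length(bp) / fs
  if (min(t) < 0 || max(t) > dur)
    stop("R-peak times fall outside the BP record")
  st <- (seq_along(bp) - 1) / fs
  win <- findInterval(st, t)        # 0 before first beat, i within [t_i, t_{i+1})
  smax <- tapply(bp, win, max)
  smin <- tapply(bp, win, min)
  ids <- as.integer(names(smax))
  wanted <- seq_len(length(t) - 1)
  present <- wanted[wanted %in% ids]
  if (length(present) < length(wanted))
    warning(sprintf("%d beat window(s) contained no BP samples; skipped",
                    length(wanted) - length(present)))
  sel <- as.character(present)
  list(sbp = event_series("SBP", as.numeric(smax[sel]), t[present]),
       dbp = event_series("DBP", as.numeric(smin[sel]), t[present]))
}

#' Respiratory cycle durations from a respiratory-flow channel
#'
#' Breath onsets are the negative-to-positive zero crossings of the flow
#' signal low-passed at 1 Hz; crossing times are refined by linear
#' interpolation between samples.  The cycle duration TT is the interval
#' between successive onsets.
#'
#' @param rf numeric respiratory-flow sample vector.
#' @param fs sampling rate in Hz.
#' @return an [event_series()] of kind `TT` (s), stamped at the closing
#'   onset of each cycle.
#' @export
extract_tt <- function(rf, fs) {
  if (length(rf) < 2) stop("need at least 2 samples")
  if (sd(rf) == 0) stop("fewer than 2 breath onsets detected")
  x <- rf - mean(rf)
  if (fs > 2.5) {
    lp <- signal::butter(4, 1 / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  n <- length(x)
  i <- which(x[-n] < 0 & x[-1] >= 0)
  if (length(i) < 2) stop("fewer than 2 breath onsets detected")
  # refine on the unfiltered (demeaned) flow: the low-pass fixes which
  # crossings are breaths, the raw signal fixes when they happen
  raw <- rf - mean(rf)
  half <- max(1L, round(0.25 * fs))
  i <- vapply(i, function(j) {
    lo <- max(1L, j - half); hi <- min(n - 1L, j + half)
    cand <- lo - 1L + which(raw[lo:hi] < 0 & raw[(lo + 1):(hi + 1)] >= 0)
    as.integer(if (length(cand) == 0) j else cand[which.min(abs(cand - j))])
  }, integer(1))
  i <- sort(unique(i))
  sig <- raw
  frac <- -sig[i] / (sig[i + 1] - sig[i])
  frac[!is.finite(frac)] <- 0
  onsets <- (i - 1 + frac) / fs
  event_series("TT", diff(onsets), onsets[-1])
}

#' Resample an event series onto a uniform grid
#'
#' Linear interpolation of `(timestamp, value)` onto a 1 Hz grid covering
#' the series span (or a caller-supplied common span for synchronization
#' across series).  The 0.25 Hz grid is obtained from the 1 Hz grid by
#' zero-phase 8th-order FIR low-pass filtering (0.1 Hz cutoff) followed by
#' keeping every 4th sample, so cardiac-band power does not alias into the
#' respiratory analysis.
#'
#' @param series an [event_series()] with at least 2 events.
#' @param target_hz 1.0 or 0.25.
#' @param span optional `c(start, end)` seconds defining the common record
#'   span; defaults to the series' own span.
#' @return a resampled `event_series` with `grid_hz` set.
#' @export
resample_series <- function(series, target_hz, span = NULL) {
  stopifnot(inherits(series, "event_series"))
  if (!target_hz %in% c(1, 0.25))
    stop("target_hz must be 1.0 or 0.25")
  if (length(series) < 2) stop("need at least 2 events to resample")
  if (is.null(span)) span <- range(series$timestamps)
  g1 <- seq(ceiling(span[1]), floor(span[2]), by = 1)
  if (length(g1) < 2) stop("common span too short to resample")
  v1 <- approx(series$timestamps, series$values, xout = g1, rule = 2)$y
  if (target_hz == 1)
    return(event_series(series$kind, v1, g1, grid_hz = 1))
  if (length(v1) < 27) stop("series too short to decimate to 0.25 Hz")
  fir <- signal::fir1(8, 0.2, type = "low")
  # demean + reflection padding suppresses zero-state edge transients
  n1 <- length(v1)
  mu <- mean(v1)
  x <- v1 - mu
  pad <- 24L
  xa <- c(rev(x[2:(pad + 1)]), x, rev(x[(n1 - pad):(n1 - 1)]))
  vf <- signal::filtfilt(fir, xa)[(pad + 1):(pad + n1)] + mu
  idx <- seq(1, length(v1), by = 4)
  vals <- vf[idx]
  # low-pass ringing must not push BBI/TT through zero on pathological input
  if (series$kind %in% c("BBI", "TT")) vals <- pmax(vals, .Machine$double.eps)
  event_series(series$kind, vals, g1[idx], grid_hz = 0.25)
}

#' Synchronize the four event series onto a common grid
#'
#' All series are linearly interpolated onto one 1 Hz grid running from the
#' latest first event to the earliest last event across the set, then
#' decimated to 0.25 Hz (see [resample_series()]).
#'
#' @param series_list named list with elements `bbi`, `sbp`, `dbp`, `tt`
#'   (event-indexed [event_series()]).
#' @param target_hz grid rate for the returned series, 1.0 or 0.25.
#' @return named list of resampled series sharing one grid.
#' @export
sync_series <- function(series_list, target_hz = 0.25) {
  need <- c("bbi", "sbp", "dbp", "tt")
  if (!all(need %in% names(series_list)))
    stop("series_list must contain bbi, sbp, dbp, tt")
  sl <- series_list[need]
  span <- c(max(vapply(sl, function(s) s$timestamps[1], numeric(1))),
            min(vapply(sl, function(s) s$timestamps[length(s)], numeric(1))))
  if (diff(span) <= 2) stop("series do not overlap long enough to synchronize")
  lapply(sl, resample_series, target_hz = target_hz, span = span)
}
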