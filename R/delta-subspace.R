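#' First-difference (delta) series of an event series
#'
#' Beat/breath-scale variability is captured by the difference between
#' consecutive values, `dX[n] = X[n+1] - X[n]`.
#'
#' @param x an [event_series()] (typically resampled) or a numeric vector.
#' @return an object of class `delta_series` with fields `kind`, `values`,
#'   `n` (= source length - 1) and `normalized`.
#' @export
delta <- function(x) {
  kind <- "dX"
  if (inherits(x, "event_series")) {
    kind <- paste0("d", x$kind)
    x <- x$values
  }
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 values to difference")
  structure(list(kind = kind, values = diff(x), n = length(x) - 1L,
                 normalized = FALSE),
            class = "delta_series")
}

#' @export
print.delta_series <- function(x, ...) {
  cat(sprintf("<delta_series %s: n = %d%s>\n", x$kind, x$n,
              if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

#' Z-score a delta series
#'
#' Centers to zero mean and scales to unit variance, making sub-space
#' thresholds and indices comparable across subjects.
#'
#' @param d a [delta()] series with positive variance.
#' @return the normalized `delta_series`.
#' @export
normalize_delta <- function(d) {
  stopifnot(inherits(d, "delta_series"))
  s <- sd(d$values)
  if (!is.finite(s) || s == 0) stop("constant delta series")
  d$values <- (d$values - mean(d$values)) / s
  d$normalized <- TRUE
  d
}

#' Vascular-change threshold
#'
#' The no-change band around zero is a fraction `alpha` of the half-range
#' of the vascular delta series: `Th = alpha * (max(dXv) - min(dXv)) / 2`.
#'
#' @param delta_v a normalized vascular [delta()] series (dSBP or dDBP).
#' @param alpha band fraction, strictly between 0 and 1 (default 0.15).
#' @return the threshold `Th` (same units as `delta_v`).
#' @export
vascular_threshold <- function(delta_v, alpha = 0.15) {
  stopifnot(inherits(delta_v, "delta_series"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  rng <- range(delta_v$values)
  if (rng[1] == rng[2]) stop("degenerate delta series: max equals min")
  alpha * (rng[2] - rng[1]) / 2
}

#' Partition a vascular delta series into up / no-change / down sub-spaces
#'
#' Samples with `dXv > Th` are labelled `up`, samples with
#' `-Th <= dXv <= Th` are `nc` (boundary values belong to no-change), and
#' samples with `dXv < -Th` are `down`.
#'
#' @param delta_v a vascular [delta()] series.
#' @param th threshold from [vascular_threshold()], positive.
#' @param alpha the band fraction used to derive `th` (metadata).
#' @param driver `"SBP"` or `"DBP"` (metadata).
#' @return an object of class `subspace_partition` with per-sample `labels`
#'   (factor with levels up/nc/down), `index_sets` (list of index vectors),
#'   `threshold`, `alpha`, `driver` and `n`.
#' @export
partition_subspace <- function(delta_v, th, alpha = NA_real_,
                               driver = c("SBP", "DBP")) {
  stopifnot(inherits(delta_v, "delta_series"))
  driver <- match.arg(driver)
  if (!is.numeric(th) || length(th) != 1 || th <= 0)
    stop("threshold must be positive")
  v <- delta_v$values
  lab <- ifelse(v > th, "up", ifelse(v < -th, "down", "nc"))
  labels <- factor(lab, levels = c("up", "nc", "down"))
  structure(list(driver = driver, threshold = th, alpha = alpha,
                 labels = labels,
                 index_sets = list(up = which(labels == "up"),
                                   nc = which(labels == "nc"),
                                   down = which(labels == "down")),
                 n = length(v)),
            class = "subspace_partition")
}

#' @export
print.subspace_partition <- function(x, ...) {
  cat(sprintf(
    "<subspace_partition %s: n = %d, Th = %.4g (alpha = %s)\n  up %d | nc %d | down %d>\n",
    x$driver, x$n, x$threshold,
    if (is.na(x$alpha)) "?" else format(x$alpha),
    length(x$index_sets$up), length(x$index_sets$nc),
    length(x$index_sets$down)))
  invisible(x)
}

#' Cardiorespiratory point sets per vascular sub-space
#'
#' Selects, for each sub-space label, the `(dBBI, dTT)` pairs at the sample
#' indices carrying that label.  All three delta series must live on the
#' same synchronized grid.
#'
#' @param partition a [partition_subspace()] result for the vascular driver.
#' @param dbbi,dtt [delta()] series of the cardiac and respiratory signals.
#' @return named list (`up`, `nc`, `down`) of two-column matrices with
#'   columns `dBBI`, `dTT`.
#' @export
align_triplet <- function(partition, dbbi, dtt) {
  stopifnot(inherits(partition, "subspace_partition"),
            inherits(dbbi, "delta_series"), inherits(dtt, "delta_series"))
  if (dbbi$n != partition$n || dtt$n != partition$n)
    stop("unsynchronized series: delta lengths differ from partition length")
  lapply(partition$index_sets, function(idx) {
    m <- cbind(dBBI = dbbi$values[idx], dTT = dtt$values[idx])
    rownames(m) <- NULL
    m
  })
}
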