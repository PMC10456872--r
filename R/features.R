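#' Descriptive statistics of a delta sub-space sample
#'
#' @param x numeric vector of delta values falling in one sub-space.
#' @return named vector with `m` (mean), `sd` (sample SD, n-1 denominator),
#'   `K` (Pearson kurtosis, normal = 3), `Sk` (Fisher skewness), `IQR`
#'   (Q3 - Q1 with linear-interpolation quantiles) and `CV`
#'   (`sd/m * 100`; `NA` when the mean is zero).  Moments needing more
#'   data than supplied (`sd` with n < 2, `K`/`Sk` with n < 4) are `NA`.
#' @export
subspace_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0)
    return(c(m = NA_real_, sd = NA_real_, K = NA_real_, Sk = NA_real_,
             IQR = NA_real_, CV = NA_real_))
  m <- mean(x)
  s <- if (n >= 2) sd(x) else NA_real_
  K <- Sk <- NA_real_
  if (n >= 4 && isTRUE(s > 0)) {
    K <- e1071::kurtosis(x, type = 1) + 3
    Sk <- e1071::skewness(x, type = 1)
  }
  iqr <- if (n >= 2) unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
         else NA_real_
  cv <- if (isTRUE(m != 0) && !is.na(s)) s / m * 100 else NA_real_
  c(m = m, sd = s, K = K, Sk = Sk, IQR = iqr, CV = cv)
}

#' Sub-space occupancy, dispersion and centroid distance
#'
#' @param x delta values of one series restricted to a sub-space.
#' @param n_total total number of grid samples in the partition.
#' @param points two-column matrix of the sub-space's `(dBBI, dTT)` points.
#' @param centroid polygon centroid `c(Cx, Cy)` of the sub-space (may be
#'   `NA` for degenerate polygons).
#' @return named vector with `p` (occupancy probability `|z|/n`), `d`
#'   (mean absolute deviation of `x` from its own mean) and `dc` (mean
#'   Euclidean distance of the points to the centroid).
#' @export
occupancy_and_distance <- function(x, n_total, points, centroid) {
  nz <- length(x)
  if (nz == 0)
    return(c(p = NA_real_, d = NA_real_, dc = NA_real_))
  p <- nz / n_total
  d <- mean(abs(x - mean(x)))
  dc <- if (anyNA(centroid)) NA_real_ else {
    pts <- as.matrix(points)
    mean(sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
  }
  c(p = p, d = d, dc = dc)
}

.STAT_NAMES <- c("m", "sd", "K", "Sk", "IQR", "CV")
.SERIES_STATS <- c(.STAT_NAMES, "p", "d")
.MORPH_STATS <- c("A", "An", "Av", "n", "dc", "theta", "beta",
                  "thetabeta", "pr", "Ar")

#' Canonical feature-name schema
#'
#' The 168 index names in canonical order: for each vascular driver
#' (SBP, DBP) and sub-space (`u`, `nc`, `d`), 8 statistics of dBBI, 8 of
#' dTT and 10 joint polygon-morphology indices (26 x 6 = 156), followed by
#' 6 global descriptive statistics for each of dSBP and dDBP (12).  Names
#' follow the pattern `"{driver}-d{series}{stat}-{z}"`, e.g.
#' `"SBP-dTTm-d"` or `"DBP-dBBI_TTAv-u"`.
#'
#' @return character vector of length 168.
#' @export
feature_schema <- function() {
  out <- character(0)
  for (driver in c("SBP", "DBP")) {
    for (z in c("u", "nc", "d")) {
      out <- c(out,
               paste0(driver, "-dBBI", .SERIES_STATS, "-", z),
               paste0(driver, "-dTT", .SERIES_STATS, "-", z),
               paste0(driver, "-dBBI_TT", .MORPH_STATS, "-", z))
    }
  }
  c(out, paste0("dSBP", .STAT_NAMES), paste0("dDBP", .STAT_NAMES))
}

# one (driver, sub-space) block of 26 indices
.subspace_block <- function(dbbi_z, dtt_z, points, n_total, containment) {
  model <- fit_polygon(points, containment)
  ctr <- model$centroid
  sb <- subspace_stats(dbbi_z)
  st <- subspace_stats(dtt_z)
  ob <- occupancy_and_distance(dbbi_z, n_total, points, ctr)
  ot <- occupancy_and_distance(dtt_z, n_total, points, ctr)
  if (!model$degenerate) {
    tri <- model$triangles
    morph <- c(A = model$area,
               An = model$area / model$n_kept,
               Av = model$area / model$n_vertices,
               n = as.numeric(model$n_vertices),
               dc = unname(ob["dc"]),
               theta = mean(tri$theta, na.rm = TRUE),
               beta = mean(tri$beta, na.rm = TRUE),
               thetabeta = NA_real_,
               pr = mean(tri$occupancy),
               Ar = mean(tri$Ar))
    morph["thetabeta"] <- morph["theta"] - morph["beta"]
  } else {
    morph <- setNames(rep(NA_real_, 10), .MORPH_STATS)
  }
  list(values = c(setNames(c(sb, ob["p"], ob["d"]), .SERIES_STATS),
                  setNames(c(st, ot["p"], ot["d"]), .SERIES_STATS),
                  morph),
       polygon = model)
}

#' Assemble the per-subject 168-index feature vector
#'
#' @param blocks named list `blocks[[driver]][[z]]` of 26-value blocks as
#'   produced internally by [baro_characterize()].
#' @param global_stats named list with 6-value [subspace_stats()] results
#'   for `dSBP` and `dDBP` (physical units).
#' @return named numeric vector of length 168 in [feature_schema()] order;
#'   unavailable indices are `NA`, never imputed.
#' @export
assemble_features <- function(blocks, global_stats) {
  out <- numeric(0)
  for (driver in c("SBP", "DBP")) {
    for (z in c("u", "nc", "d")) {
      b <- blocks[[driver]][[z]]
      vals <- unname(b)
      out <- c(out, setNames(vals,
               c(paste0(driver, "-dBBI", .SERIES_STATS, "-", z),
                 paste0(driver, "-dTT", .SERIES_STATS, "-", z),
                 paste0(driver, "-dBBI_TT", .MORPH_STATS, "-", z))))
    }
  }
  out <- c(out,
           setNames(unname(global_stats$dSBP), paste0("dSBP", .STAT_NAMES)),
           setNames(unname(global_stats$dDBP), paste0("dDBP", .STAT_NAMES)))
  schema <- feature_schema()
  if (!identical(names(out), schema))
    stop("internal error: feature schema mismatch")
  if (length(out) != 168L)
    stop("internal error: expected 168 indices, got ", length(out))
  out
}

#' Characterize one subject's baroreflex-mediated interactions
#'
#' The core characterization: the four event series are synchronized onto
#' a common 1 Hz grid and decimated to 0.25 Hz; first differences are
#' taken and z-scored per series; for each vascular driver (SBP, DBP) the
#' delta series is partitioned into up / no-change / down sub-spaces by
#' the range-proportional threshold; each sub-space's `(dBBI, dTT)`
#' scatterplot is summarized by a 95%-containment polygon and descriptive
#' statistics.  The result is the 168-index feature vector plus the fitted
#' partitions and polygons.
#'
#' @param series named list with event-indexed [event_series()] elements
#'   `bbi`, `sbp`, `dbp`, `tt`.
#' @param alpha no-change band fraction for [vascular_threshold()]
#'   (default 0.15).
#' @param containment polygon containment fraction (default 0.95).
#' @param subject_id identifier carried into the result.
#' @param pooled_thresholds optional named list `list(SBP =, DBP =)` of
#'   externally computed thresholds (e.g. pooled across a cohort); by
#'   default thresholds are computed per subject.
#' @return an object of class `baro_char` with elements `features` (named
#'   numeric, length 168), `partitions`, `polygons`, `deltas` and `meta`.
#' @seealso [coef.baro_char()], [plot.baro_char()]
#' @export
baro_characterize <- function(series, alpha = 0.15, containment = 0.95,
                              subject_id = "subject",
                              pooled_thresholds = NULL) {
  grid <- sync_series(series, target_hz = 0.25)
  raw_deltas <- lapply(grid, delta)
  deltas <- lapply(raw_deltas, normalize_delta)
  n <- deltas$bbi$n
  zmap <- c(u = "up", nc = "nc", d = "down")
  blocks <- list()
  partitions <- list()
  polygons <- list()
  for (driver in c("SBP", "DBP")) {
    dv <- deltas[[tolower(driver)]]
    th <- if (!is.null(pooled_thresholds)) pooled_thresholds[[driver]]
          else vascular_threshold(dv, alpha)
    part <- partition_subspace(dv, th, alpha = alpha, driver = driver)
    sets <- align_triplet(part, deltas$bbi, deltas$tt)
    blocks[[driver]] <- list()
    polygons[[driver]] <- list()
    for (z in names(zmap)) {
      idx <- part$index_sets[[zmap[z]]]
      blk <- .subspace_block(deltas$bbi$values[idx], deltas$tt$values[idx],
                             sets[[zmap[z]]], n, containment)
      blocks[[driver]][[z]] <- blk$values
      polygons[[driver]][[z]] <- blk$polygon
    }
    partitions[[driver]] <- part
  }
  global_stats <- list(dSBP = subspace_stats(raw_deltas$sbp$values),
                       dDBP = subspace_stats(raw_deltas$dbp$values))
  feats <- assemble_features(blocks, global_stats)
  structure(list(features = feats, partitions = partitions,
                 polygons = polygons, deltas = deltas,
                 meta = list(subject_id = subject_id, alpha = alpha,
                             containment = containment, n_grid = n)),
            class = "baro_char")
}

#' @export
print.baro_char <- function(x, ...) {
  cat(sprintf("<baro_char '%s': %d grid samples, alpha %.2f, containment %.2f>\n",
              x$meta$subject_id, x$meta$n_grid, x$meta$alpha,
              x$meta$containment))
  for (driver in names(x$partitions)) {
    p <- x$partitions[[driver]]
    cat(sprintf("  %s: Th %.3f | up %d, nc %d, down %d\n", driver,
                p$threshold, length(p$index_sets$up),
                length(p$index_sets$nc), length(p$index_sets$down)))
  }
  cat(sprintf("  %d indices (%d missing)\n", length(x$features),
              sum(is.na(x$features))))
  invisible(x)
}

#' Extract the 168-index feature vector
#' @param object a [baro_characterize()] result.
#' @param ... unused.
#' @export
coef.baro_char <- function(object, ...) object$features

#' @export
summary.baro_char <- function(object, ...) {
  print(object)
  f <- object$features
  cat("\nSelected indices:\n")
  sel <- c("SBP-dTTm-d", "SBP-dTTsd-u", "SBP-dBBIsd-nc",
           "SBP-dBBI_TTtheta-u", "SBP-dBBI_TTA-u", "DBP-dBBIp-u")
  print(round(f[sel], 4))
  invisible(object)
}

#' Plot sub-space scatterplots with their containment polygons
#' @param x a [baro_characterize()] result.
#' @param driver `"SBP"` or `"DBP"`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.baro_char <- function(x, driver = c("SBP", "DBP"), ...) {
  driver <- match.arg(driver)
  part <- x$partitions[[driver]]
  sets <- align_triplet(part, x$deltas$bbi, x$deltas$tt)
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  zmap <- c(u = "up", nc = "nc", d = "down")
  for (z in names(zmap)) {
    pts <- sets[[zmap[z]]]
    mod <- x$polygons[[driver]][[z]]
    if (!mod$degenerate) {
      plot(mod, points = pts, main = paste(driver, zmap[z]), ...)
    } else {
      graphics::plot(pts, main = paste(driver, zmap[z], "(degenerate)"),
                     xlab = "dBBI", ylab = "dTT", ...)
    }
  }
  invisible(x)
}
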