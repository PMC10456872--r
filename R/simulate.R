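#' Default per-group simulation parameters
#'
#' Physiological set points for a resting adult: mean heart period 900 ms
#' with 25 ms beat-scale variability, systolic/diastolic set points
#' 120/70 mmHg with a slow (~15 s correlation time) vascular fluctuation of
#' 4 mmHg SD, and a 3.6 s respiratory cycle with 0.3 s variability.
#' Couplings are first-order linear: `bbi_sbp_coupling` is the correlation
#' of the heart-period fluctuation with the vascular fluctuation
#' (baroreflex arm), `tt_sbp_coupling` the correlation of the breath
#' duration with the vascular fluctuation (respiratory arm), and
#' `rsa_weight` the respiratory sinus-arrhythmia share of heart-period
#' variance.
#'
#' @return named list of parameters accepted by [simulate_subject()].
#' @export
sim_group_defaults <- function() {
  list(bbi_mean = 900, bbi_sd = 25,
       sbp_set = 120, sbp_sd = 4, sbp_noise = 0.5,
       dbp_set = 70, dbp_gain = 0.6,
       tt_mean = 3.6, tt_sd = 0.3,
       rsa_weight = 0.3,
       bbi_sbp_coupling = 0.45,
       tt_sbp_coupling = 0.1,
       vasc_tau = 15)
}

# group-difference calibration: change in coupling producing a one-SD shift
# of the corresponding index between groups (fixed by a one-off calibration
# simulation; see the methods vignette)
.TT_COUPLING_PER_SD <- 0.24
.BBI_COUPLING_PER_SD <- -0.175

#' Build a cohort simulation configuration
#'
#' The first named group is the reference; every later group receives the
#' configured effects: its respiratory response to vascular change
#' (`tt_sbp_coupling`) is increased by `effect_tt` index-SD units and its
#' baroreflex coupling (`bbi_sbp_coupling`) is reduced by `effect_bbi`
#' index-SD units, emulating the depressed-respiratory-response /
#' reduced-heart-rate-variability contrast between cardiomyopathy patients
#' and controls.  Set both effects to 0 for an exchangeable (null) cohort.
#'
#' @param n_per_group named integer vector, subjects per group (at least
#'   2 each); names are the group labels.
#' @param duration_s record length in seconds (default 900, a 15-minute
#'   recording).
#' @param fs raw-signal sampling rate in Hz (used only when raw signals
#'   are emitted; default 250).
#' @param effect_tt,effect_bbi group effects in index-SD units (see
#'   above).
#' @param seed base random seed; subject seeds are derived from it.
#' @param group_params optional named list of per-group parameter lists
#'   overriding the defaults entirely.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(CON = 20, CMP = 20),
                       duration_s = 900, fs = 250,
                       effect_tt = 1, effect_bbi = 1,
                       seed = 1, group_params = NULL) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group")
  groups <- names(n_per_group)
  if (is.null(group_params)) {
    group_params <- list()
    for (i in seq_along(groups)) {
      p <- sim_group_defaults()
      if (i > 1) {
        p$tt_sbp_coupling <- p$tt_sbp_coupling +
          .TT_COUPLING_PER_SD * effect_tt
        p$bbi_sbp_coupling <- p$bbi_sbp_coupling +
          .BBI_COUPLING_PER_SD * effect_bbi
      }
      group_params[[groups[i]]] <- p
    }
  }
  structure(list(n_per_group = n_per_group, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed),
                 group_params = group_params),
            class = "sim_config")
}

# slow latent vascular fluctuation: unit-SD AR(1) on a 1 Hz grid
.latent_vascular <- function(duration_s, tau) {
  n <- ceiling(duration_s) + 5L
  phi <- exp(-1 / tau)
  innov <- rnorm(n, sd = sqrt(1 - phi^2))
  s <- numeric(n)
  s[1] <- rnorm(1)
  for (i in 2:n) s[i] <- phi * s[i - 1] + innov[i]
  list(t = seq_len(n) - 1, s = s)
}

.interp_latent <- function(lat, t) approx(lat$t, lat$s, xout = t,
                                          rule = 2)$y

#' Simulate one subject's coupled cardiorespiratory-vascular record
#'
#' Beat, breath and pressure series are driven by one slow latent vascular
#' fluctuation: per-beat SBP/DBP ride on it; the heart period couples to
#' it (baroreflex arm) and to the respiratory phase (RSA); the breath
#' duration couples to it with a group-specific gain (respiratory arm).
#' Optionally, raw ECG / BP / respiratory-flow signals are synthesized
#' from the event-level ground truth (template R waves at beat times,
#' per-beat triangular pressure pulses hitting the injected SBP/DBP
#' exactly, and a phase-continuous flow oscillation whose
#' negative-to-positive zero crossings are the breath onsets).
#'
#' @param params per-group parameter list, see [sim_group_defaults()].
#' @param duration_s record length in seconds.
#' @param seed random seed for this subject.
#' @param emit_raw also synthesize raw signals (a [physio_record()])?
#' @param fs raw-signal sampling rate (Hz).
#' @param subject_id identifier.
#' @return list with `series` (named list of event-indexed
#'   [event_series()]: `bbi`, `sbp`, `dbp`, `tt`), `truth` (beat times,
#'   breath onsets, injected per-beat SBP/DBP, parameters) and, when
#'   `emit_raw`, `record`.
#' @export
simulate_subject <- function(params = sim_group_defaults(),
                             duration_s = 900, seed = 1,
                             emit_raw = FALSE, fs = 250,
                             subject_id = "sim") {
  p <- utils::modifyList(sim_group_defaults(), params)
  if (p$bbi_mean <= 250)
    stop("non-physiological config: mean BBI must exceed 250 ms")
  if (p$tt_mean <= 0.5) stop("non-physiological config: mean TT too short")
  set.seed(as.integer(seed))
  lat <- .latent_vascular(duration_s, p$vasc_tau)

  # breath onsets
  onsets <- 0
  repeat {
    tk <- onsets[length(onsets)]
    if (tk > duration_s + 5) break
    s_here <- .interp_latent(lat, tk)
    tt <- p$tt_mean + p$tt_sd *
      (p$tt_sbp_coupling * s_here +
         sqrt(max(0, 1 - p$tt_sbp_coupling^2)) * rnorm(1))
    tt <- max(tt, 1.2, 0.1 * p$tt_mean)
    onsets <- c(onsets, tk + tt)
  }

  # respiratory phase, piecewise linear between onsets
  resp_phase <- function(t) {
    k <- findInterval(t, onsets, all.inside = TRUE)
    2 * pi * (t - onsets[k]) / (onsets[k + 1] - onsets[k])
  }

  # beats
  w_s <- p$bbi_sbp_coupling
  w_r <- p$rsa_weight
  w_e <- sqrt(max(0, 1 - w_s^2 - w_r^2))
  beats <- 0
  repeat {
    tn <- beats[length(beats)]
    if (tn > duration_s + 2) break
    s_here <- .interp_latent(lat, tn)
    bbi <- p$bbi_mean + p$bbi_sd *
      (w_s * s_here + w_r * sqrt(2) * sin(resp_phase(tn)) + w_e * rnorm(1))
    bbi <- max(bbi, 300)
    beats <- c(beats, tn + bbi / 1000)
  }
  beats <- beats[beats <= duration_s + 2]
  if (length(beats) < 4) stop("record too short to contain beats")

  s_beat <- .interp_latent(lat, beats)
  sbp <- p$sbp_set + p$sbp_sd * s_beat + p$sbp_noise * rnorm(length(beats))
  dbp <- p$dbp_set + p$dbp_gain * p$sbp_sd * s_beat +
    p$sbp_noise * rnorm(length(beats))
  dbp <- pmin(dbp, sbp - 5)

  onsets <- onsets[onsets <= duration_s + 5]
  series <- list(
    bbi = extract_bbi(beats),
    sbp = event_series("SBP", sbp, beats),
    dbp = event_series("DBP", dbp, beats),
    tt = event_series("TT", diff(onsets), onsets[-1]))
  truth <- list(beat_times = beats, breath_onsets = onsets,
                sbp = sbp, dbp = dbp, params = p, seed = seed)
  out <- list(series = series, truth = truth, subject_id = subject_id)
  if (emit_raw)
    out$record <- .synthesize_raw(beats, onsets, sbp, dbp, duration_s, fs,
                                  subject_id)
  out
}

# raw-signal synthesis from event-level ground truth
.synthesize_raw <- function(beats, onsets, sbp, dbp, duration_s, fs,
                            subject_id) {
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # ECG: Gaussian R wave (8 ms SD) + broader T wave per beat
  ecg <- rnorm(n, sd = 0.01)
  for (i in seq_along(beats)) {
    tb <- beats[i]
    if (tb > duration_s + 0.5) next
    lo <- max(1, floor((tb - 0.4) * fs)); hi <- min(n, ceiling((tb + 0.5) * fs))
    if (lo > hi) next
    idx <- lo:hi
    ecg[idx] <- ecg[idx] + exp(-(t[idx] - tb)^2 / (2 * 0.008^2)) +
      0.2 * exp(-(t[idx] - tb - 0.25)^2 / (2 * 0.05^2))
  }

  # BP: triangular pulse per beat window rising from DBP to SBP at 30% of
  # the beat, back down to DBP — window extrema equal the injected values
  bp <- rep(dbp[1], n)
  k <- findInterval(t, beats)
  valid <- k >= 1 & k < length(beats)
  u <- (t[valid] - beats[k[valid]]) /
    (beats[k[valid] + 1] - beats[k[valid]])
  w <- ifelse(u < 0.3, u / 0.3, 1 - (u - 0.3) / 0.7)
  bp[valid] <- dbp[k[valid]] + (sbp[k[valid]] - dbp[k[valid]]) * w

  # RF: unit-amplitude sine of the piecewise-linear respiratory phase
  kk <- findInterval(t, onsets, all.inside = TRUE)
  phase <- 2 * pi * (t - onsets[kk]) / (onsets[kk + 1] - onsets[kk])
  rf <- sin(phase)

  physio_record(list(ecg = ecg, bp = bp, rf = rf), fs = fs,
                subject_id = subject_id)
}

#' Simulate a labelled cohort of subjects
#'
#' @param config a [sim_config()].
#' @param emit_raw also synthesize raw signals per subject (slow; default
#'   `FALSE`).
#' @return object of class `sim_cohort`: list with `subjects` (each
#'   holding `subject_id`, `group`, `series`, `truth`), `labels` (data
#'   frame `subject_id`, `group`) and `config`.
#' @export
simulate_cohort <- function(config, emit_raw = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- list()
  labels <- data.frame(subject_id = character(0), group = character(0),
                       stringsAsFactors = FALSE)
  counter <- 0L
  for (grp in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[grp]])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", grp, i)
      seed_i <- (config$seed * 10007L + counter * 131L) %% 2147483629L
      sub <- simulate_subject(config$group_params[[grp]],
                              duration_s = config$duration_s,
                              seed = seed_i, emit_raw = emit_raw,
                              fs = config$fs, subject_id = sid)
      sub$group <- grp
      subjects[[sid]] <- sub
      labels <- rbind(labels,
                      data.frame(subject_id = sid, group = grp,
                                 stringsAsFactors = FALSE))
    }
  }
  structure(list(subjects = subjects, labels = labels, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$labels$group)
  cat(sprintf("<sim_cohort: %d subjects (%s); %g s records>\n",
              nrow(x$labels),
              paste(names(tab), tab, sep = " = ", collapse = ", "),
              x$config$duration_s))
  invisible(x)
}

#' Characterize every subject of a cohort into a feature table
#'
#' @param cohort a [simulate_cohort()] result, or any list of subjects
#'   each with `series` and `subject_id`.
#' @param alpha,containment see [baro_characterize()].
#' @return data frame with `subject_id`, `group` and the 168 feature
#'   columns (names per [feature_schema()], preserved verbatim).
#' @export
characterize_cohort <- function(cohort, alpha = 0.15, containment = 0.95) {
  subjects <- if (inherits(cohort, "sim_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(sub) {
    ch <- baro_characterize(sub$series, alpha = alpha,
                            containment = containment,
                            subject_id = sub$subject_id)
    ch$features
  })
  feat <- do.call(rbind, rows)
  out <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, function(s)
      if (is.null(s$group)) NA_character_ else s$group, ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(feat, check.names = FALSE))
  rownames(out) <- NULL
  out
}
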