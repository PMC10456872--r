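#' Default pipeline configuration
#'
#' @param seed base random seed.
#' @param out_dir output directory for artifacts (feature table, reports,
#'   manifest); `NULL` disables writing.
#' @param alpha,containment characterization parameters.
#' @param rho_max,top_k,full_sample_screen,kernels,C_grid,sigma_grid,d_grid model
#'   search parameters, see [model_search()].
#' @param comparisons list of comparisons, each
#'   `list(name =, positive =, negative =)` naming group labels; the
#'   `positive` group is the sensitivity class.
#' @param simulate a [sim_config()] to generate the cohort, or `NULL`.
#' @param series_csv path to a tidy event-series CSV plus `groups_csv`
#'   (columns `subject_id`, `group`) to analyze recorded data.
#' @param groups_csv see `series_csv`.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       alpha = 0.15, containment = 0.95,
                       rho_max = 0.7, top_k = 10, full_sample_screen = FALSE,
                       kernels = c("gaussian", "laplace", "anova"),
                       C_grid = c(0.5, 1, 2.2, 5, 10),
                       sigma_grid = c(0.5, 0.8, 1, 1.5, 2, 3),
                       d_grid = c(1, 2, 3),
                       comparisons = NULL,
                       simulate = NULL, series_csv = NULL,
                       groups_csv = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (containment <= 0 || containment > 1)
    stop("containment must lie in (0, 1]")
  structure(list(seed = seed, out_dir = out_dir, alpha = alpha,
                 containment = containment, rho_max = rho_max,
                 top_k = top_k, full_sample_screen = full_sample_screen,
                 kernels = kernels, C_grid = C_grid,
                 sigma_grid = sigma_grid, d_grid = d_grid,
                 comparisons = comparisons, simulate = simulate,
                 series_csv = series_csv, groups_csv = groups_csv),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; a
#' `simulate:` block (keys `n_per_group`, `duration_s`, `effect_tt`,
#' `effect_bbi`) is converted to a [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    sim <- sim_config(
      n_per_group = unlist(s$n_per_group),
      duration_s = if (is.null(s$duration_s)) 900 else s$duration_s,
      effect_tt = if (is.null(s$effect_tt)) 1 else s$effect_tt,
      effect_bbi = if (is.null(s$effect_bbi)) 1 else s$effect_bbi,
      seed = if (is.null(s$seed)) y$seed else s$seed)
  }
  args <- y[setdiff(names(y), "simulate")]
  args$simulate <- sim
  do.call(run_config, args)
}

#' Run the full characterization and classification pipeline
#'
#' Stages: obtain event series (simulate or read), characterize every
#' subject into the 168-index feature table, then run [model_search()]
#' for each configured comparison.  Feature extraction never sees group
#' labels.  When `config$out_dir` is set, the feature table, per-
#' comparison reports (JSON) and a manifest with MD5 checksums are
#' written.
#'
#' @param config a [run_config()].
#' @return list with `features` (data frame), `reports` (named list of
#'   `baro_model`s) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log <- list()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    log[[length(log) + 1L]] <<- list(
      stage = name, seconds = as.numeric(Sys.time() - tic, units = "secs"))
    res
  }

  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", simulate_cohort(config$simulate))
    subjects <- cohort$subjects
    labels <- cohort$labels
  } else if (!is.null(config$series_csv)) {
    series <- stage("read_series", read_event_series(config$series_csv))
    if (is.null(config$groups_csv))
      stop("stage 'read_series': groups_csv required with series_csv")
    gdf <- stage("read_groups", {
      if (!file.exists(config$groups_csv))
        stop("input file not found: ", config$groups_csv)
      read.csv(config$groups_csv, stringsAsFactors = FALSE)
    })
    subjects <- lapply(names(series), function(sid)
      list(subject_id = sid, series = series[[sid]],
           group = gdf$group[match(sid, gdf$subject_id)]))
    names(subjects) <- names(series)
    labels <- data.frame(subject_id = names(series),
                         group = vapply(subjects, `[[`, "", "group"),
                         stringsAsFactors = FALSE)
  } else {
    stop("stage 'input': config must provide either simulate or series_csv")
  }

  # stage isolation: characterization receives series only, no labels
  features <- stage("features", characterize_cohort(
    lapply(subjects, function(s) s[c("subject_id", "series")]),
    alpha = config$alpha, containment = config$containment))
  features$group <- labels$group[match(features$subject_id,
                                       labels$subject_id)]

  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    grps <- unique(labels$group)
    if (length(grps) == 2)
      comparisons <- list(list(name = paste0(grps[2], "-vs-", grps[1]),
                               positive = grps[2], negative = grps[1]))
    else comparisons <- list()
  }

  feat_cols <- feature_schema()
  reports <- list()
  for (cmp in comparisons) {
    sel <- features$group %in% c(cmp$positive, cmp$negative)
    reports[[cmp$name]] <- stage(paste0("classify:", cmp$name),
      model_search(features[sel, feat_cols],
                   features$group[sel], positive = cmp$positive,
                   kernels = config$kernels, C_grid = config$C_grid,
                   sigma_grid = config$sigma_grid, d_grid = config$d_grid,
                   rho_max = config$rho_max, top_k = config$top_k,
                   full_sample_screen = config$full_sample_screen))
  }

  manifest <- list(seed = config$seed,
                   alpha = config$alpha, containment = config$containment,
                   n_subjects = nrow(labels),
                   comparisons = vapply(comparisons, `[[`, "", "name"),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("barogeo")),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
                   stages = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fpath <- file.path(config$out_dir, "features.csv")
    write_feature_table(features, fpath)
    files <- c(fpath, paste0(fpath, ".schema.json"))
    for (nm in names(reports)) {
      rpath <- file.path(config$out_dir,
                         paste0("report_", gsub("[^A-Za-z0-9_-]", "_", nm),
                                ".json"))
      write_model_report(reports[[nm]], rpath)
      files <- c(files, rpath)
    }
    manifest$files <- lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(features = features, reports = reports, manifest = manifest)
}

#' Write a model report as JSON
#'
#' Serializes the comparison, screening table, chosen model, per-fold
#' predictions, confusion counts and metrics.
#'
#' @param model a [model_search()] result.
#' @param path output JSON path; a CSV mirror of the screening table is
#'   written alongside as `<path>.screening.csv`.
#' @export
write_model_report <- function(model, path) {
  stopifnot(inherits(model, "baro_model"))
  rep <- list(
    comparison = paste0(model$positive, "-vs-", model$negative),
    positive_class = model$positive,
    feature_pair = model$pair,
    kernel = model$kernel,
    C = model$C, sigma = model$sigma, d = model$d,
    acc = model$acc, sn = model$sn, sp = model$sp,
    counts = as.list(model$counts),
    predictions = model$predictions,
    truth = model$truth,
    full_sample_screen = model$full_sample_screen,
    screening = model$screening[, c("index", "p", "mean_a", "sd_a",
                                    "mean_b", "sd_b", "pass")])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  write.csv(model$screening, paste0(path, ".screening.csv"),
            row.names = FALSE)
  invisible(path)
}
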