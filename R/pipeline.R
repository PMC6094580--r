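# End-to-end orchestration: config, the full analysis pipeline, plot-data
# export, and a small command-line front end.

#' Pipeline configuration
#'
#' All defaults mirror the standard protocol: 10-s epochs, 60-min non-wear
#' window, 8 h/day on >= 4 days validity, the 16-bin spectrum, 100
#' Monte-Carlo repetitions with a 50% holdout and at most 10 components.
#'
#' @param epoch_csv Path to a long epoch CSV ([read_epoch_csv()]); `NULL`
#'   when `features` are supplied directly.
#' @param panel_csv Path to a metabolic panel CSV ([read_panel_csv()]);
#'   `NULL` when a `panel` data frame is supplied.
#' @param features Optional precomputed subjects x bins matrix (rownames =
#'   subject ids), bypassing epoch processing.
#' @param panel Optional panel data frame.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param criteria A [wear_criteria()].
#' @param bin_edges Lower bin edges for the spectrum.
#' @param repetitions,holdout_fraction,a_max Resampling settings.
#' @param seed Master seed for all resampling.
#' @param per_outcome Also fit one signature per single outcome.
#' @param sex_stratified Fit boy/girl models and report the loading-pattern
#'   correlation.
#' @param epoch_length Epoch length (s) used when reading epoch CSVs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_csv = NULL, panel_csv = NULL,
                            features = NULL, panel = NULL,
                            out_dir = NULL,
                            criteria = wear_criteria(),
                            bin_edges = default_bin_edges(),
                            repetitions = 100, holdout_fraction = 0.5,
                            a_max = 10, seed = 1,
                            per_outcome = FALSE, sex_stratified = FALSE,
                            epoch_length = 10L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: epoch processing into spectra (unless features are
#' precomputed), metabolic outcome derivation and the composite score on the
#' complete-case intersection, the univariate correlation profile, and the
#' multivariate signature (component selection, target projection, SR
#' profile with confidence intervals) for the composite and optionally each
#' single outcome and each sex. Every exclusion is logged. With `out_dir`
#' set, descriptive, univariate, and SR-profile tables are written as CSV,
#' plot data as JSON, and a run manifest records the seed and settings.
#'
#' @param config A [pipeline_config()].
#' @return A list of artifacts: `features`, `meta`, `outcomes`, `univariate`,
#'   `signatures` (named list of `signature_profile`s), `sex_patterns`
#'   (when stratified), `log` (exclusion accounting), `paths` (written
#'   files).
#' @export
run_pipeline <- function(config) {
  log <- list()
  scheme <- bin_scheme(config$bin_edges)

  # --- features -----------------------------------------------------------
  if (!is.null(config$features)) {
    X <- as.matrix(config$features)
    meta <- data.frame(subject_id = rownames(X))
    log$wear_excluded <- character(0)
  } else {
    streams <- read_epoch_csv(config$epoch_csv, config$epoch_length)
    processed <- lapply(streams, process_stream,
                        criteria = config$criteria, scheme = scheme)
    sm <- spectrum_matrix(processed)
    X <- sm$X; meta <- sm$meta
    log$wear_excluded <- sm$excluded
  }
  log$n_with_features <- nrow(X)

  # --- outcomes -----------------------------------------------------------
  panel <- if (!is.null(config$panel)) config$panel
           else read_panel_csv(config$panel_csv)
  cc <- stats::complete.cases(
    panel[, c("sex", "age", "body_mass", "height", "waist", "sbp",
              "tc", "hdl", "tg", "glucose", "insulin", "andersen_distance")])
  log$panel_incomplete <- panel$subject_id[!cc]
  panel <- panel[cc, , drop = FALSE]
  ids <- intersect(rownames(X), panel$subject_id)
  log$n_analyzed <- length(ids)
  if (length(ids) == 0) stop("empty analysis set after exclusions")
  X <- X[ids, , drop = FALSE]
  panel <- panel[match(ids, panel$subject_id), , drop = FALSE]
  outc <- build_outcomes(panel)
  Y <- cbind(outc$adjusted, composite = outc$composite)

  # --- univariate profile -------------------------------------------------
  univ <- univariate_profile(X, Y)

  # --- signatures ---------------------------------------------------------
  targets <- "composite"
  if (config$per_outcome)
    targets <- c(targets, colnames(outc$adjusted))
  signatures <- list()
  for (tg in targets) {
    signatures[[tg]] <- fit_signature(
      X, Y[, tg], repetitions = config$repetitions,
      holdout_fraction = config$holdout_fraction,
      a_max = min(config$a_max, floor(length(ids) / 2) - 1, ncol(X)),
      seed = config$seed)
  }

  sex_patterns <- NULL
  if (config$sex_stratified) {
    by_sex <- split(seq_along(ids), panel$sex)
    fits <- lapply(by_sex, function(i)
      fit_signature(X[i, , drop = FALSE], Y[i, "composite"],
                    repetitions = config$repetitions,
                    holdout_fraction = config$holdout_fraction,
                    a_max = min(config$a_max, floor(length(i) / 2) - 1,
                                ncol(X)),
                    seed = config$seed))
    r <- compare_patterns(fits[[1]]$tp$p_tp, fits[[2]]$tp$p_tp)
    sex_patterns <- list(fits = fits, pattern_r = r)
  }

  # --- descriptives -------------------------------------------------------
  desc_vars <- cbind(age = panel$age, sbp = panel$sbp, tg = panel$tg,
                     tc_hdl = outc$derived$tc_hdl, homa = outc$derived$homa,
                     wc_height = outc$derived$wc_height,
                     andersen = panel$andersen_distance,
                     composite = outc$composite)
  descriptives <- data.frame(
    variable = colnames(desc_vars),
    mean = colMeans(desc_vars),
    sd = apply(desc_vars, 2, stats::sd), row.names = NULL)

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(paths, wr(descriptives, "descriptives.csv"))
    univ_df <- data.frame(bin = rownames(univ$r), univ$r, check.names = FALSE)
    paths <- c(paths, wr(univ_df, "univariate_r.csv"))
    for (tg in names(signatures))
      paths <- c(paths, wr(signatures[[tg]]$profile,
                           paste0("sr_profile_", tg, ".csv")))
    paths <- c(paths, export_sr_plot_data(
      signatures, file.path(config$out_dir, "sr_plot_data.json")))
    manifest <- list(
      seed = config$seed, n_analyzed = log$n_analyzed,
      n_wear_excluded = length(log$wear_excluded),
      n_panel_incomplete = length(log$panel_incomplete),
      repetitions = config$repetitions,
      holdout_fraction = config$holdout_fraction,
      a_max = config$a_max,
      bin_edges = config$bin_edges,
      selected_components = vapply(signatures, function(s) s$selection$a,
                                   numeric(1)),
      r2 = vapply(signatures, function(s) s$r2, numeric(1)),
      package_version = as.character(utils::packageVersion("actisig")))
    mp <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, mp)
  }

  list(features = X, meta = meta,
       outcomes = list(adjusted = outc$adjusted, composite = outc$composite,
                       derived = outc$derived),
       univariate = univ, signatures = signatures,
       sex_patterns = sex_patterns, descriptives = descriptives,
       log = log, paths = paths)
}

#' Export SR profiles as plot-ready JSON
#'
#' Ordered bin labels, signed SR bars and CI whiskers for an SR bar chart;
#' by the reporting convention a negative bar means more activity at that
#' intensity is associated with better metabolic health.
#'
#' @param signatures Named list of `signature_profile` objects (or one).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_sr_plot_data <- function(signatures, path) {
  if (inherits(signatures, "signature_profile"))
    signatures <- list(profile = signatures)
  obj <- lapply(signatures, function(s) {
    list(bins = as.character(s$profile$variable),
         sr = s$profile$sr,
         ci_lower = s$profile$lower,
         ci_upper = s$profile$upper,
         significant = s$profile$significant,
         n_components = s$selection$a,
         r2 = s$r2,
         no_model = s$no_model,
         convention = "negative bar = associated with better metabolic health")
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-import exported SR plot data
#'
#' @param path JSON path written by [export_sr_plot_data()].
#' @return Named list of plot-data lists.
#' @export
read_sr_plot_data <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic epoch + panel CSV pair),
#' `run-all` (full pipeline from CSVs). Flags: `--epochs`, `--panel`,
#' `--out`, `--seed`, `--n`, `--repetitions`, `--per-outcome`,
#' `--sex-stratified`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status 0, invisibly.
#' @export
actisig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: actisig <simulate|run-all> [--flags]", call. = FALSE)
  cmd <- args[1]
  flag <- function(name, default = NULL) {
    hit <- which(args == paste0("--", name))
    if (length(hit)) args[hit[1] + 1] else default
  }
  switch_flag <- function(name) any(args == paste0("--", name))
  seed <- as.integer(flag("seed", "1"))
  out <- flag("out", "actisig_out")
  if (cmd == "simulate") {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    n <- as.integer(flag("n", "50"))
    cohort <- simulate_cohort(cohort_config(n_subjects = n, seed = seed))
    write_panel_csv(cohort$panel, file.path(out, "panel.csv"))
    utils::write.csv(
      data.frame(subject_id = rownames(cohort$features),
                 cohort$features, check.names = FALSE),
      file.path(out, "features.csv"), row.names = FALSE)
    message("wrote panel.csv and features.csv to ", out)
  } else if (cmd == "run-all") {
    feats <- NULL
    fpath <- flag("features")
    if (!is.null(fpath)) {
      fdf <- utils::read.csv(fpath, check.names = FALSE)
      feats <- as.matrix(fdf[, -1])
      rownames(feats) <- fdf[[1]]
    }
    cfg <- pipeline_config(
      epoch_csv = flag("epochs"), panel_csv = flag("panel"),
      features = feats, out_dir = out, seed = seed,
      repetitions = as.integer(flag("repetitions", "100")),
      per_outcome = switch_flag("per-outcome"),
      sex_stratified = switch_flag("sex-stratified"))
    res <- run_pipeline(cfg)
    message("analyzed n = ", res$log$n_analyzed, "; outputs in ", out)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  invisible(0L)
}
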