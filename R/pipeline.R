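# File I/O contracts and end-to-end pipeline orchestration.
#
# All files are plain text: CSV with header, UTF-8, "." decimal separator,
# times in seconds, weights in grams. Every run writes a manifest carrying
# the seed and a hash of the configuration so outputs are traceable.

#' Read / write long-format meal curves
#'
#' CSV with columns `participant_id`, `meal_id`, `time_s`, `weight_g`.
#'
#' @param path file path.
#' @param curves long curve data frame.
#' @return `read_meal_curves` returns the data frame; `write_meal_curves`
#'   returns `path` invisibly.
#' @export
read_meal_curves <- function(path) {
  if (!file.exists(path)) stop("meal-curve file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  .check_curves(x)
  x$participant_id <- as.character(x$participant_id)
  x$meal_id <- as.character(x$meal_id)
  x
}

#' @rdname read_meal_curves
#' @export
write_meal_curves <- function(curves, path) {
  .check_curves(curves)
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the participant exposure table
#'
#' CSV with column `participant_id` plus any of `exposure`, `sex`, `age`,
#' `bmi`, `genotype`, `fat_pct`.
#'
#' @param path file path.
#' @param exposures exposure data frame.
#' @return `read_exposures` returns the data frame; `write_exposures` returns
#'   `path` invisibly.
#' @export
read_exposures <- function(path) {
  if (!file.exists(path)) stop("exposure file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(x))
    stop("exposure file lacks column participant_id: ", path)
  x$participant_id <- as.character(x$participant_id)
  x
}

#' @rdname read_exposures
#' @export
write_exposures <- function(exposures, path) {
  stopifnot(is.data.frame(exposures), "participant_id" %in% names(exposures))
  write.csv(exposures, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] used when the pipeline simulates its input;
#'   ignored when `curves_file`/`exposures_file` are given.
#' @param curves_file,exposures_file optional paths to existing input CSVs.
#' @param random_slopes fit the full model (default) or intercepts only.
#' @param effect_sd,alpha,power,k power-analysis settings (see
#'   [power_analysis()]).
#' @param seed integer seed governing all randomness of the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), curves_file = NULL,
                            exposures_file = NULL, random_slopes = TRUE,
                            effect_sd = 0.5, alpha = 0.05, power = 0.80,
                            k = 2:4, seed = 1L) {
  out <- list(sim = sim, curves_file = curves_file,
              exposures_file = exposures_file,
              random_slopes = isTRUE(random_slopes),
              effect_sd = effect_sd, alpha = alpha, power = power, k = k,
              seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim` key
#' holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- if (is.null(y$sim)) sim_config() else do.call(sim_config, y$sim)
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(rapply(config, as.vector, how = "replace")), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full meal-curve pipeline
#'
#' Stages, in order: (1) simulate a cohort (or read existing curves and
#' exposures), (2) smooth the curves by the running-minimum rule and
#' summarize each meal, (3) fit the three-level mixed model and extract BLUP
#' eating speeds, (4) power analysis from the observed SDs and the fitted
#' ICC, (5) descriptive table. All artifacts are written under `out_dir`
#' together with `manifest.json` (seed, configuration hash, per-stage record
#' counts). Given the same configuration and seed the numeric outputs are
#' reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `smoothed`, `summaries`, `fit`, `speeds`, `power`, `descriptives`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  hash <- .config_hash(config)
  set.seed(config$seed)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(config$curves_file)) {
      cohort <- simulate_cohort(config$sim)
      curves <- cohort$curves
      exposures <- cohort$exposures
      write_meal_curves(curves, file.path(out_dir, "curves_raw.csv"))
      write_exposures(exposures, file.path(out_dir, "exposures.csv"))
      yaml::write_yaml(list(seed = config$seed, config_hash = hash,
                            n_participants = config$sim$n_participants,
                            meals_per_participant =
                              config$sim$meals_per_participant),
                       file.path(out_dir, "sim_truth.yaml"))
    } else {
      cohort <- NULL
      curves <- read_meal_curves(config$curves_file)
      if (is.null(config$exposures_file))
        stop("exposures_file must accompany curves_file")
      exposures <- read_exposures(config$exposures_file)
    }
    say(sprintf("[simulate] %d snapshots in, %d participants", nrow(curves),
                length(unique(curves$participant_id))))

    stage <- "preprocess"
    smoothed <- smooth_monotone(trim_leading_zeros(curves))
    summaries <- summarize_meals(smoothed)
    write_meal_curves(smoothed, file.path(out_dir, "curves_smoothed.csv"))
    write.csv(summaries, file.path(out_dir, "meal_summaries.csv"),
              row.names = FALSE, quote = FALSE)
    say(sprintf("[preprocess] %d snapshots -> %d meal summaries",
                nrow(smoothed), nrow(summaries)))

    stage <- "fit"
    fit <- fit_meal_model(smoothed, exposures[c("participant_id", "exposure")],
                          random_slopes = config$random_slopes)
    speeds <- if (config$random_slopes) extract_meal_speeds(fit) else NULL
    fit_json <- list(
      seed = config$seed, config_hash = hash,
      coefficients = fit$coefficients,
      vcov_participant = fit$vcov_participant,
      vcov_meal = fit$vcov_meal,
      sigma2_resid = fit$sigma2_resid,
      reml_loglik = fit$reml_loglik,
      icc = compute_icc(fit),
      mean_duration = fit$mean_duration
    )
    jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(speeds))
      write.csv(speeds, file.path(out_dir, "meal_speeds.csv"),
                row.names = FALSE, quote = FALSE)
    say(sprintf("[fit] logLik = %.2f over %d meals", fit$reml_loglik,
                fit$n_meals))

    stage <- "power"
    pw <- power_analysis(
      sd_weight = sd_food_weight(summaries),
      sd_speed = if (is.null(speeds)) NA_real_ else sd_eating_speed(speeds),
      icc = compute_icc(fit), effect_sd = config$effect_sd,
      alpha = config$alpha, power = config$power, k = config$k)
    jsonlite::write_json(c(list(seed = config$seed, config_hash = hash),
                           unclass(pw)),
                         file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say(sprintf("[power] SD weight %.1f g, SD speed %.3f g/s, ICC %.3f",
                pw$sd_weight, pw$sd_speed, pw$icc))

    stage <- "describe"
    desc <- descriptive_table(.exposure_for_describe(exposures), summaries)
    write.csv(desc$categories, file.path(out_dir, "descriptives_categories.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(desc$continuous, file.path(out_dir, "descriptives_continuous.csv"),
              row.names = FALSE, quote = FALSE)

    manifest <- list(seed = config$seed, config_hash = hash,
                     stages = list(
                       simulate = list(snapshots = nrow(curves)),
                       preprocess = list(snapshots = nrow(smoothed),
                                         meals = nrow(summaries)),
                       fit = list(meals = fit$n_meals,
                                  participants = fit$n_participants),
                       power = list(k = config$k)),
                     files = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(cohort = cohort, smoothed = smoothed, summaries = summaries,
         fit = fit, speeds = speeds, power = pw, descriptives = desc,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# map a simulated exposure factor onto the descriptive-table column it codes
.exposure_for_describe <- function(exposures) {
  x <- exposures
  if ("exposure" %in% names(x) && !"genotype" %in% names(x)) {
    lv <- unique(as.character(x$exposure))
    if (all(lv %in% c("T/T", "A/T", "A/A"))) x$genotype <- x$exposure
  }
  x
}
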