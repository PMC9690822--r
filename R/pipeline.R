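# Named sub-seed per pipeline stage, derived from one top-level seed so
# stages are isolated but jointly reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1, evaluate = 2)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + 10007 * offsets[[stage]]) %% 2147483647)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. All randomness (simulation
#' and the evaluation split) flows from the single `seed` via named
#' per-stage sub-seeds.
#'
#' @param input Path to an intake CSV, or `NULL` to simulate a cohort.
#' @param catalog Path to a catalog config (JSON/YAML), or `NULL` for
#'   [default_catalog()].
#' @param n_participants Cohort size when simulating.
#' @param energy_bounds Plausibility window in kcal/day (keep inclusive).
#' @param train_fraction,given,good_rating,list_sizes Evaluation-scheme
#'   parameters, as in [evaluation_scheme()].
#' @param k_ubcf,k_ibcf,min_overlap,positive_only Neighborhood parameters,
#'   as in [neighborhood_config()].
#' @param top_n Production recommendation-list cap (default 5).
#' @param eligible_only Restrict production recommendations to eligible
#'   groups (default `TRUE`).
#' @param outdir Output directory for artifacts.
#' @param seed Top-level integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, catalog = NULL,
                            n_participants = 2000,
                            energy_bounds = c(500, 4000),
                            train_fraction = 0.70, given = 10,
                            good_rating = 1, list_sizes = c(1, 3, 5, 10),
                            k_ubcf = 25, k_ibcf = 30, min_overlap = 3,
                            positive_only = TRUE, top_n = 5,
                            eligible_only = TRUE, outdir = "ffqrec_run",
                            seed = 1) {
  stopifnot(length(energy_bounds) == 2, energy_bounds[1] < energy_bounds[2])
  structure(list(input = input, catalog = catalog,
                 n_participants = n_participants,
                 energy_bounds = energy_bounds,
                 train_fraction = train_fraction, given = given,
                 good_rating = good_rating, list_sizes = list_sizes,
                 k_ubcf = k_ubcf, k_ibcf = k_ibcf,
                 min_overlap = min_overlap, positive_only = positive_only,
                 top_n = top_n, eligible_only = eligible_only,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take [pipeline_config()]
#' defaults.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext)
  )
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, cfg)
}

#' Run the full dietary-recommendation pipeline
#'
#' Executes filter (energy plausibility) -> quintile ratings -> UBCF/IBCF
#' fit -> production top-N recommendations -> withheld-item evaluation, and
#' writes all artifacts under `config$outdir`:
#' \describe{
#'   \item{cohort.csv, labels.csv}{the simulated cohort (when no `input`)}
#'   \item{ratings.csv}{the observed rating matrix, long format}
#'   \item{recommendations.csv}{production top-N lists
#'     (`user,rank,item,predicted_rating`), UBCF predictions, eligibility
#'     filter per config}
#'   \item{evaluation.json}{error metrics, confusion sweep, ROC/PR points}
#'   \item{manifest.json}{echo of every tunable plus versions and seed}
#' }
#'
#' @param config A `pipeline_config`, or path to one (JSON/YAML).
#' @return Invisibly, a list with the artifact `paths`, the `evaluation`
#'   report and the recommendation data frame.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- if (is.null(config$catalog)) default_catalog()
             else read_catalog(config$catalog)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (is.null(config$input)) {
    cohort <- generate_cohort(synthetic_config(
      n_participants = config$n_participants,
      seed = stage_seed(config$seed, "simulate")))
    intake <- cohort$intake
    paths$cohort <- file.path(config$outdir, "cohort.csv")
    paths$labels <- file.path(config$outdir, "labels.csv")
    write_intake_csv(intake, paths$cohort)
    utils::write.csv(cohort$labels, paths$labels, row.names = FALSE,
                     quote = FALSE)
  } else {
    intake <- read_intake_csv(config$input, catalog)
  }

  intake <- filter_by_energy(intake, config$energy_bounds[1],
                             config$energy_bounds[2], quiet = TRUE)
  ratings <- quintile_ratings(intake, catalog, warn = FALSE)
  paths$ratings <- file.path(config$outdir, "ratings.csv")
  write_rating_matrix(ratings, paths$ratings)

  cfg_ub <- neighborhood_config("UBCF", config$k_ubcf, config$min_overlap,
                                config$positive_only)
  cfg_ib <- neighborhood_config("IBCF", config$k_ibcf, config$min_overlap,
                                config$positive_only)

  # production recommendations: UBCF on the full cohort
  S_user <- pearson_similarity(ratings, "user", cfg_ub$min_overlap)
  P <- predict_ubcf(ratings, S_user, cfg_ub)
  recs <- top_n_recommend(P, catalog, n_max = config$top_n,
                          eligible_only = config$eligible_only)
  paths$recommendations <- file.path(config$outdir, "recommendations.csv")
  write_recommendations(recs, paths$recommendations)

  scheme <- evaluation_scheme(config$train_fraction, config$given,
                              config$good_rating,
                              seed = stage_seed(config$seed, "evaluate"),
                              list_sizes = config$list_sizes)
  ev <- evaluate_sweep(ratings, scheme,
                       cfgs = list(UBCF = cfg_ub, IBCF = cfg_ib))
  paths$evaluation <- file.path(config$outdir, "evaluation.json")
  write_evaluation_json(ev, paths$evaluation)

  manifest <- c(unclass(config),
                list(r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("ffqrec")),
                     n_participants_kept = nrow(intake),
                     stage_seeds = list(
                       simulate = stage_seed(config$seed, "simulate"),
                       evaluate = stage_seed(config$seed, "evaluate"))))
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(paths = paths, evaluation = ev, recommendations = recs))
}
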