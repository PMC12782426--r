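#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages in dependency order — `synth`, `simulate`,
#' `extract_features`, `fit`, `predict`, `per_cell` — writing every artifact
#' as delimited or structured text under `out_dir`, followed by a JSON
#' manifest recording the package version, the seed, the configuration and
#' the MD5 checksum of each output. All randomness flows from the single
#' configured seed; two identical runs produce byte-identical model files.
#' A stage failure leaves earlier stages' outputs intact.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Required fields: `seed` (integer), `out_dir`. Stage blocks:
#'   \describe{
#'     \item{synth}{`n_cells`, `n_frames`, `noise_frac`, `L` — writes
#'       `synth_features.tsv` and the ground-truth `synth_model.txt`.}
#'     \item{simulate}{`duration`, plus optional [spring_params()] and
#'       [illumination_schedule()] fields and `rule`, `dt`, `px_per_unit`,
#'       `y_jitter_sd` — writes `sim_tracks.tsv` and four kymographs.}
#'     \item{extract_features}{`tracks` (path; defaults to the simulate
#'       stage's output), `axis`, `min_frames` — writes `features_<axis>.tsv`.}
#'     \item{fit}{`features` (path; defaults to an earlier stage's output),
#'       `lambda` or `cv: true`, `folds`, `grouping` — writes `model.txt`
#'       and, under CV, `cv_curve.tsv`.}
#'     \item{predict}{`model`, `features` (paths, with the same defaults) —
#'       writes `predictions.tsv`.}
#'     \item{per_cell}{`lambda` (defaults to the fitted one), `n_best`,
#'       `n_worst` — writes `ranking.tsv`, `similarity.tsv`, `pca_scores.tsv`,
#'       `rf_best.txt`, `rf_worst.txt`.}
#'   }
#' @return Invisibly, a list with `status` (0), `artifacts` (named paths) and
#'   `manifest` (path).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config field 'seed' is required")
  stop_if_not_scalar_num(config$seed, "seed", integer = TRUE)
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  art <- list()
  path_of <- function(name) file.path(out_dir, name)

  if (!is.null(config$synth)) {
    s <- config$synth
    L <- as.integer(s$L %||% 20L)
    spec <- synthetic_spec(
      rf = default_true_rf(L = L),
      n_cells = as.integer(s$n_cells %||% 300L),
      n_frames = as.integer(s$n_frames %||% 400L),
      ar_coef = s$ar_coef %||% 0.85,
      noise_frac = s$noise_frac %||% 0.1,
      seed = config$seed)
    gen <- generate_linear_response_dataset(spec)
    art$features <- write_feature_table(gen$table, path_of("synth_features.tsv"))
    art$true_model <- write_response_function(gen$rf, path_of("synth_model.txt"))
  }

  if (!is.null(config$simulate)) {
    s <- config$simulate
    params <- spring_params(
      k = s$k %||% 2, mu0 = s$mu0 %||% 10, R0 = s$R0 %||% 0.5,
      alpha = s$alpha %||% 1.5, beta = s$beta %||% 2.5,
      sigma = s$sigma %||% 0.1, eta = s$eta %||% 0,
      n_cells = as.integer(s$n_cells %||% 100L),
      radius_rule = s$rule %||% "instantaneous")
    schedule <- illumination_schedule(
      sweep_velocity = s$sweep_velocity %||% 0.1,
      band_width = s$band_width %||% 30,
      direction = s$direction %||% "leftward")
    sim <- run_spring_simulation(params, schedule,
                                 duration = s$duration %||% 420,
                                 dt = s$dt %||% 0.01)
    tracks <- tracks_from_simulation(sim,
                                     frame_interval = s$frame_interval %||% 2,
                                     px_per_unit = s$px_per_unit %||% 3,
                                     y_jitter_sd = s$y_jitter_sd %||% 3,
                                     seed = config$seed)
    art$tracks <- write_track_table(tracks, path_of("sim_tracks.tsv"))
    for (f in names(sim$kymographs))
      art[[paste0("kymograph_", f)]] <-
        write_kymograph(sim, f, path_of(paste0("kymograph_", f, ".tsv")))
  }

  if (!is.null(config$extract_features)) {
    s <- config$extract_features
    tracks_path <- s$tracks %||% art$tracks
    if (is.null(tracks_path))
      stop("config field 'extract_features$tracks' is required ",
           "(no simulate stage output available)")
    if (!file.exists(tracks_path))
      stop("extract_features$tracks: file not found: ", tracks_path)
    tracks <- read_track_table(tracks_path)
    tracks <- filter_trajectories(tracks,
                                  min_frames = s$min_frames %||% 400L,
                                  require_first_frame =
                                    isTRUE(s$require_first_frame))
    cfg <- smoothing_config(
      sg_window = as.integer(s$sg_window %||% 11L),
      fit_radius_erk = s$fit_radius_erk %||% 10,
      fit_radius_vel = s$fit_radius_vel %||% 10,
      kde_sigma = s$kde_sigma %||% 25,
      frame_interval = s$frame_interval %||% 2)
    axis <- s$axis %||% "orthogonal"
    ft <- assemble_feature_table(tracks, cfg, axis = axis)
    art$features <- write_feature_table(
      ft, path_of(paste0("features_", axis, ".tsv")))
  }

  fitted_lambda <- NULL
  if (!is.null(config$fit)) {
    s <- config$fit
    features_path <- s$features %||% art$features
    if (is.null(features_path))
      stop("config field 'fit$features' is required (no earlier feature output)")
    if (!file.exists(features_path))
      stop("fit$features: file not found: ", features_path)
    table <- read_feature_table(features_path)
    lag <- lag_spec(L = as.integer(s$L %||% 20L),
                    frame_interval = s$frame_interval %||% 2)
    design <- build_design(table, lag)
    rcfg <- ridge_config(folds = as.integer(s$folds %||% 5L),
                         grouping = s$grouping %||% "sample",
                         seed = config$seed,
                         standardize = isTRUE(s$standardize))
    if (isTRUE(s$cv) || is.null(s$lambda)) {
      cv <- cv_lambda(design, rcfg)
      fitted_lambda <- cv$lambda
      utils::write.table(cv$curve, path_of("cv_curve.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      art$cv_curve <- path_of("cv_curve.tsv")
    } else {
      fitted_lambda <- s$lambda
    }
    rf <- ridge_fit(design, fitted_lambda, standardize = rcfg$standardize)
    art$model <- write_response_function(rf, path_of("model.txt"))
  }

  if (!is.null(config$predict)) {
    s <- config$predict
    model_path <- s$model %||% art$model
    if (is.null(model_path)) stop("config field 'predict$model' is required")
    if (!file.exists(model_path))
      stop("predict$model: file not found: ", model_path)
    features_path <- s$features %||% art$features
    if (is.null(features_path)) stop("config field 'predict$features' is required")
    rf <- read_response_function(model_path)
    table <- read_feature_table(features_path)
    pred <- predict_acceleration(rf, table)
    utils::write.table(pred, path_of("predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    art$predictions <- path_of("predictions.tsv")
  }

  if (!is.null(config$per_cell)) {
    s <- config$per_cell
    features_path <- s$features %||% art$features
    if (is.null(features_path)) stop("config field 'per_cell$features' is required")
    model_path <- s$model %||% art$model
    if (is.null(model_path)) stop("config field 'per_cell$model' is required")
    table <- read_feature_table(features_path)
    rf <- read_response_function(model_path)
    lambda <- s$lambda %||% fitted_lambda
    if (is.null(lambda))
      stop("config field 'per_cell$lambda' is required when no fit stage ran")
    rf_set <- fit_per_cell(table, rf$lag, lambda)
    ranking <- rank_cells(rf, table)
    utils::write.table(ranking, path_of("ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    S <- similarity_matrix(rf_set, order = ranking$cell_id)
    utils::write.table(as.data.frame(S), path_of("similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pca <- pca_response_functions(rf_set)
    utils::write.table(as.data.frame(pca$scores), path_of("pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_best <- as.integer(s$n_best %||% 20L)
    n_worst <- as.integer(s$n_worst %||% 20L)
    if (length(rf_set$rfs) >= n_best + n_worst) {
      sg <- subgroup_mean_rf(rf_set, ranking, n_best, n_worst)
      art$rf_best <- write_response_function(sg$best, path_of("rf_best.txt"))
      art$rf_worst <- write_response_function(sg$worst, path_of("rf_worst.txt"))
    }
    art$ranking <- path_of("ranking.tsv")
    art$similarity <- path_of("similarity.tsv")
    art$pca_scores <- path_of("pca_scores.tsv")
  }

  manifest <- list(
    package = "waveresponse",
    version = as.character(utils::packageVersion("waveresponse")),
    seed = config$seed,
    config = config,
    artifacts = lapply(art, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifest_path <- path_of("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(status = 0L, artifacts = art, manifest = manifest_path))
}
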