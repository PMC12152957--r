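#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end run: enumeration depth, output paths,
#' the synthetic-surface configuration (or a path to a real property CSV),
#' the regression target and the seed propagated to every stochastic stage.
#'
#' @param max_rings enumeration depth (2..8).
#' @param out_dir directory receiving the stage artifacts.
#' @param synth a [synthetic_config()], or `NULL` to load real properties.
#' @param properties_path CSV of curated properties, required when
#'   `synth = NULL`.
#' @param target regression target column, `"gap"` or `"e_rel"`.
#' @param restrict_to_n_rings ring count used for positional-feature trend
#'   summaries (`NULL` = no restriction).
#' @param seed integer seed.
#' @return A classed list (`bn_pipeline_config`).
#' @export
pipeline_config <- function(max_rings = 6, out_dir = ".",
                            synth = synthetic_config(),
                            properties_path = NULL,
                            target = c("gap", "e_rel"),
                            restrict_to_n_rings = NULL,
                            seed = 1L) {
  target <- match.arg(target)
  if (is.null(synth) && is.null(properties_path))
    stop("either a synthetic config or a property table path is required",
         call. = FALSE)
  if (!is.null(synth)) stopifnot(inherits(synth, "bn_synth_config"))
  if (!is.null(properties_path) && !file.exists(properties_path))
    stop("property table not found: ", properties_path, call. = FALSE)
  structure(list(max_rings = max_rings, out_dir = out_dir, synth = synth,
                 properties_path = properties_path, target = target,
                 restrict_to_n_rings = restrict_to_n_rings,
                 seed = as.integer(seed)),
            class = "bn_pipeline_config")
}

#' Run the full pipeline
#'
#' Enumerate scaffolds and isomers, featurize, obtain properties (synthetic or
#' loaded), curate relative energies, summarize trends, train the regressor
#' and run the ablation study.  Each stage logs its input/output counts and
#' writes its artifact under `config$out_dir`: `scaffolds.tsv`, `isomers.tsv`,
#' `features.csv`, `properties.csv`, `report.json`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with `scaffolds`, `space`, `features`,
#'   `properties`, `trends`, `fit` and `ablation`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "bn_pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  scaffolds <- enumerate_scaffolds(config$max_rings)
  say("enumerate: %d scaffolds (2..%d rings)", length(scaffolds),
      config$max_rings)
  write_scaffolds(scaffolds, path("scaffolds.tsv"))

  space <- enumerate_bn_space(scaffolds)
  say("enumerate-bn: %d isomers", nrow(space$isomers))
  write_isomers(space$isomers, path("isomers.tsv"))

  features <- featurize_space(space)
  say("featurize: %d feature vectors", nrow(features))
  write_features(features, path("features.csv"))

  if (!is.null(config$synth)) {
    cfg <- config$synth
    cfg$seed <- config$seed
    properties <- generate_properties(features, cfg)
    say("synth: %d property records (seed %d)", nrow(properties), config$seed)
  } else {
    properties <- load_real_properties(config$properties_path)
    say("load: %d property records", nrow(properties))
  }
  properties <- compute_e_rel(properties)
  write_properties(properties, path("properties.csv"))

  merged <- merge(features, properties, by = c("molecule_id", "n_rings"))
  if (nrow(merged) != nrow(features))
    warning("property table does not cover the full isomer space: ",
            nrow(merged), " of ", nrow(features), " isomers analyzed")

  trend_features <- c("n_rings", "n_LL", "n_SP", "n_DR")
  trends <- lapply(trend_features, function(f)
    trend_summary(merged, f, config$target,
                  restrict_n_rings = if (f == "n_rings") NULL else
                    config$restrict_to_n_rings))
  names(trends) <- trend_features

  fit <- train_and_evaluate(merged, config$target, seed = config$seed)
  say("train: test MAE %.4f, R^2 %.4f", fit$test_mae, fit$test_r2)
  ablation <- ablation_study(merged, config$target, seed = config$seed)
  say("ablation: most influential = %s",
      ablation$dropped[which.max(ablation$delta_mae)])

  report <- list(
    n_scaffolds = length(scaffolds),
    n_isomers = nrow(space$isomers),
    target = config$target,
    seed = config$seed,
    test_mae = fit$test_mae,
    test_r2 = fit$test_r2,
    cv = fit$cv,
    importance = fit$importance,
    ablation = ablation,
    trends = trends
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  say("report: %s", path("report.json"))

  invisible(list(scaffolds = scaffolds, space = space, features = features,
                 properties = properties, trends = trends, fit = fit,
                 ablation = ablation))
}
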