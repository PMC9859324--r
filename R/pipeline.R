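# End-to-end pipeline: derived covariates -> descriptives -> screening ->
# Moran gate -> Bayesian fit -> (optional) YLL clustering.

.default_config <- function() {
  list(
    input = list(region_csv = NULL, station_csv = NULL, yll_csv = NULL,
                 geojson = NULL),
    cutoff = 140,
    screening = list(threshold = 0.7, direction = "backward",
                     min_improvement = -4),
    moran = list(n_permutations = 9999, alpha = 0.05, input = "residuals"),
    model = list(n_chains = 4, n_iter = 15000, n_burnin = 5000, thin = 1),
    cluster = list(k = 3),
    seed = 1L,
    output_dir = NULL
  )
}

# Recursively overlay user values on defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      abort_input("unknown config key: '%s'", full)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) abort_input("config key '%s' must be a mapping", full)
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), overlays it on the defaults
#' (cut-off 140 mmHg, screening threshold 0.7, Moran alpha 0.05 with 9999
#' permutations on fixed-effect residuals, cluster k = 3), rejects unknown
#' keys with their full path, and checks value ranges and referenced paths.
#'
#' @param path Path to a YAML file, or a list of config values.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- .merge_config(.default_config(), user)
  if (is.null(cfg$input$region_csv)) abort_input("input.region_csv is required")
  for (p in c("region_csv", "station_csv", "yll_csv", "geojson")) {
    if (!is.null(cfg$input[[p]]) && !file.exists(cfg$input[[p]])) {
      abort_input("input.%s does not exist: '%s'", p, cfg$input[[p]])
    }
  }
  if (cfg$moran$alpha <= 0 || cfg$moran$alpha >= 1) {
    abort_input("moran.alpha must be in (0, 1), got %g", cfg$moran$alpha)
  }
  if (!cfg$moran$input %in% c("residuals", "raw")) {
    abort_input("moran.input must be 'residuals' or 'raw'")
  }
  if (cfg$cutoff <= 0) abort_input("cutoff must be positive")
  if (cfg$cluster$k < 1) abort_input("cluster.k must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    msg <- sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    stop(errorCondition(msg, class = c("oxylife_stage_error", "error"),
                        partial_report = report))
  })
  message(sprintf("[oxylife] stage %-16s done in %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  value
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and derive covariates (station aggregation when a
#' station table is supplied; GDP per capita standardized for modeling) ->
#' descriptive 140 mmHg comparison -> Pearson/DIC correlation filter ->
#' stepwise DIC selection -> Global Moran's I gate on the residuals of the
#' selected fixed-effects-only fit (or on raw life expectancy per config) ->
#' Gibbs fit of the gated CAR or IID model -> (when a YLL matrix is
#' supplied) Ward clustering and between-cluster tests. Every random stage
#' is seeded from the config seed, so identical config yields a
#' byte-identical report. A stage failure aborts with the stage name; the
#' partial report is attached to the error condition.
#'
#' @param config A `pipeline_config` (see [validate_config()]) or a path to
#'   a YAML config.
#' @return A `pipeline_report` list: `descriptive`, `screening`, `moran`,
#'   `chosen_model`, `fit` (posterior summaries, DIC, adjusted R-squared),
#'   `cluster` (labels + tests + Newick) or a skip reason, and `provenance`.
#'   When `output_dir` is set, CSV/JSON/Newick artifacts are written there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  report <- list()

  data <- .stage(report, "read", {
    regions <- read_region_table(config$input$region_csv)
    if (!is.null(config$input$geojson) && !all(c("lon", "lat") %in% names(regions))) {
      cen <- read_geometry(config$input$geojson)
      regions <- merge(regions, cen, by = "region_id")
    }
    if (!is.null(config$input$station_csv)) {
      st <- read.csv(config$input$station_csv, stringsAsFactors = FALSE)
      agg <- aggregate_stations(st, region_ids = regions$region_id)
      if (!"oxygen" %in% names(regions)) {
        regions$oxygen <- oxygen_from_pressure(agg$pressure)
      }
      for (v in setdiff(names(agg), c("region_id", "pressure"))) {
        if (!v %in% names(regions)) regions[[v]] <- agg[[v]]
      }
    }
    regions
  })
  candidates <- intersect(c("oxygen", .covariate_names), names(data))
  complete <- complete.cases(data[, c("life_expectancy", candidates)])
  if (any(!complete)) {
    message(sprintf("[oxylife] %d region(s) with missing cells excluded from model stages",
                    sum(!complete)))
  }
  model_data <- data[complete, , drop = FALSE]
  if ("gdp_per_capita" %in% names(model_data)) {
    model_data$gdp_per_capita <- as.numeric(scale(model_data$gdp_per_capita))
  }
  report$n_regions <- nrow(data)
  report$n_modeled <- nrow(model_data)

  report$descriptive <- .stage(report, "descriptive", {
    compare_oxygen_groups(data, cutoff = config$cutoff)
  })

  spec <- model_spec("IID", n_chains = config$model$n_chains,
                     n_iter = config$model$n_iter,
                     n_burnin = config$model$n_burnin,
                     thin = config$model$thin, seed = config$seed)
  W <- .stage(report, "weights", {
    inverse_distance_weights(model_data[, c("region_id", "lon", "lat")])
  })
  report$screening <- .stage(report, "screening", {
    screen_covariates(model_data, candidates,
                      threshold = config$screening$threshold,
                      spec = spec, direction = config$screening$direction,
                      min_improvement = config$screening$min_improvement)
  })
  selected <- report$screening$selected

  report$moran <- .stage(report, "moran_gate", {
    if (config$moran$input == "residuals" && length(selected) > 0) {
      gate_lm <- lm(stats::reformulate(selected, "life_expectancy"),
                    data = model_data)
      # re-project each permutation through the residual-maker matrix so the
      # gate keeps its nominal size under spatially structured covariates
      Xg <- model.matrix(gate_lm)
      M <- diag(nrow(Xg)) - Xg %*% solve(crossprod(Xg), t(Xg))
      morans_i(residuals(gate_lm), W,
               n_permutations = config$moran$n_permutations,
               seed = config$seed, projection = M)
    } else {
      morans_i(model_data$life_expectancy, W,
               n_permutations = config$moran$n_permutations,
               seed = config$seed)
    }
  })
  report$chosen_model <- select_spatial_model(report$moran, config$moran$alpha)

  report$fit <- .stage(report, "fit", {
    if (length(selected) == 0) {
      abort_input("no covariates selected; nothing to fit")
    }
    X <- as.matrix(model_data[, selected, drop = FALSE])
    y <- model_data$life_expectancy
    sp <- spec
    sp$model <- report$chosen_model
    if (report$chosen_model == "CAR") fit_car(y, X, W, sp) else fit_iid(y, X, sp)
  })

  if (!is.null(config$input$yll_csv)) {
    report$cluster <- .stage(report, "cluster", {
      yll_df <- read.csv(config$input$yll_csv, stringsAsFactors = FALSE)
      Y <- as.matrix(yll_df[, -1, drop = FALSE])
      rownames(Y) <- yll_df[[1]]
      cl <- ward_cluster(Y, k = config$cluster$k)
      oxy <- data$oxygen[match(rownames(Y), data$region_id)]
      tests <- compare_clusters(Y, cl$labels, oxygen = oxy)
      dend <- export_dendrogram(cl)
      list(labels = cl$labels, merges = cl$merges, tests = tests,
           newick = dend$newick)
    })
  } else {
    report$cluster <- list(skipped = "no YLL matrix supplied")
  }

  report$provenance <- list(seed = config$seed,
                            config = unclass(config),
                            package = "oxylife",
                            version = as.character(utils::packageVersion("oxylife")))
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write pipeline artifacts to a directory
#'
#' Emits `report.json` (the full report, no timestamps, byte-stable for a
#' given config and seed), `descriptive.csv`, `fit_summaries.csv`,
#' `cluster_tests.csv` and `dendrogram.nwk` as applicable.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    n_regions = report$n_regions,
    n_modeled = report$n_modeled,
    descriptive = report$descriptive,
    screening = list(
      dropped = report$screening$dropped,
      stepwise_trace = report$screening$stepwise_trace,
      selected = report$screening$selected
    ),
    moran = unclass(report$moran),
    chosen_model = report$chosen_model,
    fit = list(model = report$fit$model, dic = report$fit$dic,
               p_d = report$fit$p_d,
               adjusted_r2_fixed = report$fit$adjusted_r2_fixed,
               adjusted_r2_full = report$fit$adjusted_r2_full,
               summaries = report$fit$summaries),
    cluster = if (!is.null(report$cluster$skipped)) report$cluster else
      list(labels = as.list(report$cluster$labels),
           tests = report$cluster$tests,
           newick = report$cluster$newick),
    provenance = report$provenance
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  if (is.data.frame(report$descriptive) && nrow(report$descriptive) > 0) {
    write.csv(report$descriptive, file.path(dir, "descriptive.csv"),
              row.names = FALSE)
  }
  write.csv(report$fit$summaries, file.path(dir, "fit_summaries.csv"),
            row.names = FALSE)
  if (is.null(report$cluster$skipped)) {
    write.csv(report$cluster$tests, file.path(dir, "cluster_tests.csv"),
              row.names = FALSE)
    writeLines(report$cluster$newick, file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("oxylife pipeline report: %d regions (%d modeled)\n",
              x$n_regions, x$n_modeled))
  cat(sprintf("Moran's I = %.3f (p = %.4g) -> %s model\n",
              x$moran$I, x$moran$p_value, x$chosen_model))
  cat("Selected covariates:", paste(x$screening$selected, collapse = ", "), "\n")
  cat(sprintf("DIC = %.2f, adjusted R2 (full) = %.3f\n",
              x$fit$dic, x$fit$adjusted_r2_full))
  if (is.null(x$cluster$skipped)) {
    cat(sprintf("Clusters: %s\n", paste(table(x$cluster$labels), collapse = "/")))
  }
  invisible(x)
}
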