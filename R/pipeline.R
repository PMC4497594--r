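# Config-driven orchestration: simulate or ingest an OD table, fit the
# interaction models, run the evaluation suite, and write a reproducible
# run directory with a checksummed manifest.

pipeline_default_config <- function() {
  list(
    mode = "synthetic",          # synthetic | od_table | diaries
    od_path = NULL,              # od_table mode
    records_path = NULL,         # diaries mode
    tower_map_path = NULL,
    districts_path = NULL,
    distance_col = "dist_euclid_km",
    duration_edges = c(14, 30, 60, 90, 120),
    models = c("gravity", "radiation"),
    exclusion_rule = "fixed",    # fixed | empirical
    seed = 1,
    out_dir = "mobflow-run",
    synthetic = list()           # passed to synthetic_national_od()
  )
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, config)
  if (!cfg$mode %in% c("synthetic", "od_table", "diaries")) {
    stopf("mode must be one of synthetic, od_table, diaries")
  }
  if (cfg$mode == "od_table" && is.null(cfg$od_path)) {
    stopf("od_table mode requires od_path")
  }
  if (cfg$mode == "diaries" &&
      (is.null(cfg$records_path) || is.null(cfg$tower_map_path) ||
       is.null(cfg$districts_path))) {
    stopf("diaries mode requires records_path, tower_map_path and districts_path")
  }
  if (!cfg$exclusion_rule %in% c("fixed", "empirical")) {
    stopf("exclusion_rule must be 'fixed' or 'empirical'")
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Obtains an OD table (simulated, read from CSV, or aggregated from
#' diaries), fits the configured interaction models, computes the error /
#' goodness-of-fit / exclusion / model-choice diagnostics, and writes every
#' artifact plus a manifest (file checksums and a config hash) to the run
#' directory. Deterministic under a fixed seed.
#'
#' @param config named list (see `mobflow:::pipeline_default_config()` for
#'   keys and defaults) or a path to a JSON file with the same fields.
#' @return invisibly, a list with the fitted objects, reports and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage: obtain OD table and districts -------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (cfg$mode == "synthetic") {
    world <- stage("simulate", do.call(synthetic_national_od,
                                       c(list(seed = cfg$seed), cfg$synthetic)))
    districts <- world$districts
    od <- world$od[, setdiff(names(world$od), "truth_mean")]
    D <- district_distances(districts)
  } else if (cfg$mode == "od_table") {
    od <- stage("read_od", read_od_table(cfg$od_path))
    districts <- stage("read_od", districts_from_od(od))
    D <- distance_matrix_from_od(od, cfg$distance_col)
  } else {
    records <- stage("read_diaries", read.csv(cfg$records_path,
                                              stringsAsFactors = FALSE))
    tower_map <- stage("read_diaries", read.csv(cfg$tower_map_path,
                                                stringsAsFactors = FALSE))
    districts <- stage("read_diaries", read.csv(cfg$districts_path,
                                                stringsAsFactors = FALSE))
    series <- stage("daily_locations",
                    assign_daily_locations(records, tower_map, seed = cfg$seed))
    trips <- stage("trips", extract_trips(series))
    od <- stage("aggregate", aggregate_od(trips, districts, zero_fill = TRUE))
    D <- district_distances(districts)
  }

  # --- stage: fits --------------------------------------------------------
  fits <- list(); preds <- list(); reports <- list()
  if ("gravity" %in% cfg$models) {
    fits$gravity <- stage("fit_gravity", fit_gravity(od, cfg$distance_col))
    preds$gravity <- predict(fits$gravity)
    reports$gravity <- fit_statistics(od, preds$gravity, "gravity", n_params = 4)
  }
  if ("radiation" %in% cfg$models) {
    fits$radiation <- stage("fit_radiation",
                            fit_radiation_fraction(od, districts, distance = D))
    preds$radiation <- predict(fits$radiation)
    reports$radiation <- fit_statistics(od, preds$radiation, "radiation",
                                        n_params = 1)
  }

  # --- stage: evaluation --------------------------------------------------
  evalout <- list()
  if (all(c("gravity", "radiation") %in% names(preds))) {
    err_g <- route_errors(od, preds$gravity, "gravity")
    err_r <- route_errors(od, preds$radiation, "radiation")
    common <- intersect(paste(err_g$origin_id, err_g$dest_id),
                        paste(err_r$origin_id, err_r$dest_id))
    err_g <- err_g[paste(err_g$origin_id, err_g$dest_id) %in% common, ]
    err_r <- err_r[paste(err_r$origin_id, err_r$dest_id) %in% common, ]
    flags <- flag_unmodelable(list(gravity = err_g, radiation = err_r),
                              rule = cfg$exclusion_rule)
    winners <- label_better_model(err_g, err_r, exclude = flags$unmodelable)
    gm_all <- gravity_factor(od, cfg$distance_col)
    names(gm_all) <- paste(od$origin_id, od$dest_id)
    gm <- gm_all[paste(winners$origin_id, winners$dest_id)]
    choice <- tryCatch(fit_choice_logistic(winners, gm),
                       error = function(e) conditionMessage(e))
    evalout <- list(
      ks = ks_normality(err_g$error),
      flagged_share = mean(flags$unmodelable),
      flags = flags, winners = winners, choice = choice
    )
  }

  # --- stage: write run directory -----------------------------------------
  paths <- character()
  wr <- function(name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  wr("od.csv", function(p) write_od_table(od, p))
  wr("districts.csv", function(p) write.csv(districts, p, row.names = FALSE))
  fitjson <- list()
  if (!is.null(fits$gravity)) {
    fitjson$gravity <- list(params = as.list(coef(fits$gravity)),
                            ci = apply(fits$gravity$ci, 1, as.list),
                            reduction_deviance = fits$gravity$reduction_deviance)
  }
  if (!is.null(fits$radiation)) {
    fitjson$radiation <- list(tct = fits$radiation$tct,
                              tct_linear = fits$radiation$tct_linear,
                              boundary = fits$radiation$boundary)
  }
  fitjson$reports <- lapply(reports, function(r) {
    r[c("model", "n_routes", "n_positive", "reduction_deviance",
        "adjusted_r2", "sse", "dice_mean")]
  })
  if (length(evalout)) {
    fitjson$evaluation <- list(
      ks_statistic = evalout$ks$statistic,
      ks_p_value = evalout$ks$p_value,
      flagged_share = evalout$flagged_share,
      choice = if (inherits(evalout$choice, "choice_model")) {
        list(b0 = evalout$choice$b0, b1 = evalout$choice$b1,
             pseudo_r2 = evalout$choice$pseudo_r2)
      } else evalout$choice
    )
  }
  wr("fits.json", function(p) {
    jsonlite::write_json(fitjson, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  if (length(evalout)) {
    wr("route_diagnostics.csv", function(p) {
      write.csv(evalout$flags, p, row.names = FALSE)
    })
  }
  cfg_serial <- cfg[order(names(cfg))]
  cfg_serial$out_dir <- NULL   # incidental to the analysis, not hashed
  config_hash <- substr(tools::md5sum(
    wr("config.json", function(p) {
      jsonlite::write_json(cfg_serial, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }))[[1]], 1, 32)
  manifest <- list(
    config_hash = config_hash,
    files = lapply(paths, function(p) list(path = basename(p),
                                           md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, od = od, districts = districts, fits = fits,
                 reports = reports, evaluation = evalout,
                 manifest = manifest))
}
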