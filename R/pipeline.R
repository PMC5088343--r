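#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Checks all constraints and reports
#' every violation at once rather than stopping at the first: required paths
#' must exist, the cutpoint must lie in [0, 1], `min_posts` must be a
#' nonnegative count.
#'
#' Required fields: `posts` (JSON-lines), `tract_layer` (GeoJSON),
#' `labeled_corpus` (CSV with `text`,`label`), `food_lexicon` (CSV),
#' `activity_lexicon` (CSV), `out_dir`. Optional: `zip_layer`,
#' `activity_exclusions`, `cutpoint` (default 0.80), `min_posts` (default 30),
#' `outlier_threshold` (default 0.01), `l2_strength` (default 1), `seed`
#' (default 1).
#'
#' @param document Path to a YAML config, or a list.
#' @return A `pipeline_config` list if valid; otherwise a `config_errors`
#'   character vector of all violations.
#' @export
validate_config <- function(document) {
  cfg <- if (is.character(document) && length(document) == 1L) {
    if (!file.exists(document)) {
      return(structure(paste0("config file not found: ", document),
                       class = "config_errors"))
    }
    yaml::read_yaml(document)
  } else if (is.list(document)) {
    document
  } else {
    return(structure("config must be a YAML path or a list", class = "config_errors"))
  }
  errors <- character()
  req_paths <- c("posts", "tract_layer", "labeled_corpus",
                 "food_lexicon", "activity_lexicon")
  for (f in req_paths) {
    if (is.null(cfg[[f]])) {
      errors <- c(errors, paste0("missing required field: ", f))
    } else if (!file.exists(cfg[[f]])) {
      errors <- c(errors, paste0(f, ": path does not exist: ", cfg[[f]]))
    }
  }
  for (f in c("zip_layer", "activity_exclusions")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      errors <- c(errors, paste0(f, ": path does not exist: ", cfg[[f]]))
    }
  }
  if (is.null(cfg$out_dir)) errors <- c(errors, "missing required field: out_dir")
  cfg$cutpoint <- cfg$cutpoint %||% 0.80
  if (!is.numeric(cfg$cutpoint) || cfg$cutpoint < 0 || cfg$cutpoint > 1) {
    errors <- c(errors, "cutpoint: must be a number in [0, 1]")
  }
  cfg$min_posts <- cfg$min_posts %||% 30L
  if (!is.numeric(cfg$min_posts) || cfg$min_posts < 0) {
    errors <- c(errors, "min_posts: must be a nonnegative count")
  }
  cfg$outlier_threshold <- cfg$outlier_threshold %||% 0.01
  if (!is.numeric(cfg$outlier_threshold) || cfg$outlier_threshold <= 0 ||
      cfg$outlier_threshold > 1) {
    errors <- c(errors, "outlier_threshold: must be in (0, 1]")
  }
  cfg$l2_strength <- cfg$l2_strength %||% 1
  if (!is.numeric(cfg$l2_strength) || cfg$l2_strength < 0) {
    errors <- c(errors, "l2_strength: must be >= 0")
  }
  cfg$seed <- cfg$seed %||% 1L
  if (length(errors) > 0L) {
    return(structure(errors, class = "config_errors"))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Orchestrates ingest -> spatial join -> sentiment training -> annotation ->
#' aggregation: reads and cleans the post stream, joins posts to the tract
#' (and optional zip) layer, trains the sentiment model on the labeled corpus,
#' annotates every post, and writes per-level indicator tables. All outputs
#' are CSV/JSON-lines under `out_dir`; a structured run log (one record per
#' stage with its counts) is written alongside. Identical config and seed
#' produce byte-identical outputs.
#'
#' @param config A `pipeline_config` (see [validate_config()]), or a path/list
#'   to validate first.
#' @return Invisibly, a list with `annotations`, `indicators` (per level),
#'   `join_report`, `corpus_stats`, `national`, and `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_errors")) {
      abort(paste0("invalid config:\n", paste("-", config, collapse = "\n")))
    }
  }
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_rows <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    log_rows[[name]] <<- tibble(stage = name,
                                n = if (is.data.frame(res)) nrow(res) else NA_integer_,
                                seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  posts <- stage("ingest", parse_posts(config$posts))
  posts <- stage("clean", clean_posts(posts, config$outlier_threshold))
  corpus_stats <- attr(posts, "corpus_stats")

  tract <- load_area_layer(config$tract_layer)
  zip <- if (!is.null(config$zip_layer)) load_area_layer(config$zip_layer) else NULL
  posts <- stage("join", spatial_join(posts, tract, zip))
  jr <- join_report(posts)

  corpus <- readr::read_csv(config$labeled_corpus, show_col_types = FALSE,
                            progress = FALSE)
  model <- stage("train_sentiment",
                 train_maxent(corpus, l2_strength = config$l2_strength))
  model$cutpoint <- config$cutpoint

  food_lex <- load_food_lexicon(config$food_lexicon)
  act_lex <- load_activity_lexicon(config$activity_lexicon,
                                   config$activity_exclusions %||% character())
  ann <- stage("annotate", annotate_posts(posts, model, food_lex, act_lex))

  indicators <- list()
  indicators$tract <- stage("aggregate_tract",
                            aggregate_area(ann, "tract", config$min_posts))
  if (!is.null(zip)) {
    indicators$zip <- stage("aggregate_zip",
                            aggregate_area(ann, "zip", config$min_posts))
  }
  national <- summarize_national(ann)

  out <- function(name) file.path(config$out_dir, name)
  readr::write_csv(tidyr::unnest(corpus_stats,
                                 cols = "flagged_users", keep_empty = TRUE),
                   out("corpus_stats.csv"))
  readr::write_csv(jr, out("join_report.csv"))
  save_sentiment_model(model, out("sentiment_model.json"))
  readr::write_csv(ann, out("annotations.csv"))
  for (lvl in names(indicators)) {
    readr::write_csv(indicators[[lvl]], out(paste0("indicators_", lvl, ".csv")))
  }
  readr::write_csv(national, out("national_summary.csv"))
  run_log <- bind_rows(log_rows)
  readr::write_csv(run_log, out("run_log.csv"))

  invisible(list(annotations = ann, indicators = indicators, join_report = jr,
                 corpus_stats = corpus_stats, national = national,
                 model = model, log = run_log))
}
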