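#' Annotate posts with sentiment, food, and activity signals
#'
#' Tokenizes each post and combines all per-post signals: happy score and
#' dichotomized happy label, food matches (any-food flag, healthy and
#' fast-food counts, caloric density), and activity matches (any-activity
#' flag, exercise intensity). Intensity for a multi-activity post is the mean
#' of its matched activities' kcal (switchable to sum); it is `NA` when the
#' post has no activity match.
#'
#' @param posts Post tibble (with `tract_id`/`zip_id` if already joined).
#' @param model A `sentiment_maxent` model.
#' @param food_lex A [load_food_lexicon()] object.
#' @param activity_lex A [load_activity_lexicon()] object.
#' @param cutpoint Happy cutpoint; defaults to the model's (0.80 unless
#'   calibrated).
#' @param intensity_combine How to combine kcal across a post's activities.
#' @return Tibble of per-post annotations.
#' @export
annotate_posts <- function(posts, model, food_lex, activity_lex,
                           cutpoint = model$cutpoint,
                           intensity_combine = c("mean", "sum")) {
  intensity_combine <- match.arg(intensity_combine)
  toks <- tokenize_list(posts$text)
  score <- happy_score(model, toks)
  n <- nrow(posts)
  healthy_count <- integer(n)
  fastfood_count <- integer(n)
  any_food <- logical(n)
  density <- numeric(n)
  any_activity <- logical(n)
  intensity <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fm <- match_food(toks[[i]], food_lex)
    fl <- food_flags(fm)
    healthy_count[i] <- fl$healthy_count
    fastfood_count[i] <- fl$fastfood_count
    any_food[i] <- fl$any_food
    density[i] <- caloric_density(fm)
    am <- match_activity(toks[[i]], activity_lex)
    if (nrow(am) > 0L) {
      any_activity[i] <- TRUE
      kcal <- exercise_intensity(am$met)
      intensity[i] <- if (intensity_combine == "mean") mean(kcal) else sum(kcal)
    }
  }
  out <- tibble(
    post_id = posts$post_id,
    happy_score = score,
    happy = classify_happy(score, cutpoint) == 1L,
    any_food = any_food,
    healthy_count = healthy_count,
    fastfood_count = fastfood_count,
    caloric_density = density,
    any_activity = any_activity,
    intensity_kcal = intensity
  )
  for (col in intersect(c("tract_id", "zip_id"), names(posts))) {
    out[[col]] <- posts[[col]]
  }
  out
}

indicator_row <- function(ann) {
  food <- ann[ann$any_food, , drop = FALSE]
  healthy <- food[food$healthy_count > 0L, , drop = FALSE]
  fast <- food[food$fastfood_count > 0L, , drop = FALSE]
  act <- ann[ann$any_activity, , drop = FALSE]
  pct <- function(x) if (length(x) == 0L) NA_real_ else 100 * mean(x)
  tibble(
    n_posts = nrow(ann),
    pct_happy = 100 * mean(ann$happy),
    pct_food = 100 * mean(ann$any_food),
    pct_food_healthy = pct(food$healthy_count > 0L),
    pct_food_fastfood = pct(food$fastfood_count > 0L),
    mean_caloric_density = if (nrow(food) == 0L) NA_real_ else mean(food$caloric_density),
    pct_food_happy = pct(food$happy),
    pct_healthy_food_happy = pct(healthy$happy),
    pct_fastfood_happy = pct(fast$happy),
    pct_activity = 100 * mean(ann$any_activity),
    mean_intensity = if (nrow(act) == 0L) NA_real_ else mean(act$intensity_kcal),
    pct_activity_happy = pct(act$happy)
  )
}

#' Aggregate post annotations into area-level indicators
#'
#' Computes, per area, the indicator battery: percent of posts that are happy,
#' about food, and about physical activity; among food posts, the percent
#' healthy / fast-food / happy and the mean caloric density; among activity
#' posts, the mean exercise intensity and percent happy. Conditional
#' indicators are `NA` (never 0) when their denominator is empty. Areas with
#' fewer than `min_posts` assigned posts are suppressed, since tiny
#' denominators make percentage indicators extremely noisy.
#'
#' @param annotations Output of [annotate_posts()], carrying the requested
#'   area-id column.
#' @param level `"tract"` or `"zip"`.
#' @param min_posts Minimum posts per area (default 30).
#' @return Tibble of per-area indicators, one row per retained area.
#' @export
aggregate_area <- function(annotations, level = c("tract", "zip"),
                           min_posts = 30L) {
  level <- match.arg(level)
  idcol <- paste0(level, "_id")
  if (!idcol %in% names(annotations)) {
    abort(paste0("annotations carry no '", idcol, "' column; run spatial_join()"))
  }
  ann <- annotations[!is.na(annotations[[idcol]]), , drop = FALSE]
  out <- ann %>%
    group_by(area_id = .data[[idcol]]) %>%
    dplyr::group_modify(~ indicator_row(.x)) %>%
    ungroup() %>%
    arrange(.data$area_id)
  n_suppressed <- sum(out$n_posts < min_posts)
  if (n_suppressed > 0L) {
    inform(paste0("aggregate_area: suppressed ", n_suppressed,
                  " area(s) with fewer than ", min_posts, " posts"))
  }
  out[out$n_posts >= min_posts, , drop = FALSE]
}

#' Corpus-wide indicator summary
#'
#' The same indicator battery as [aggregate_area()] computed over all posts,
#' plus median caloric density and median exercise intensity.
#'
#' @param annotations Output of [annotate_posts()].
#' @return One-row tibble.
#' @export
summarize_national <- function(annotations) {
  if (nrow(annotations) == 0L) abort("no annotations to summarize")
  row <- indicator_row(annotations)
  food <- annotations[annotations$any_food, , drop = FALSE]
  act <- annotations[annotations$any_activity, , drop = FALSE]
  row$median_caloric_density <-
    if (nrow(food) == 0L) NA_real_ else median(food$caloric_density)
  row$median_intensity <-
    if (nrow(act) == 0L) NA_real_ else median(act$intensity_kcal)
  row
}

#' Plot area indicators as a tile map over a grid layer
#'
#' Convenience choropleth-style view for synthetic grid layers: each area is
#' drawn at its polygon centroid and filled by the chosen indicator.
#'
#' @param indicators Output of [aggregate_area()].
#' @param layer The [area_layer()] the areas came from.
#' @param fill Indicator column to map to fill.
#' @return A ggplot object.
#' @export
plot_indicator_map <- function(indicators, layer, fill = "pct_happy") {
  cent <- tibble(
    area_id = layer$areas$area_id,
    lon = vapply(layer$areas$bbox, function(b) (b[1L] + b[3L]) / 2, numeric(1)),
    lat = vapply(layer$areas$bbox, function(b) (b[2L] + b[4L]) / 2, numeric(1))
  )
  df <- left_join(indicators, cent, by = "area_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = fill)
}

#' Plot a calibration table
#'
#' Accuracy and predicted prevalence against the cutpoint grid, with the
#' selected cutpoint marked.
#'
#' @param object A `calibration_table` from [calibrate_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"cutpoint",
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutpoint, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "selected_cutpoint"),
                        linetype = 2) +
    ggplot2::labs(x = "cutpoint", y = NULL, colour = NULL)
}
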