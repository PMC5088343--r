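#' Load a food lexicon
#'
#' Reads a CSV with columns `phrase`, `kcal_per_100g`, `healthy`, `fastfood`.
#' Phrases must be unique, lowercase, one or two tokens; caloric density is
#' calories per 100 grams and must be nonnegative; an entry cannot be flagged
#' both healthy and fast-food. Two-word and one-word phrases are indexed
#' separately because matching gives two-word phrases precedence.
#'
#' A small packaged subset ships with the package
#' (`system.file("extdata", "food_lexicon.csv", package = "tweetscape")`);
#' full-scale use expects the caller's own nutrient table.
#'
#' @param table Path to a CSV file, or a data frame with the same columns.
#' @return A `food_lexicon` object.
#' @export
load_food_lexicon <- function(table) {
  df <- read_lexicon_table(table, c("phrase", "kcal_per_100g", "healthy", "fastfood"))
  df$kcal_per_100g <- as.numeric(df$kcal_per_100g)
  df$healthy <- as.logical(df$healthy)
  df$fastfood <- as.logical(df$fastfood)
  validate_phrases(df$phrase)
  if (any(df$kcal_per_100g < 0)) abort("negative kcal_per_100g in food lexicon")
  if (any(df$healthy & df$fastfood)) {
    abort("food entry flagged both healthy and fastfood")
  }
  df$n_tokens <- lengths(strsplit(df$phrase, " "))
  structure(list(entries = df,
                 counts = c(total = nrow(df), healthy = sum(df$healthy),
                            fastfood = sum(df$fastfood))),
            class = "food_lexicon")
}

#' Load a physical-activity lexicon
#'
#' Reads a CSV with columns `phrase`, `met`, `team_sport`, plus an optional
#' plain-text file of exclusion phrases (one per line) — common idioms such as
#' "running late" that mention an activity word without describing physical
#' activity. The veto set (watch/attend word forms, which signal spectating)
#' and the play set (play word forms, required for team sports) are fixed.
#'
#' @param table Path to a CSV file, or a data frame.
#' @param exclusions Path to the exclusion-phrase file, or a character vector.
#' @return An `activity_lexicon` object.
#' @export
load_activity_lexicon <- function(table, exclusions = character()) {
  df <- read_lexicon_table(table, c("phrase", "met", "team_sport"))
  df$met <- as.numeric(df$met)
  df$team_sport <- as.logical(df$team_sport)
  validate_phrases(df$phrase)
  if (any(df$met <= 0)) abort("MET values must be > 0")
  df$n_tokens <- lengths(strsplit(df$phrase, " "))
  if (is.character(exclusions) && length(exclusions) == 1L && file.exists(exclusions)) {
    exclusions <- readLines(exclusions, warn = FALSE)
  }
  exclusions <- tolower(trimws(exclusions))
  exclusions <- exclusions[nzchar(exclusions)]
  if (any(exclusions %in% df$phrase)) {
    abort("exclusion phrases must be disjoint from activity entry phrases")
  }
  structure(list(
    entries = df,
    exclusion_phrases = strsplit(exclusions, " "),
    veto_terms = c("watch", "watching", "watches", "watched",
                   "attend", "attending", "attends", "attended"),
    play_terms = c("play", "playing", "played")
  ), class = "activity_lexicon")
}

read_lexicon_table <- function(table, cols) {
  df <- if (is.character(table) && length(table) == 1L) {
    readr::read_csv(table, show_col_types = FALSE, progress = FALSE)
  } else if (is.data.frame(table)) {
    as_tibble(table)
  } else {
    abort("lexicon must be a CSV path or a data frame")
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("lexicon missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df$phrase <- as.character(df$phrase)
  df[, cols]
}

validate_phrases <- function(phrase) {
  if (anyDuplicated(phrase)) abort("duplicate phrase in lexicon")
  if (any(phrase != tolower(phrase))) abort("lexicon phrases must be lowercase")
  n_tok <- lengths(strsplit(phrase, " "))
  if (any(n_tok < 1L | n_tok > 2L)) abort("lexicon phrases must be 1-2 tokens")
  invisible(phrase)
}

# Two-word-then-one-word left-to-right matcher. First scans token pairs for
# two-word phrases, consuming both positions of each match; then scans the
# remaining unconsumed tokens for one-word phrases. Every occurrence counts;
# no token position is ever consumed twice.
match_phrases <- function(tokens, entries, masked = NULL) {
  n <- length(tokens)
  if (is.null(masked)) masked <- rep(FALSE, n)
  consumed <- masked
  hits_entry <- integer()
  hits_pos <- integer()
  two <- entries$phrase[entries$n_tokens == 2L]
  if (n >= 2L && length(two) > 0L) {
    i <- 1L
    while (i < n) {
      if (!consumed[i] && !consumed[i + 1L]) {
        pair <- paste(tokens[i], tokens[i + 1L])
        k <- match(pair, entries$phrase)
        if (!is.na(k)) {
          hits_entry <- c(hits_entry, k)
          hits_pos <- c(hits_pos, i)
          consumed[i:(i + 1L)] <- TRUE
          i <- i + 2L
          next
        }
      }
      i <- i + 1L
    }
  }
  one_idx <- which(!consumed & tokens %in% entries$phrase[entries$n_tokens == 1L])
  if (length(one_idx) > 0L) {
    ks <- match(tokens[one_idx], entries$phrase)
    hits_entry <- c(hits_entry, ks)
    hits_pos <- c(hits_pos, one_idx)
    consumed[one_idx] <- TRUE
  }
  ord <- order(hits_pos)
  res <- entries[hits_entry[ord], , drop = FALSE]
  res$position <- hits_pos[ord]
  structure(as_tibble(res), consumed = which(consumed & !masked),
            class = c("match_result", class(as_tibble(res))))
}

#' Match food phrases in a tokenized post
#'
#' Scans left to right for two-word food phrases first (e.g. "orange
#' chicken"), consuming both tokens of each match, then scans the remaining
#' tokens for one-word phrases (e.g. "taco"). Each occurrence counts, so a
#' token mentioned twice yields two matches, but no token position is ever
#' consumed twice — "orange chicken" never additionally matches "chicken".
#'
#' @param tokens Lowercase token vector (see [tokenize()]).
#' @param lexicon A [load_food_lexicon()] object.
#' @return A `match_result` tibble: one row per matched occurrence with the
#'   entry's attributes and its token `position`.
#' @export
match_food <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "food_lexicon"))
  match_phrases(tokens, lexicon$entries)
}

#' Caloric density of a post's food mentions
#'
#' Sums kcal-per-100g over all matched food occurrences (duplicates included).
#' Returns 0 for a post with no food match; at aggregation, density is
#' averaged over food posts only, so the 0 never enters an area mean.
#'
#' @param result A `match_result` from [match_food()].
#' @return Total kcal per 100 g.
#' @export
caloric_density <- function(result) {
  if (nrow(result) == 0L) return(0)
  sum(result$kcal_per_100g)
}

#' Healthy / fast-food counts for a post
#'
#' @param result A `match_result` from [match_food()].
#' @return A list with `healthy_count`, `fastfood_count`, `any_food`.
#' @export
food_flags <- function(result) {
  list(healthy_count = if (nrow(result) == 0L) 0L else sum(result$healthy),
       fastfood_count = if (nrow(result) == 0L) 0L else sum(result$fastfood),
       any_food = nrow(result) > 0L)
}

#' Match physical-activity phrases in a tokenized post
#'
#' Applies the activity rules in order: (1) if any veto term (watch/attend
#' word forms) is present anywhere, the whole post is rejected — it is likely
#' about spectating; (2) token positions covered by an exclusion idiom
#' ("running late", "walk away", "walking dead") are masked before matching;
#' (3) two-word-then-one-word matching runs on the unmasked tokens; (4)
#' matches of team-sport entries are kept only if a play word form occurs
#' anywhere in the post.
#'
#' @param tokens Lowercase token vector.
#' @param lexicon A [load_activity_lexicon()] object.
#' @return A `match_result` tibble (possibly empty).
#' @export
match_activity <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "activity_lexicon"))
  empty <- lexicon$entries[0L, , drop = FALSE]
  empty$position <- integer()
  empty <- structure(as_tibble(empty), consumed = integer(),
                     class = c("match_result", class(as_tibble(empty))))
  if (any(tokens %in% lexicon$veto_terms)) return(empty)
  masked <- rep(FALSE, length(tokens))
  for (phr in lexicon$exclusion_phrases) {
    L <- length(phr)
    if (L == 0L || length(tokens) < L) next
    for (i in seq_len(length(tokens) - L + 1L)) {
      if (all(tokens[i:(i + L - 1L)] == phr)) masked[i:(i + L - 1L)] <- TRUE
    }
  }
  res <- match_phrases(tokens, lexicon$entries, masked = masked)
  if (nrow(res) > 0L && any(res$team_sport)) {
    has_play <- any(tokens %in% lexicon$play_terms)
    if (!has_play) {
      keep <- !res$team_sport
      consumed <- attr(res, "consumed")
      res <- structure(res[keep, , drop = FALSE],
                       consumed = setdiff(consumed, res$position[!keep]),
                       class = class(res))
    }
  }
  res
}

#' Exercise-intensity energy expenditure
#'
#' Converts a MET value to kcal burned over a bout:
#' `kcal = MET x 3.5 x body mass (kg) / 200 x minutes`, with the defaults
#' standardizing every mention to a 30-minute bout by a 155-pound person.
#'
#' @param met Metabolic equivalent of the activity (> 0).
#' @param minutes Bout duration (> 0), default 30.
#' @param weight_lb Body weight in pounds (> 0), default 155.
#' @return kcal.
#' @examples
#' exercise_intensity(3.5) # about 129.2 kcal
#' @export
exercise_intensity <- function(met, minutes = 30, weight_lb = 155) {
  if (any(met <= 0) || any(minutes <= 0) || any(weight_lb <= 0)) {
    abort("`met`, `minutes` and `weight_lb` must all be > 0")
  }
  met * 3.5 * (weight_lb * 0.45359237) / 200 * minutes
}

#' Extract mentioned mileage and duration
#'
#' Finds a number immediately preceding a distance or duration unit token:
#' `mile`/`miles` for miles, `hour(s)`/`hr(s)` for hours,
#' `minute(s)`/`min(s)` for minutes. Absent or unparseable quantities are
#' returned as `NA`.
#'
#' @param tokens Lowercase token vector.
#' @return One-row tibble with `miles`, `hours`, `minutes`.
#' @export
mileage_and_duration <- function(tokens) {
  units <- list(
    miles = c("mile", "miles"),
    hours = c("hour", "hours", "hr", "hrs"),
    minutes = c("minute", "minutes", "min", "mins")
  )
  out <- list(miles = NA_real_, hours = NA_real_, minutes = NA_real_)
  if (length(tokens) >= 2L) {
    for (nm in names(units)) {
      pos <- which(tokens %in% units[[nm]])
      pos <- pos[pos > 1L]
      if (length(pos) > 0L) {
        val <- suppressWarnings(as.numeric(tokens[pos[1L] - 1L]))
        if (is.na(val)) {
          inform(paste0("mileage_and_duration: unparseable quantity before '",
                        tokens[pos[1L]], "'"))
        } else {
          out[[nm]] <- val
        }
      }
    }
  }
  tibble(miles = out$miles, hours = out$hours, minutes = out$minutes)
}
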