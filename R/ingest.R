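#' Parse raw post records into a tidy post table
#'
#' Accepts either a path to a JSON-lines file (one record per line with fields
#' `id`, `user_id`, `created_at`, `text`, `coordinates` as `[lon, lat]`) or a
#' data frame with columns `id`/`post_id`, `user_id`, `created_at`, `text`,
#' `lon`, `lat`. Records missing a required field, with an empty post id, or
#' with coordinates outside valid longitude/latitude ranges are skipped and
#' counted, never fixed up.
#'
#' @param records Path to a JSON-lines file, or a data frame of raw records.
#' @return A tibble with columns `post_id`, `user_id`, `created_at`, `text`,
#'   `lon`, `lat` and attribute `n_skipped` (count of malformed records).
#' @export
parse_posts <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    if (!file.exists(records)) abort(paste0("cannot read post stream: ", records))
    lines <- readLines(records, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    df <- tibble(
      post_id = vapply(raw, function(r) as_chr1(r[["id"]]), character(1)),
      user_id = vapply(raw, function(r) as_chr1(r[["user_id"]]), character(1)),
      created_at = vapply(raw, function(r) as_chr1(r[["created_at"]]), character(1)),
      text = vapply(raw, function(r) as_chr1(r[["text"]]), character(1)),
      lon = vapply(raw, function(r) coord_of(r, 1L), numeric(1)),
      lat = vapply(raw, function(r) coord_of(r, 2L), numeric(1))
    )
  } else if (is.data.frame(records)) {
    df <- as_tibble(records)
    if ("id" %in% names(df) && !"post_id" %in% names(df)) {
      df <- rename(df, post_id = "id")
    }
    needed <- c("post_id", "user_id", "created_at", "text", "lon", "lat")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols) > 0L) {
      abort(paste0("raw records missing columns: ", paste(missing_cols, collapse = ", ")))
    }
    df <- mutate(df,
      post_id = as.character(.data$post_id),
      user_id = as.character(.data$user_id),
      created_at = as.character(.data$created_at),
      text = as.character(.data$text),
      lon = as.numeric(.data$lon), lat = as.numeric(.data$lat)
    )
    df <- select(df, dplyr::all_of(needed))
  } else {
    abort("`records` must be a file path or a data frame")
  }

  ok <- !is.na(df$post_id) & nzchar(df$post_id) &
    !is.na(df$user_id) & !is.na(df$text) &
    !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    inform(paste0("parse_posts: skipped ", n_skipped, " malformed record(s)"))
  }
  out <- df[ok, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

as_chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x[[1L]])
}

coord_of <- function(r, i) {
  co <- r[["coordinates"]]
  if (is.null(co) || length(co) < 2L) return(NA_real_)
  suppressWarnings(as.numeric(co[[i]]))
}

#' Remove duplicate posts by post id
#'
#' Keeps the first occurrence of each `post_id` in input order; output order
#' is preserved.
#'
#' @param posts A post tibble (see [parse_posts()]).
#' @return The deduplicated tibble.
#' @export
deduplicate <- function(posts) {
  posts[!duplicated(posts$post_id), , drop = FALSE]
}

#' Remove job-posting posts
#'
#' Drops any post whose token set contains the hashtags `#hiring`, `#jobs` or
#' `#job` (case-insensitive). Plain words like "job" without the hashtag are
#' retained.
#'
#' @param posts A post tibble.
#' @return The filtered tibble.
#' @export
filter_job_posts <- function(posts) {
  if (nrow(posts) == 0L) return(posts)
  toks <- tokenize_list(posts$text)
  is_job <- vapply(toks, function(tk) any(tk %in% c("#hiring", "#jobs", "#job")),
                   logical(1))
  posts[!is_job, , drop = FALSE]
}

# tokenize() returns a bare vector for length-1 input; always want a list here
tokenize_list <- function(text) {
  out <- tokenize(text)
  if (length(text) == 1L) list(out) else out
}

#' Flag users contributing an outsized share of the corpus
#'
#' Returns the users whose posts account for strictly more than `threshold`
#' of all posts, ordered by descending share. Flagging is separated from
#' removal ([remove_users()]) so that a review step can intervene: high-volume
#' accounts are often automated or advertising accounts, but that judgment is
#' not automated here.
#'
#' @param posts A post tibble.
#' @param threshold Share-of-corpus cutoff in (0, 1]; default 0.01 (1%).
#' @return A tibble with columns `user_id`, `n_posts`, `share`.
#' @export
flag_outlier_users <- function(posts, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1]")
  }
  if (nrow(posts) == 0L) {
    return(tibble(user_id = character(), n_posts = integer(), share = numeric()))
  }
  posts %>%
    count(.data$user_id, name = "n_posts") %>%
    mutate(share = .data$n_posts / nrow(posts)) %>%
    filter(.data$share > threshold) %>%
    arrange(dplyr::desc(.data$share), .data$user_id)
}

#' Remove all posts from the given users
#'
#' @param posts A post tibble.
#' @param users Character vector of user ids (e.g. from
#'   [flag_outlier_users()]), possibly after manual review.
#' @return The filtered tibble.
#' @export
remove_users <- function(posts, users) {
  posts[!(posts$user_id %in% users), , drop = FALSE]
}

#' Run the full cleaning sequence and record corpus statistics
#'
#' Applies [deduplicate()], [filter_job_posts()], and
#' [flag_outlier_users()] + [remove_users()] in order, recording the corpus
#' size after each step. The counts are monotone non-increasing by
#' construction.
#'
#' @param posts A post tibble.
#' @param outlier_threshold Passed to [flag_outlier_users()].
#' @return The cleaned tibble, with attribute `corpus_stats`: a one-row tibble
#'   with `n_total`, `n_after_dedup`, `n_after_job_filter`,
#'   `n_after_outlier_filter`, `flagged_users` (list column).
#' @export
clean_posts <- function(posts, outlier_threshold = 0.01) {
  n_total <- nrow(posts)
  posts <- deduplicate(posts)
  n_dedup <- nrow(posts)
  posts <- filter_job_posts(posts)
  n_job <- nrow(posts)
  flagged <- flag_outlier_users(posts, outlier_threshold)
  posts <- remove_users(posts, flagged$user_id)
  n_out <- nrow(posts)
  stats <- tibble(
    n_total = n_total, n_after_dedup = n_dedup,
    n_after_job_filter = n_job, n_after_outlier_filter = n_out,
    flagged_users = list(flagged$user_id)
  )
  stopifnot(n_total >= n_dedup, n_dedup >= n_job, n_job >= n_out)
  attr(posts, "corpus_stats") <- stats
  posts
}

#' Read and write posts as JSON-lines
#'
#' One JSON object per line with fields `id`, `user_id`, `created_at`,
#' `text`, `coordinates` (`[lon, lat]`, longitude first as in GeoJSON), plus
#' any area assignments present.
#'
#' @param posts A post tibble.
#' @param path File path.
#' @return `write_posts_jsonl()` returns `path` invisibly; `read_posts_jsonl()`
#'   returns a parsed post tibble.
#' @export
write_posts_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    rec <- list(
      id = posts$post_id[i], user_id = posts$user_id[i],
      created_at = posts$created_at[i], text = posts$text[i],
      coordinates = c(posts$lon[i], posts$lat[i])
    )
    for (extra in intersect(c("tract_id", "zip_id"), names(posts))) {
      rec[[extra]] <- posts[[extra]][i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_posts_jsonl
#' @export
read_posts_jsonl <- function(path) {
  parse_posts(path)
}
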