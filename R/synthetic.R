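#' Vocabulary model for synthetic posts
#'
#' Bundles the token classes the generator composes posts from: happy,
#' unhappy, and neutral sentiment terms (pairwise disjoint), plus food phrases
#' (with kcal per 100 g and healthy/fast-food flags) and physical-activity
#' phrases (with MET values and team-sport flags). All phrases are one or two
#' lowercase tokens.
#'
#' @param happy_terms,unhappy_terms,neutral_terms Character vectors of single
#'   tokens; must be pairwise disjoint.
#' @param food_terms Tibble with `phrase`, `kcal_per_100g`, `healthy`,
#'   `fastfood`.
#' @param activity_terms Tibble with `phrase`, `met`, `team_sport`.
#' @return A `vocab_model` object.
#' @export
vocab_model <- function(happy_terms, unhappy_terms, neutral_terms,
                        food_terms, activity_terms) {
  classes <- list(happy_terms, unhappy_terms, neutral_terms)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(classes[[i]], classes[[j]])) > 0L) {
      abort("sentiment term lists must be pairwise disjoint")
    }
  }
  all_phrases <- c(food_terms$phrase, activity_terms$phrase)
  n_tok <- lengths(strsplit(all_phrases, " "))
  if (any(n_tok < 1L | n_tok > 2L)) abort("phrases must be 1-2 tokens")
  if (any(food_terms$kcal_per_100g < 0)) abort("kcal must be >= 0")
  if (any(activity_terms$met <= 0)) abort("MET must be > 0")
  structure(list(
    happy_terms = happy_terms, unhappy_terms = unhappy_terms,
    neutral_terms = neutral_terms,
    food_terms = as_tibble(food_terms), activity_terms = as_tibble(activity_terms)
  ), class = "vocab_model")
}

#' Default vocabulary for simulations
#'
#' A small built-in vocabulary whose sentiment classes are disjoint and whose
#' food/activity phrases match the bundled fixture lexicons. Neutral terms
#' deliberately avoid tokens that could complete an activity exclusion idiom
#' (e.g. no "late", "away", or "dead"), so generated ground truth stays
#' recoverable by the matchers.
#'
#' @return A [vocab_model()].
#' @export
default_vocab <- function() {
  food <- load_food_lexicon(tweetscape_extdata("food_lexicon.csv"))
  act <- load_activity_lexicon(tweetscape_extdata("activity_lexicon.csv"),
                               tweetscape_extdata("activity_exclusions.txt"))
  vocab_model(
    happy_terms = c("happy", "love", "great", "awesome", "wonderful", "joy",
                    "amazing", "fantastic", "blessed", "smile", "excited",
                    "beautiful", "thrilled", "grateful"),
    unhappy_terms = c("sad", "angry", "terrible", "awful", "hate", "miserable",
                      "annoyed", "upset", "gloomy", "worst", "tired", "bored",
                      "stressed", "lonely"),
    neutral_terms = c("today", "morning", "downtown", "weather", "meeting",
                      "street", "coffee-shop", "bus", "office", "tonight",
                      "weekend", "city", "again", "really", "just"),
    food_terms = food$entries[, c("phrase", "kcal_per_100g", "healthy", "fastfood")],
    activity_terms = act$entries[, c("phrase", "met", "team_sport")]
  )
}

tweetscape_extdata <- function(file) {
  system.file("extdata", file, package = "tweetscape", mustWork = TRUE)
}

#' Per-area ground truth for the generator
#'
#' Convenience constructor for the per-area truth table consumed by
#' [simulate_posts()].
#'
#' @param layer An [area_layer()].
#' @param p_happy,p_food,p_activity Probabilities, recycled across areas.
#' @param n_posts Posts per area, recycled.
#' @return Tibble with `area_id`, `p_happy`, `p_food`, `p_activity`, `n_posts`.
#' @export
make_area_truth <- function(layer, p_happy = 0.2, p_food = 0.051,
                            p_activity = 0.018, n_posts = 200) {
  n <- nrow(layer$areas)
  truth <- tibble(
    area_id = layer$areas$area_id,
    p_happy = rep_len(p_happy, n), p_food = rep_len(p_food, n),
    p_activity = rep_len(p_activity, n), n_posts = rep_len(n_posts, n)
  )
  check_truth(truth)
  truth
}

check_truth <- function(truth) {
  probs <- c(truth$p_happy, truth$p_food, truth$p_activity)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (any(truth$n_posts < 0)) abort("n_posts must be >= 0")
  invisible(truth)
}

#' Simulate geotagged posts with known ground truth
#'
#' For each area in `truth`, draws `n_posts` points uniformly inside the
#' area's polygon (rejection sampling in its bounding box) and composes each
#' post's text from the vocabulary: with probability `p_happy` the sentiment
#' tokens come from the happy list, otherwise from the unhappy and neutral
#' lists; independently, a food phrase is inserted with probability `p_food`
#' and an activity phrase with probability `p_activity` (team-sport phrases
#' are accompanied by the token "played" so participation, not spectating, is
#' simulated). Ground-truth labels are returned in a sidecar table, never
#' embedded in the text. Identical seeds reproduce identical output.
#'
#' @param layer An [area_layer()].
#' @param truth Per-area truth table (see [make_area_truth()]).
#' @param vocab A [vocab_model()].
#' @param seed Integer seed.
#' @param n_users Number of distinct simulated users.
#' @return A list with `posts` (post tibble) and `truth_labels` (tibble:
#'   `post_id`, `area_id`, `happy`, `has_food`, `has_activity`).
#' @export
simulate_posts <- function(layer, truth, vocab, seed = 1L, n_users = 50L) {
  check_truth(truth)
  unknown <- setdiff(truth$area_id, layer$areas$area_id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown area id(s) in truth: ", paste(unknown, collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  rows <- vector("list", nrow(truth))
  labels <- vector("list", nrow(truth))
  counter <- 0L
  for (a in seq_len(nrow(truth))) {
    tr <- truth[a, ]
    i <- match(tr$area_id, layer$areas$area_id)
    rings <- layer$areas$geometry[[i]]
    bb <- layer$areas$bbox[[i]]
    n <- tr$n_posts
    if (n == 0L) next
    pts <- sample_points_in_polygon(n, rings, bb)
    happy <- runif(n) < tr$p_happy
    has_food <- runif(n) < tr$p_food
    has_act <- runif(n) < tr$p_activity
    text <- vapply(seq_len(n), function(k) {
      compose_post_text(vocab, happy[k], has_food[k], has_act[k])
    }, character(1))
    ids <- sprintf("p%06d", counter + seq_len(n))
    counter <- counter + n
    rows[[a]] <- tibble(
      post_id = ids,
      user_id = sprintf("u%03d", sample.int(n_users, n, replace = TRUE)),
      created_at = sprintf("2015-04-%02dT%02d:%02d:00Z",
                           sample.int(28, n, TRUE), sample.int(24, n, TRUE) - 1L,
                           sample.int(60, n, TRUE) - 1L),
      text = text, lon = pts[, 1L], lat = pts[, 2L]
    )
    labels[[a]] <- tibble(post_id = ids, area_id = tr$area_id,
                          happy = happy, has_food = has_food,
                          has_activity = has_act)
  }
  list(posts = bind_rows(rows), truth_labels = bind_rows(labels))
}

sample_points_in_polygon <- function(n, rings, bb) {
  out <- matrix(NA_real_, nrow = n, ncol = 2L)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    x <- runif(m, bb[1L], bb[3L])
    y <- runif(m, bb[2L], bb[4L])
    keep <- vapply(seq_len(m), function(j) point_in_polygon(x[j], y[j], rings),
                   logical(1))
    k <- min(sum(keep), n - got)
    if (k > 0L) {
      out[got + seq_len(k), 1L] <- x[keep][seq_len(k)]
      out[got + seq_len(k), 2L] <- y[keep][seq_len(k)]
      got <- got + k
    }
  }
  out
}

compose_post_text <- function(vocab, happy, has_food, has_activity) {
  n_sent <- sample(2:4, 1L)
  toks <- if (happy) {
    sample(vocab$happy_terms, n_sent)
  } else {
    # not-happy mixes unhappy and neutral language
    c(sample(vocab$unhappy_terms, max(1L, n_sent - 2L)),
      sample(vocab$neutral_terms, min(2L, n_sent - 1L)))
  }
  toks <- c(toks, sample(vocab$neutral_terms, 1L))
  if (has_food) {
    f <- vocab$food_terms[sample.int(nrow(vocab$food_terms), 1L), ]
    toks <- append(toks, strsplit(f$phrase, " ")[[1L]],
                   after = sample.int(length(toks), 1L) - 1L)
  }
  if (has_activity) {
    a <- vocab$activity_terms[sample.int(nrow(vocab$activity_terms), 1L), ]
    piece <- strsplit(a$phrase, " ")[[1L]]
    if (a$team_sport) piece <- c("played", piece)
    toks <- c(toks, piece)
  }
  paste(toks, collapse = " ")
}

#' Simulate a labeled sentiment corpus
#'
#' Generates `n` (text, label) pairs: with probability `p_happy` a document is
#' built from happy terms (label 1), otherwise from unhappy plus neutral terms
#' (label 0). Because the class vocabularies are disjoint, the corpus is
#' linearly separable and a well-trained classifier should approach the Bayes
#' rule on held-out data.
#'
#' @param n Number of examples (>= 1).
#' @param p_happy Probability an example is happy.
#' @param vocab A [vocab_model()].
#' @param seed Integer seed.
#' @return Tibble with columns `text`, `label` (1 = happy, 0 = not happy).
#' @export
simulate_labeled_corpus <- function(n, p_happy = 0.5, vocab = default_vocab(),
                                    seed = 1L) {
  if (n < 1) abort("`n` must be >= 1")
  if (length(vocab$happy_terms) == 0L || length(vocab$unhappy_terms) == 0L ||
      length(vocab$neutral_terms) == 0L) {
    abort("vocabulary class lists must be non-empty")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  label <- as.integer(runif(n) < p_happy)
  text <- vapply(label, function(y) {
    compose_post_text(vocab, y == 1L, FALSE, FALSE)
  }, character(1))
  tibble(text = text, label = label)
}

#' Simulate a corpus from a known token-logistic model
#'
#' Generates documents whose tokens `w1..wK` appear independently with
#' probability `p_token`, and labels drawn from a Bernoulli with success
#' probability `plogis(intercept + sum of weights of present tokens)`. Used to
#' check that the classifier recovers generating weights.
#'
#' @param n Number of documents.
#' @param weights Named numeric vector of generating token weights.
#' @param intercept Generating intercept.
#' @param p_token Per-token inclusion probability.
#' @param seed Integer seed.
#' @return Tibble with `text`, `label`, plus attribute `weights`.
#' @export
simulate_token_logistic <- function(n, weights, intercept = 0, p_token = 0.3,
                                    seed = 1L) {
  stopifnot(!is.null(names(weights)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  K <- length(weights)
  X <- matrix(runif(n * K) < p_token, nrow = n)
  eta <- intercept + X %*% weights
  label <- as.integer(runif(n) < plogis(eta))
  text <- vapply(seq_len(n), function(i) {
    present <- names(weights)[X[i, ]]
    if (length(present) == 0L) "empty-post" else paste(present, collapse = " ")
  }, character(1))
  out <- tibble(text = text, label = label)
  attr(out, "weights") <- weights
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
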