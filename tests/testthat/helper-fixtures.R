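# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture_food_lexicon <- function() {
  if (is.null(fixture_env$food)) {
    fixture_env$food <- load_food_lexicon(
      system.file("extdata", "food_lexicon.csv", package = "tweetscape"))
  }
  fixture_env$food
}

fixture_activity_lexicon <- function() {
  if (is.null(fixture_env$act)) {
    fixture_env$act <- load_activity_lexicon(
      system.file("extdata", "activity_lexicon.csv", package = "tweetscape"),
      system.file("extdata", "activity_exclusions.txt", package = "tweetscape"))
  }
  fixture_env$act
}

fixture_vocab <- function() {
  if (is.null(fixture_env$vocab)) fixture_env$vocab <- default_vocab()
  fixture_env$vocab
}

# a trained model on a separable corpus, reused across tests
fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    corpus <- simulate_labeled_corpus(1000, 0.5, fixture_vocab(), seed = 42)
    fixture_env$model <- train_maxent(corpus, l2_strength = 0.1)
  }
  fixture_env$model
}

make_posts <- function(text, user_id = "u1", lon = 0.5, lat = 0.5,
                       post_id = NULL) {
  n <- length(text)
  tibble::tibble(
    post_id = post_id %||% sprintf("p%03d", seq_len(n)),
    user_id = rep_len(user_id, n),
    created_at = rep("2015-06-01T00:00:00Z", n),
    text = text,
    lon = rep_len(lon, n), lat = rep_len(lat, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
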