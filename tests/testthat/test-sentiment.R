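test_that("feature extraction is binary presence over the vocabulary", {
  vocab <- build_vocabulary(list(c("great", "day"), c("bad", "day")))
  expect_equal(extract_features(character(), vocab), integer())
  expect_equal(extract_features(c("great", "great"), vocab),
               extract_features("great", vocab))
  toks <- c("great", "unknown", "day", "nonsense")
  expect_equal(extract_features(toks, vocab),
               sort(unname(vocab[c("great", "day")])))
})

test_that("training reaches near-perfect accuracy on a separable corpus", {
  corpus <- simulate_labeled_corpus(600, 0.5, fixture_vocab(), seed = 31)
  model <- train_maxent(corpus, l2_strength = 0.1)
  sc <- happy_score(model, corpus$text)
  expect_gte(mean(classify_happy(sc, 0.5) == corpus$label), 0.95)
  expect_true(model$training_log$converged)
})

test_that("labels independent of tokens give scores near 0.5", {
  withr::with_seed(8, {
    texts <- replicate(400, paste(sample(letters[1:6], 4, TRUE), collapse = " "))
    labels <- rbinom(400, 1, 0.5)
  })
  model <- train_maxent(tibble::tibble(text = texts, label = labels),
                        l2_strength = 1)
  sc <- happy_score(model, texts)
  expect_true(all(abs(sc - 0.5) < 0.2))
  expect_lt(abs(mean(sc) - 0.5), 0.05)
})

test_that("single-class training is rejected", {
  expect_error(train_maxent(tibble::tibble(text = c("a", "b"), label = c(1, 1))),
               "both classes")
})

test_that("duplicating the training set leaves the unpenalized fit unchanged", {
  # tokens included independently with class-dependent probabilities: the
  # corpus overlaps (finite MLE) and no exact collinearity arises
  withr::with_seed(13, {
    n <- 300
    happy <- rbinom(n, 1, 0.5)
    texts <- vapply(happy, function(y) {
      p <- if (y == 1) c(good = 0.7, nice = 0.6, bad = 0.2, poor = 0.25)
           else c(good = 0.25, nice = 0.2, bad = 0.7, poor = 0.6)
      paste(names(p)[runif(4) < p], collapse = " ")
    }, character(1))
  })
  df <- tibble::tibble(text = texts, label = happy)
  m1 <- train_maxent(df, l2_strength = 0, tolerance = 1e-8)
  m2 <- train_maxent(dplyr::bind_rows(df, df), l2_strength = 0, tolerance = 1e-8)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-6)
})

test_that("training matches glm() on a small unpenalized problem", {
  withr::with_seed(21, {
    n <- 200
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x1 - 0.8 * x2))
  })
  texts <- vapply(seq_len(n), function(i) {
    paste(c(if (x1[i]) "alpha", if (x2[i]) "beta"), collapse = " ")
  }, character(1))
  model <- train_maxent(tibble::tibble(text = texts, label = y),
                        l2_strength = 0, tolerance = 1e-10)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(model$weights["alpha"]), unname(coef(ref)["x1"]),
               tolerance = 1e-5)
  expect_equal(unname(model$weights["beta"]), unname(coef(ref)["x2"]),
               tolerance = 1e-5)
  expect_equal(unname(model$weights["(bias)"]),
               unname(coef(ref)["(Intercept)"]), tolerance = 1e-5)
})

test_that("regularization monotonicity: more penalty, lower train likelihood", {
  corpus <- simulate_labeled_corpus(300, 0.5, fixture_vocab(), seed = 17)
  loglik <- function(l2) {
    m <- train_maxent(corpus, l2_strength = l2)
    sc <- happy_score(m, corpus$text)
    sum(log(ifelse(corpus$label == 1, sc, 1 - sc)))
  }
  lls <- vapply(c(0.01, 0.5, 2, 10), loglik, numeric(1))
  expect_true(all(diff(lls) < 1e-8))
})

test_that("happy_score behaves at the margins", {
  model <- fixture_model()
  vocab <- fixture_vocab()
  happy_text <- paste(vocab$happy_terms[1:4], collapse = " ")
  expect_gt(happy_score(model, happy_text), 0.9)
  # unseen token -> bias-only posterior, same as empty input
  expect_equal(happy_score(model, "zzzunseen"),
               happy_score(model, character()))
  withr::with_seed(4, {
    rand <- replicate(50, paste(sample(c(vocab$happy_terms, vocab$unhappy_terms,
                                         "zzz"), 5, TRUE), collapse = " "))
  })
  sc <- happy_score(model, rand)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("exactly symmetric training data scores an unseen token at 0.5", {
  df <- tibble::tibble(text = c("up", "down"), label = c(1L, 0L))
  m <- train_maxent(df, l2_strength = 1)
  expect_equal(unname(happy_score(m, "neverseen")), 0.5, tolerance = 1e-6)
})

test_that("classify_happy applies an inclusive cutpoint", {
  expect_equal(classify_happy(0.80), 1L)
  expect_equal(classify_happy(0.79), 0L)
  expect_equal(classify_happy(c(0, 0.5, 1), cutpoint = 0), c(1L, 1L, 1L))
  expect_error(classify_happy(1.2), "\\[0, 1\\]")
})

test_that("calibration table matches hand-enumerated confusion tables", {
  # scores {0.9, 0.7, 0.2}, labels {1, 1, 0}: accuracy 1 at 0.5, 2/3 at 0.8
  tab <- calibrate_threshold(c(0.9, 0.7, 0.2), c(1, 1, 0), grid = c(0.5, 0.8))
  expect_equal(tab$accuracy, c(1, 2 / 3))
  expect_equal(attr(tab, "selected_cutpoint"), 0.5)
  # perfect scores: accuracy 1 at every interior cutpoint
  tab2 <- calibrate_threshold(c(1, 1, 0, 0), c(1, 1, 0, 0),
                              grid = c(0.25, 0.5, 0.75))
  expect_true(all(tab2$accuracy == 1))
  # prevalence non-increasing on any grid
  withr::with_seed(6, { sc <- runif(200); lb <- rbinom(200, 1, 0.3) })
  tab3 <- calibrate_threshold(sc, lb)
  expect_true(all(diff(tab3$predicted_happy_prevalence) <= 0))
  expect_error(calibrate_threshold(sc, lb[-1]), "length")
})

test_that("accuracy ties break toward the labeled prevalence", {
  # both cutpoints get accuracy 0.5; 0.9 predicts prevalence 0 vs labeled 0.5
  tab <- calibrate_threshold(c(0.6, 0.6), c(1, 0), grid = c(0.5, 0.9))
  expect_equal(tab$accuracy, c(0.5, 0.5))
  expect_equal(attr(tab, "selected_cutpoint"), 0.5)
})

test_that("baseline valence score averages matched tokens only", {
  tab <- c(happy = 8, sad = 2, ok = 5)
  expect_equal(baseline_valence_score(c("happy", "sad"), tab), 5)
  expect_equal(baseline_valence_score(c("x", "y"), tab), NA_real_)
  expect_equal(baseline_valence_score(c("sad", "happy"), tab),
               baseline_valence_score(c("happy", "sad"), tab))
  expect_equal(baseline_valence_score(c("happy", "z"), tab, coverage_min = 2),
               NA_real_)
  expect_error(baseline_valence_score("a", numeric()), "non-empty")
})

test_that("quality report computes the hand formulas", {
  # confusion TP=2 FP=1 FN=1 TN=6 -> accuracy 0.8, F = 2/3
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  ref  <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  q <- evaluate_against_labels(pred, ref)
  expect_equal(q$accuracy, 0.8)
  expect_equal(q$f_score, 2 / 3)
  expect_equal(c(q$tp, q$fp, q$fn, q$tn), c(2, 1, 1, 6))
  # perfect agreement
  q2 <- evaluate_against_labels(ref, ref)
  expect_equal(q2$accuracy, 1)
  expect_equal(q2$f_score, 1)
  # all-negative predictions with positives present: F 0 by convention
  q3 <- suppressMessages(evaluate_against_labels(rep(0, 4), c(1, 0, 1, 0)))
  expect_equal(q3$f_score, 0)
  expect_error(evaluate_against_labels(integer(), integer()), "non-empty")
})

test_that("models round-trip through JSON serialization", {
  model <- fixture_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_sentiment_model(model, f)
  back <- load_sentiment_model(f)
  expect_equal(back$weights, model$weights)
  expect_equal(back$cutpoint, model$cutpoint)
  texts <- c("happy great day", "sad awful morning")
  expect_equal(happy_score(back, texts), happy_score(model, texts))
})

test_that("tidy and glance expose the fit", {
  model <- fixture_model()
  td <- tidy(model)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(td), length(model$weights))
  gl <- glance(model)
  expect_equal(gl$cutpoint, 0.80)
  expect_true(gl$converged)
})
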