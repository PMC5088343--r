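#' Build a vocabulary from tokenized training documents
#'
#' @param token_lists List of token vectors.
#' @param min_count Drop tokens seen in fewer than `min_count` documents.
#' @return Named integer vector mapping token to feature id.
#' @export
build_vocabulary <- function(token_lists, min_count = 1L) {
  tab <- table(unlist(lapply(token_lists, unique)))
  toks <- sort(names(tab)[tab >= min_count])
  stats::setNames(seq_along(toks), toks)
}

#' Extract a binary unigram feature vector
#'
#' Features are binary presence indicators of in-vocabulary unigrams plus an
#' always-on bias feature; repeated tokens contribute once and
#' out-of-vocabulary tokens are ignored.
#'
#' @param tokens Token vector.
#' @param vocabulary Named integer map from [build_vocabulary()].
#' @return Sorted integer vector of active feature ids (the bias is implicit).
#' @export
extract_features <- function(tokens, vocabulary) {
  ids <- vocabulary[unique(tokens)]
  sort(unname(ids[!is.na(ids)]))
}

#' Train the maximum-entropy (penalized logistic) sentiment classifier
#'
#' Two-class maximum entropy over binary unigram features is exactly
#' L2-penalized logistic regression, fit here by Newton iterations with step
#' halving on the penalized negative log-likelihood. The objective is convex,
#' initialization is at zero, and the stopping rule is the sup-norm of the
#' gradient, so training is deterministic given the example order. The bias
#' weight is not penalized.
#'
#' @param data Data frame with a text column and a 0/1 label column (1 =
#'   happy). The text column may hold strings (tokenized internally) or a
#'   list of token vectors.
#' @param text,label Column names.
#' @param l2_strength Nonnegative L2 penalty on token weights (default 1).
#' @param tolerance Convergence tolerance on the gradient sup-norm.
#' @param max_iter Maximum Newton iterations; non-convergence warns but still
#'   returns the model.
#' @param min_count Vocabulary pruning threshold.
#' @return A `sentiment_maxent` model: vocabulary, named weight vector
#'   (including `"(bias)"`), penalty, cutpoint (default 0.80, see
#'   [calibrate_threshold()]), and a training log.
#' @export
train_maxent <- function(data, text = "text", label = "label",
                         l2_strength = 1, tolerance = 1e-6, max_iter = 500L,
                         min_count = 1L) {
  stopifnot(is.data.frame(data))
  if (tolerance <= 0) abort("`tolerance` must be > 0")
  if (l2_strength < 0) abort("`l2_strength` must be >= 0")
  y <- as.integer(data[[label]])
  if (length(unique(y)) < 2L) {
    abort("training set must contain both classes")
  }
  toks <- data[[text]]
  if (!is.list(toks)) toks <- tokenize_list(as.character(toks))
  vocab <- build_vocabulary(toks, min_count = min_count)
  V <- length(vocab)
  n <- length(y)

  # dense n x (V+1) design; column 1 is the bias
  X <- matrix(0, nrow = n, ncol = V + 1L)
  X[, 1L] <- 1
  for (i in seq_len(n)) {
    ids <- extract_features(toks[[i]], vocab)
    if (length(ids) > 0L) X[i, ids + 1L] <- 1
  }
  pen <- c(0, rep(l2_strength, V))  # bias unpenalized

  w <- numeric(V + 1L)
  nll <- function(w) {
    eta <- drop(X %*% w)
    # numerically stable -loglik
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(pen * w^2) / 2
  }
  obj <- nll(w)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- plogis(drop(X %*% w))
    g <- drop(crossprod(X, p - y)) + pen * w
    if (max(abs(g)) < tolerance) { converged <- TRUE; break }
    wts <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * wts, X)
    diag(H) <- diag(H) + pen
    # exactly collinear features (e.g. a token present in every document,
    # duplicating the bias) make H singular at l2 = 0; a tiny ridge on the
    # step keeps the direction well-defined without moving the optimum
    step <- tryCatch(solve(H, g), error = function(e) {
      diag(H) <- diag(H) + 1e-8 * max(diag(H))
      solve(H, g)
    })
    # step halving keeps the Newton update monotone on the penalized objective
    alpha <- 1
    repeat {
      w_new <- w - alpha * step
      obj_new <- nll(w_new)
      if (obj_new <= obj + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    w <- w_new
    obj <- obj_new
  }
  if (!converged) {
    p <- plogis(drop(X %*% w))
    g <- drop(crossprod(X, p - y)) + pen * w
    converged <- max(abs(g)) < tolerance
    if (!converged) {
      warn(paste0("train_maxent: not converged after ", iter,
                  " iterations (gradient sup-norm ",
                  format(max(abs(g)), digits = 3), ")"))
    }
  }
  weights <- stats::setNames(w, c("(bias)", names(vocab)))
  structure(list(
    vocabulary = vocab, weights = weights, l2_strength = l2_strength,
    cutpoint = 0.80,
    training_log = list(iterations = iter, objective = obj, converged = converged)
  ), class = "sentiment_maxent")
}

#' @export
print.sentiment_maxent <- function(x, ...) {
  cat("<sentiment_maxent: ", length(x$vocabulary), " features, l2 = ",
      x$l2_strength, ", cutpoint = ", x$cutpoint, ">\n", sep = "")
  invisible(x)
}

#' Happy score of a post
#'
#' Posterior probability of the happy class under the fitted logistic model.
#' Out-of-vocabulary tokens are ignored; an empty token list yields the
#' bias-only posterior. Always in [0, 1].
#'
#' @param model A `sentiment_maxent` model.
#' @param tokens A token vector, a list of token vectors, or a character
#'   vector of raw texts (tokenized internally).
#' @return Numeric vector of scores in [0, 1].
#' @export
happy_score <- function(model, tokens) {
  stopifnot(inherits(model, "sentiment_maxent"))
  if (is.character(tokens) && length(tokens) == 0L) {
    tokens <- list(character())  # one empty post, not zero posts
  } else if (is.character(tokens)) {
    tokens <- tokenize_list(tokens)
  }
  if (!is.list(tokens)) tokens <- list(tokens)
  w <- model$weights
  vapply(tokens, function(tk) {
    ids <- extract_features(tk, model$vocabulary)
    plogis(w[[1L]] + sum(w[ids + 1L]))
  }, numeric(1))
}

#' Classify a happy score at a cutpoint
#'
#' Happy iff `score >= cutpoint`; the boundary is inclusive, so the default
#' operational cutpoint 0.80 classifies a score of exactly 0.80 as happy.
#'
#' @param score Numeric scores in [0, 1].
#' @param cutpoint Threshold in [0, 1]; default 0.80.
#' @return Integer vector of 0/1 labels.
#' @export
classify_happy <- function(score, cutpoint = 0.80) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("scores must lie in [0, 1]")
  }
  as.integer(score >= cutpoint)
}

#' Calibrate the classification cutpoint against human labels
#'
#' Computes accuracy and predicted-happy prevalence at each candidate
#' cutpoint. The selected cutpoint maximizes accuracy; ties are broken toward
#' the cutpoint whose predicted prevalence is closest to the labeled
#' prevalence, so the operating point preserves the prevalence human raters
#' see. Raising the cutpoint can only shrink the set of posts called happy, so
#' the prevalence column is non-increasing.
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels 0/1 reference labels, same length.
#' @param grid Strictly increasing cutpoint grid.
#' @return A `calibration_table` tibble with columns `cutpoint`, `accuracy`,
#'   `predicted_happy_prevalence`, and attribute `selected_cutpoint`.
#' @export
calibrate_threshold <- function(scores, labels,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length")
  }
  if (length(grid) == 0L) abort("`grid` must be non-empty")
  grid <- sort(unique(grid))
  tab <- tibble(
    cutpoint = grid,
    accuracy = vapply(grid, function(cp) mean((scores >= cp) == (labels == 1)),
                      numeric(1)),
    predicted_happy_prevalence = vapply(grid, function(cp) mean(scores >= cp),
                                        numeric(1))
  )
  best <- which(tab$accuracy == max(tab$accuracy))
  if (length(best) > 1L) {
    prev_gap <- abs(tab$predicted_happy_prevalence[best] - mean(labels == 1))
    best <- best[which.min(prev_gap)]
  }
  structure(tab, selected_cutpoint = tab$cutpoint[best],
            class = c("calibration_table", class(tab)))
}

#' @export
print.calibration_table <- function(x, ...) {
  NextMethod()
  cat("selected cutpoint:", attr(x, "selected_cutpoint"), "\n")
  invisible(x)
}

#' Bag-of-words valence baseline
#'
#' Scores a post as the arithmetic mean valence of its tokens found in a
#' valence word list (e.g. a 1-9 hedonic rating table). Undefined (`NA`) when
#' fewer than `coverage_min` tokens match.
#'
#' @param tokens Token vector.
#' @param valence_table Named numeric vector (token -> valence).
#' @param coverage_min Minimum number of matched tokens.
#' @return Mean valence, or `NA`.
#' @export
baseline_valence_score <- function(tokens, valence_table, coverage_min = 1L) {
  if (length(valence_table) == 0L) abort("valence table must be non-empty")
  vals <- valence_table[tokens[tokens %in% names(valence_table)]]
  if (length(vals) < coverage_min) return(NA_real_)
  mean(vals)
}

#' Evaluate predictions against reference labels
#'
#' @param predicted,reference 0/1 vectors of equal, nonzero length.
#' @return A `quality_report`: one-row tibble with `accuracy`, `precision`,
#'   `recall`, `f_score` (F1 on the positive class) and the 2x2 confusion
#'   counts `tp`, `fp`, `fn`, `tn`. When no positives are predicted but
#'   positives exist, F is 0 by convention (reported via a message).
#' @export
evaluate_against_labels <- function(predicted, reference) {
  if (length(predicted) == 0L || length(predicted) != length(reference)) {
    abort("`predicted` and `reference` must be non-empty and of equal length")
  }
  predicted <- as.integer(predicted)
  reference <- as.integer(reference)
  tp <- sum(predicted == 1L & reference == 1L)
  fp <- sum(predicted == 1L & reference == 0L)
  fn <- sum(predicted == 0L & reference == 1L)
  tn <- sum(predicted == 0L & reference == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  if (tp + fp == 0L && tp + fn > 0L) {
    inform("no positive predictions with positives present: F set to 0")
  }
  structure(tibble(
    accuracy = (tp + tn) / length(predicted),
    precision = precision, recall = recall, f_score = f,
    tp = tp, fp = fp, fn = fn, tn = tn
  ), class = c("quality_report", class(tibble())))
}

#' Serialize / restore a sentiment model as JSON
#'
#' @param model A `sentiment_maxent` model.
#' @param path File path.
#' @return `save_sentiment_model()` returns `path` invisibly;
#'   `load_sentiment_model()` returns the model.
#' @export
save_sentiment_model <- function(model, path) {
  obj <- list(
    vocabulary = as.list(model$vocabulary),
    weights = as.list(model$weights),
    l2_strength = model$l2_strength,
    cutpoint = model$cutpoint,
    training_log = model$training_log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_sentiment_model
#' @export
load_sentiment_model <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(
    vocabulary = stats::setNames(as.integer(unlist(obj$vocabulary)),
                                 names(obj$vocabulary)),
    weights = stats::setNames(as.numeric(unlist(obj$weights)),
                              names(obj$weights)),
    l2_strength = obj$l2_strength,
    cutpoint = obj$cutpoint,
    training_log = obj$training_log
  ), class = "sentiment_maxent")
}

#' Tidy a fitted sentiment model
#'
#' @param x A `sentiment_maxent` model.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (the token weights; the bias is
#'   the `"(bias)"` term).
#' @method tidy sentiment_maxent
#' @export
tidy.sentiment_maxent <- function(x, ...) {
  tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @rdname tidy.sentiment_maxent
#' @method glance sentiment_maxent
#' @export
glance.sentiment_maxent <- function(x, ...) {
  tibble(n_features = length(x$vocabulary),
         l2_strength = x$l2_strength,
         cutpoint = x$cutpoint,
         iterations = x$training_log$iterations,
         objective = x$training_log$objective,
         converged = x$training_log$converged)
}
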