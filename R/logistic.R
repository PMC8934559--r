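# Logistic-regression classifiers and the shared training/evaluation
# protocol (repeated two-fold cross-validation with score averaging).

#' Fit a logistic-regression classifier
#'
#' Plain binomial GLM on the feature matrix; scores are fitted mirror
#' probabilities in `[0,1]`.  Perfect separation is allowed (the fitted
#' probabilities saturate); the accompanying convergence warnings are
#' suppressed.
#'
#' @param features numeric matrix (rows = images).
#' @param labels vector coercible to 0/1 (1 or `"mirror"` = mirror).
#' @return a `logistic_model` with a `predict_score(newdata)` closure.
#' @export
fit_logistic <- function(features, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) stop("single-class input: need both classes")
  x <- as.matrix(features)
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  structure(list(
    fit = fit,
    predict_score = function(newdata) {
      nd <- data.frame(matrix(as.matrix(newdata), ncol = ncol(x)))
      colnames(nd) <- colnames(df)[-1]
      p <- suppressWarnings(
        stats::predict(fit, newdata = nd, type = "response"))
      pmin(pmax(unname(p), 0), 1)
    }), class = "logistic_model")
}

# labels -> 0/1 with 1 = mirror.  Ambiguous classes keep the label of the
# class their generator stands in for (amb_mirror -> mirror).
as_binary_label <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  l <- as.character(labels)
  out <- ifelse(l %in% c("mirror", "amb_mirror", "1"), 1L,
                ifelse(l %in% c("glass", "amb_glass", "0"), 0L, NA_integer_))
  if (anyNA(out)) stop("unrecognized class labels")
  out
}

#' Threshold a prediction score into a class
#'
#' Scores below 0.5 are glass; 0.5 or greater is mirror.
#'
#' @param score numeric vector in `[0,1]`.
#' @return character vector of `"glass"` / `"mirror"`.
#' @export
score_to_class <- function(score) {
  if (any(score < 0 | score > 1)) stop("scores must lie in [0,1]")
  ifelse(score < 0.5, "glass", "mirror")
}

#' Classification accuracy of scores against labels
#'
#' @param scores numeric vector in `[0,1]`.
#' @param labels class labels (character or 0/1).
#' @return fraction correct in `[0,1]`.
#' @export
accuracy <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- as_binary_label(score_to_class(scores))
  mean(pred == as_binary_label(labels))
}

#' Repeated two-fold cross-validated prediction scores
#'
#' Each repeat draws a fresh stratified 50/50 split; a model is trained on
#' each half and scores the other half, so every image is a test item exactly
#' once per repeat.  Final scores are the per-image mean across repeats.
#'
#' @param factory function `(features, labels) -> model` where the model has
#'   a `predict_score(newdata)` closure (e.g. [fit_logistic()] or a CNN
#'   factory from [cnn_factory()]).
#' @param features matrix (rows = images, rownames = ids) or a 4-D image
#'   array with ids in `dimnames(x)[[4]]`.
#' @param labels per-image class labels, same order as rows.
#' @param n_repeats number of repeats (default 10).
#' @param seed master seed for the splits.
#' @return list with `scores` (data frame image_id, score), `per_repeat`
#'   (matrix images x repeats) and `accuracy` (at the 0.5 rule against
#'   `labels`).
#' @export
crossval_predict <- function(factory, features, labels, n_repeats = 10L,
                             seed = 1L) {
  is_array <- length(dim(features)) == 4L
  n <- if (is_array) dim(features)[4] else nrow(features)
  ids <- if (is_array) dimnames(features)[[4]] else rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  y <- as_binary_label(labels)
  if (min(table(y)) < 2L) stop("need at least 2 images per class")
  take <- function(idx) {
    if (is_array) features[, , , idx, drop = FALSE]
    else features[idx, , drop = FALSE]
  }
  per_repeat <- matrix(NA_real_, n, n_repeats,
                       dimnames = list(ids, NULL))
  for (r in seq_len(n_repeats)) {
    split_seed <- derive_seed(seed, r)
    fold1 <- with_rng(split_seed, {
      unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, floor(length(ix) / 2))))
    })
    fold1 <- sort(fold1)
    fold2 <- setdiff(seq_len(n), fold1)
    takes_seed <- "seed" %in% names(formals(factory))
    for (fold in 1:2) {
      tr <- if (fold == 1) fold1 else fold2
      te <- if (fold == 1) fold2 else fold1
      model <- tryCatch(
        if (takes_seed)
          factory(take(tr), labels[tr], seed = derive_seed(seed, 100L * r + fold))
        else factory(take(tr), labels[tr]),
        error = function(e) stop("classifier factory failed in repeat ", r,
                                 ", fold ", fold, ": ", conditionMessage(e),
                                 call. = FALSE))
      per_repeat[te, r] <- model$predict_score(take(te))
    }
  }
  score <- rowMeans(per_repeat)
  list(scores = data.frame(image_id = ids, score = unname(score),
                           stringsAsFactors = FALSE),
       per_repeat = per_repeat,
       accuracy = accuracy(score, labels))
}
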