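# Hyperparameter search maximizing correlation with (simulated) human
# judgments on the diagnostic set, the multi-instance validation of the
# winning configuration, and the depth sweep.

#' Search space over the 11 CNN hyperparameters
#'
#' Each entry is `list(type, values|lo, hi, log)`; integer and choice
#' parameters are sampled uniformly, continuous parameters uniformly on a
#' linear or log scale.
#'
#' @return a named list (a `search_space`).
#' @export
default_search_space <- function() {
  structure(list(
    filters_base = list(type = "int", lo = 4L, hi = 24L, log = TRUE),
    filter_growth = list(type = "num", lo = 1.0, hi = 2.0, log = FALSE),
    kernel_size = list(type = "choice", values = c(3L, 5L)),
    pool_size = list(type = "choice", values = 2L),
    fc_units = list(type = "int", lo = 8L, hi = 48L, log = TRUE),
    dropout_rate = list(type = "num", lo = 0, hi = 0.5, log = FALSE),
    init_learning_rate = list(type = "num", lo = 5e-3, hi = 1e-1, log = TRUE),
    momentum = list(type = "num", lo = 0.5, hi = 0.95, log = FALSE),
    l2_penalty = list(type = "num", lo = 1e-6, hi = 1e-3, log = TRUE),
    batch_size = list(type = "choice", values = c(8L, 16L, 32L)),
    lr_decay = list(type = "num", lo = 0.8, hi = 1.0, log = FALSE)
  ), class = "search_space")
}

# sample one hyperparameter setting; returns a named list
sample_hyper <- function(space, seed) {
  with_rng(seed, {
    out <- lapply(space, function(p) {
      switch(p$type,
        choice = p$values[sample.int(length(p$values), 1L)],
        int = {
          if (isTRUE(p$log)) {
            as.integer(round(exp(stats::runif(1, log(p$lo), log(p$hi)))))
          } else as.integer(round(stats::runif(1, p$lo, p$hi)))
        },
        num = {
          if (isTRUE(p$log)) exp(stats::runif(1, log(p$lo), log(p$hi)))
          else stats::runif(1, p$lo, p$hi)
        })
    })
    out
  })
}

# map [0,1]^d coordinates back to a concrete setting
hyper_from_coords <- function(space, xc) {
  out <- lapply(seq_along(space), function(i) {
    p <- space[[i]]; v <- min(max(xc[i], 0), 1)
    switch(p$type,
      choice = p$values[round(v * (length(p$values) - 1)) + 1L],
      int = {
        if (isTRUE(p$log)) {
          as.integer(round(exp(log(p$lo) + v * (log(p$hi) - log(p$lo)))))
        } else as.integer(round(p$lo + v * (p$hi - p$lo)))
      },
      num = {
        if (isTRUE(p$log)) exp(log(p$lo) + v * (log(p$hi) - log(p$lo)))
        else p$lo + v * (p$hi - p$lo)
      })
  })
  names(out) <- names(space)
  out
}

# map a setting to [0,1]^d coordinates for the surrogate distance metric
hyper_coords <- function(space, setting) {
  vapply(names(space), function(nm) {
    p <- space[[nm]]; v <- setting[[nm]]
    switch(p$type,
      choice = if (length(p$values) == 1L) 0.5
               else (match(v, p$values) - 1) / (length(p$values) - 1),
      int = ,
      num = {
        if (isTRUE(p$log)) (log(v) - log(p$lo)) / (log(p$hi) - log(p$lo))
        else (v - p$lo) / (p$hi - p$lo)
      })
  }, numeric(1))
}

#' Human-correlation objective
#'
#' Pearson correlation between model prediction scores and human mean
#' normalized ratings on the diagnostic set.
#'
#' @param model_scores,human_mean_ratings aligned numeric vectors (>= 3).
#' @return correlation in `[-1, 1]`; errors on zero-variance input.
#' @export
human_correlation_objective <- function(model_scores, human_mean_ratings) {
  pearson_strict(model_scores, human_mean_ratings, what = "objective input")
}

# train a spec with two-fold CV on the pool and score the diagnostic set
audit_disjoint <- function(pool_x, diag_x) {
  pool_ids <- dimnames(pool_x)[[4]]
  diag_ids <- dimnames(diag_x)[[4]]
  if (!is.null(pool_ids) && !is.null(diag_ids) &&
      length(intersect(pool_ids, diag_ids))) {
    stop("diagnostic images must never appear in the training pool")
  }
  invisible(TRUE)
}

evaluate_spec <- function(spec, pool_x, pool_y, diag_x, diag_ratings, seed,
                          max_epochs = 4L) {
  audit_disjoint(pool_x, diag_x)
  n <- dim(pool_x)[4]
  y <- as_binary_label(pool_y)
  # one stratified two-fold split; each fold-model scores the held-out half
  # (pool accuracy) and the diagnostic set (objective, averaged over folds)
  fold1 <- with_rng(derive_seed(seed, 1L), {
    sort(unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, floor(length(ix) / 2)))))
  })
  fold2 <- setdiff(seq_len(n), fold1)
  fac <- cnn_factory(spec, max_epochs = max_epochs)
  heldout <- numeric(n)
  diag_s <- matrix(0, dim(diag_x)[4], 2L)
  folds <- list(fold1, fold2)
  for (f in 1:2) {
    tr <- folds[[f]]; te <- folds[[3 - f]]
    m <- fac(pool_x[, , , tr, drop = FALSE], pool_y[tr],
             seed = derive_seed(seed, 100L + f))
    heldout[te] <- m$predict_score(pool_x[, , , te, drop = FALSE])
    diag_s[, f] <- m$predict_score(diag_x)
  }
  s <- rowMeans(diag_s)
  list(objective = human_correlation_objective(s, diag_ratings),
       accuracy = accuracy(heldout, pool_y), diag_scores = s)
}

#' Hyperparameter search at a fixed depth
#'
#' Each iteration samples a hyperparameter setting (uniformly for
#' `strategy = "random"`, or by a sequential surrogate that proposes the
#' candidate with the best predicted objective plus an exploration bonus
#' for `strategy = "surrogate"`), trains the CNN with two-fold
#' cross-validation on the training pool, and scores the human-correlation
#' objective on the held-out diagnostic set.  Failed trials are recorded
#' and skipped.
#'
#' @param depth network depth for every trial.
#' @param space a `search_space`.
#' @param pool_x,pool_y training pool (never contains diagnostic ids).
#' @param diag_x,diag_ratings diagnostic images and human mean ratings.
#' @param n_iter search iterations (default 200).
#' @param strategy `"surrogate"` or `"random"`.
#' @param seed master seed.
#' @param max_epochs per-trial training epochs (desk-scale default 4).
#' @param evaluator trial evaluator `function(spec, seed) ->
#'   list(objective, accuracy)`; the default trains the CNN with two-fold
#'   cross-validation on the pool and scores the diagnostic objective.
#'   Injectable for testing the search logic against cheap objectives.
#' @return list with `best` (list: spec, objective, accuracy, iteration)
#'   and `trace` (data frame per iteration, including the monotone
#'   best-so-far curve).
#' @export
search_depth <- function(depth, space = default_search_space(),
                         pool_x, pool_y, diag_x, diag_ratings,
                         n_iter = 200L, strategy = c("surrogate", "random"),
                         seed = 1L, max_epochs = 4L, evaluator = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(evaluator)) {
    audit_disjoint(pool_x, diag_x)
    evaluator <- function(spec, seed) {
      evaluate_spec(spec, pool_x, pool_y, diag_x, diag_ratings,
                    seed = seed, max_epochs = max_epochs)
    }
  }
  # random warm-up before the surrogate takes over; about a third of small
  # budgets, capped at 5
  n_init <- min(5L, max(2L, ceiling(n_iter / 3)), n_iter)
  trials <- list()
  trace <- data.frame()
  best <- list(objective = -Inf)
  coords <- NULL
  for (it in seq_len(n_iter)) {
    if (strategy == "random" || it <= n_init) {
      setting <- sample_hyper(space, derive_seed(seed, it))
    } else {
      # surrogate: candidates mix fresh global samples with local jitters
      # of the incumbent; scored by inverse-distance-weighted prediction
      # over observed trials plus an exploration bonus on the distance to
      # the nearest one
      glob <- lapply(seq_len(16L), function(c)
        sample_hyper(space, derive_seed(seed, 10000L + it * 100L + c)))
      loc <- if (!is.null(best$setting)) {
        best_xc <- hyper_coords(space, best$setting)
        lapply(seq_len(16L), function(c) {
          jit <- with_rng(derive_seed(seed, 20000L + it * 100L + c),
                          stats::rnorm(length(best_xc), 0, 0.08))
          hyper_from_coords(space, best_xc + jit)
        })
      } else list()
      cand <- c(glob, loc)
      obs_y <- vapply(trials, function(t) t$objective, numeric(1))
      pred <- vapply(cand, function(s) {
        xc <- hyper_coords(space, s)
        d <- sqrt(colSums((t(coords) - xc)^2))
        k <- order(d)[seq_len(min(3L, length(d)))]
        w <- 1 / (d[k] + 1e-6)^2
        sum(w * obs_y[k]) / sum(w) + 0.05 * min(d)
      }, numeric(1))
      setting <- cand[[which.max(pred)]]
    }
    spec <- do.call(cnn_spec, c(list(depth = depth), setting))
    res <- tryCatch(
      evaluator(spec, derive_seed(seed, 500L + it)),
      error = function(e) NULL)
    obj <- if (is.null(res)) NA_real_ else res$objective
    trials[[it]] <- list(setting = setting, spec = spec,
                         objective = if (is.null(res)) -Inf else obj)
    coords <- rbind(coords, hyper_coords(space, setting))
    if (!is.null(res) && obj > best$objective) {
      best <- list(spec = spec, setting = setting, objective = obj,
                   accuracy = res$accuracy, iteration = it)
    }
    trace <- rbind(trace, data.frame(
      iteration = it, objective = obj,
      accuracy = if (is.null(res)) NA_real_ else res$accuracy,
      best_so_far = if (is.finite(best$objective)) best$objective else NA_real_,
      failed = is.null(res)))
  }
  list(best = best, trace = trace)
}

#' Validate a configuration across training instances
#'
#' Retrains `n_instances` networks that differ only in their initial random
#' state and reports the per-instance objective; the headline value is the
#' maximum across instances.
#'
#' @param best_spec a [cnn_spec()].
#' @param pool_x,pool_y,diag_x,diag_ratings as in [search_depth()].
#' @param n_instances instances (default 30).
#' @param seed master seed; instance i uses `derive_seed(seed, i)`.
#' @param max_epochs per-instance training epochs.
#' @return list with `objectives`, `mean`, `sd`, `max`.
#' @export
validate_instances <- function(best_spec, pool_x, pool_y, diag_x,
                               diag_ratings, n_instances = 30L, seed = 1L,
                               max_epochs = 4L) {
  obj <- vapply(seq_len(n_instances), function(i) {
    evaluate_spec(best_spec, pool_x, pool_y, diag_x, diag_ratings,
                  seed = derive_seed(seed, i),
                  max_epochs = max_epochs)$objective
  }, numeric(1))
  list(objectives = obj, mean = mean(obj),
       sd = if (n_instances > 1L) stats::sd(obj) else 0, max = max(obj))
}

#' Depth sweep with equal search budget per depth
#'
#' @param depths depths to search (default 1..12).
#' @param ... arguments passed to [search_depth()] (pool, diagnostic set,
#'   `n_iter`, `strategy`, `max_epochs`).
#' @param seed master seed; depth d uses an independent derived seed, so
#'   per-depth results do not depend on sweep order.
#' @return list with `table` (depth, best_objective, best_accuracy) and
#'   `argmax_depth`.
#' @export
depth_sweep <- function(depths = 1:12, ..., seed = 1L) {
  rows <- lapply(depths, function(d) {
    r <- search_depth(depth = d, ..., seed = derive_seed(seed, 1000L + d))
    data.frame(depth = d, best_objective = r$best$objective,
               best_accuracy = r$best$accuracy %||% NA_real_)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, argmax_depth = tab$depth[which.max(tab$best_objective)])
}
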