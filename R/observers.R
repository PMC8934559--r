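# Simulated observers.
#
# The observer model is a latent-evidence model: an observer perceives
# a + eps with eps ~ Normal(0, sigma_obs), bins the percept into fifths of
# [0,1] for the 5-point rating task, thresholds it at 0.5 for binary or
# three-way judgments, and with probability `lapse` responds uniformly at
# random.  With sigma_obs = 0 and lapse = 0 every observer produces the same
# deterministic response to a given image, which is what makes the 10/10
# consistency criterion of the diagnostic pipeline attainable by
# construction.

#' Observer profile
#'
#' @param observer_id identifier.
#' @param rating_noise_sd standard deviation of additive latent noise
#'   (`sigma_obs`), `>= 0`.
#' @param lapse_rate probability of a uniform random response.
#' @param p_hard probability of the "hard to recognize" response in the
#'   three-way task.
#' @param p_recog_slope sensitivity of the recognizability response (kept for
#'   forward compatibility; the recognizability task uses a planted
#'   per-image probability).
#' @return an `observer_profile` object.
#' @export
observer_profile <- function(observer_id = "obs1", rating_noise_sd = 0.05,
                             lapse_rate = 0, p_hard = 0, p_recog_slope = 1) {
  stopifnot(rating_noise_sd >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            p_hard >= 0, p_hard <= 1)
  structure(list(observer_id = as.character(observer_id),
                 rating_noise_sd = rating_noise_sd, lapse_rate = lapse_rate,
                 p_hard = p_hard, p_recog_slope = p_recog_slope),
            class = "observer_profile")
}

# Bin a latent percept into a 1..5 rating: k with percept in [(k-1)/5, k/5),
# last bin upper-inclusive; out-of-range percepts clip to the end bins.
percept_to_rating <- function(percept) {
  k <- floor(percept * 5) + 1
  pmin(pmax(k, 1), 5)
}

#' Simulate a 5-point rating
#'
#' With probability `lapse_rate` the rating is uniform on 1..5; otherwise the
#' latent percept `a + eps` is binned into fifths of `[0,1]` (last bin
#' upper-inclusive).
#'
#' @param a appearance in `[0,1]`.
#' @param obs an [observer_profile()].
#' @param seed integer seed.
#' @return integer rating in 1..5.
#' @export
simulate_rating <- function(a, obs, seed) {
  stopifnot(a >= 0, a <= 1)
  with_rng(seed, {
    if (obs$lapse_rate > 0 && stats::runif(1) < obs$lapse_rate) {
      sample.int(5L, 1L)
    } else {
      eps <- if (obs$rating_noise_sd > 0)
        stats::rnorm(1, 0, obs$rating_noise_sd) else 0
      as.integer(percept_to_rating(a + eps))
    }
  })
}

#' Simulate a three-way judgment (mirror / glass / hard)
#'
#' "hard" with probability `p_hard`; otherwise mirror iff `a + eps >= 0.5`
#' (the 0.5-or-greater-is-mirror rule).
#'
#' @inheritParams simulate_rating
#' @return one of `"mirror"`, `"glass"`, `"hard"`.
#' @export
simulate_threeway <- function(a, obs, seed) {
  stopifnot(a >= 0, a <= 1)
  with_rng(seed, {
    if (obs$p_hard > 0 && stats::runif(1) < obs$p_hard) {
      "hard"
    } else {
      eps <- if (obs$rating_noise_sd > 0)
        stats::rnorm(1, 0, obs$rating_noise_sd) else 0
      if (a + eps >= 0.5) "mirror" else "glass"
    }
  })
}

#' Simulate a binary recognizability vote
#'
#' A Bernoulli draw with the stimulus's planted recognizability probability.
#'
#' @param p_recog planted probability that the object shape and material are
#'   recognizable.
#' @param obs an [observer_profile()] (unused beyond its identity; kept so
#'   the call signature matches the other tasks).
#' @param seed integer seed.
#' @return logical.
#' @export
simulate_recognizability <- function(p_recog, obs, seed) {
  stopifnot(p_recog >= 0, p_recog <= 1)
  with_rng(seed, stats::runif(1) < p_recog)
}

#' Normalize a 1..5 rating to \code{[0,1]}
#'
#' @param rating integer vector of ratings in 1..5.
#' @return `(rating - 1) / 4`.
#' @export
normalize_rating <- function(rating) (rating - 1) / 4

#' Simulate a crowdsourcing session with catch trials
#'
#' Each worker is shown `n_per_worker` images: `n_per_worker - n_catch` test
#' images plus `n_catch` catch images of extreme appearance (a = 0 or a = 1).
#' A catch trial passes iff the binary class of the worker's rating
#' (normalized rating `< 0.5` = glass, `>= 0.5` = mirror) matches the catch
#' ground truth; a worker failing any catch is flagged rejected and their
#' test ratings are marked excluded.
#'
#' Test images are assigned in balanced passes: the image list is shuffled
#' once per pass and sliced into consecutive blocks, so with
#' `n_workers * (n_per_worker - n_catch)` a multiple of `nrow(manifest)`
#' every image receives the same number of ratings.
#'
#' @param manifest stimulus manifest (columns `image_id`, `class_label`, `a`).
#' @param workers list of [observer_profile()].
#' @param n_per_worker trials per worker (default 100).
#' @param n_catch number of catch trials per worker (default 2; one glass,
#'   one mirror, alternating).
#' @param seed integer master seed.
#' @return list with `responses` (data frame: image_id, observer_id, task,
#'   value, trial_index, is_catch, excluded) and `workers` (data frame:
#'   observer_id, accepted).
#' @export
simulate_crowd_session <- function(manifest, workers, n_per_worker = 100L,
                                   n_catch = 2L, seed = 1L) {
  n_test <- n_per_worker - n_catch
  n_img <- nrow(manifest)
  if (n_img < n_test) {
    stop("fewer images (", n_img, ") than test trials per worker (", n_test, ")")
  }
  n_workers <- length(workers)
  # balanced assignment: consecutive blocks of per-pass shuffles
  total <- n_workers * n_test
  n_pass <- ceiling(total / n_img)
  order_all <- unlist(lapply(seq_len(n_pass), function(p)
    with_rng(derive_seed(seed, 7000L + p), sample.int(n_img))))
  resp <- vector("list", n_workers)
  status <- data.frame(observer_id = character(n_workers),
                       accepted = logical(n_workers),
                       stringsAsFactors = FALSE)
  catch_a <- rep(c(0, 1), length.out = n_catch)
  for (w in seq_len(n_workers)) {
    obs <- workers[[w]]
    block <- order_all[((w - 1) * n_test + 1):(w * n_test)]
    test_ids <- manifest$image_id[block]
    test_a <- manifest$a[block]
    ratings <- vapply(seq_len(n_test), function(i)
      simulate_rating(test_a[i], obs, derive_seed(seed, w * 100000L + i)),
      integer(1))
    catch_ratings <- vapply(seq_len(n_catch), function(i)
      simulate_rating(catch_a[i], obs, derive_seed(seed, w * 100000L + n_test + i)),
      integer(1))
    catch_pass <- (normalize_rating(catch_ratings) >= 0.5) == (catch_a >= 0.5)
    accepted <- all(catch_pass)
    status$observer_id[w] <- obs$observer_id
    status$accepted[w] <- accepted
    resp[[w]] <- data.frame(
      image_id = c(test_ids, sprintf("catch_%d", seq_len(n_catch))),
      observer_id = obs$observer_id,
      task = "rating5",
      value = c(ratings, catch_ratings),
      trial_index = seq_len(n_per_worker),
      is_catch = c(rep(FALSE, n_test), rep(TRUE, n_catch)),
      excluded = !accepted,
      stringsAsFactors = FALSE)
  }
  list(responses = do.call(rbind, resp), workers = status)
}

#' Summarize ratings per image
#'
#' Normalizes ratings to `[0,1]`, averages per image, assigns the fifths bin
#' of the mean, and flags consistency (all contributing observers in the same
#' bin; requires at least 2 ratings).
#'
#' @param responses data frame with columns `image_id`, `value` (ratings
#'   1..5) and optionally `excluded`/`is_catch` (excluded and catch rows are
#'   dropped).
#' @return data frame: image_id, n_ratings, mean_norm_rating, bin, consistent.
#' @export
summarize_ratings <- function(responses) {
  r <- responses
  if (!is.null(r$is_catch)) r <- r[!r$is_catch, , drop = FALSE]
  if (!is.null(r$excluded)) r <- r[!r$excluded, , drop = FALSE]
  sp <- split(normalize_rating(r$value), r$image_id)
  out <- data.frame(
    image_id = names(sp),
    n_ratings = vapply(sp, length, integer(1)),
    mean_norm_rating = vapply(sp, mean, numeric(1)),
    stringsAsFactors = FALSE)
  out$bin <- bin_of(out$mean_norm_rating)
  out$consistent <- vapply(sp, function(v)
    length(v) >= 2L && length(unique(bin_of(v))) == 1L, logical(1))
  rownames(out) <- NULL
  out
}
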