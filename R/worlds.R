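# Planted simulation scenarios ("worlds").
#
# Each selection round is exercised on a simulated response table whose
# planted composition mirrors the published quotas: candidate pools are
# generous enough to fill every sampling cell, conflict and recognizability
# rates are planted exactly, and the laboratory observers are noiseless
# (sigma_obs = 0, lapse = 0), which is the regime in which the 10-of-10
# consistency criterion is attainable.  Appearance values are drawn from
# bin interiors (away from bin boundaries) so that the noiseless responses
# are unambiguous.

# n appearance values uniform in the interior of rating bin `bin`
a_in_bin <- function(n, bin, seed, margin = 0.03) {
  lo <- (bin - 1) / 5 + margin
  hi <- bin / 5 - margin
  with_rng(seed, stats::runif(n, lo, hi))
}

#' Panel of identically parameterized laboratory observers
#'
#' @param n number of observers.
#' @param sigma,lapse,p_hard shared [observer_profile()] parameters.
#' @return list of observer profiles.
#' @export
lab_panel <- function(n = 10L, sigma = 0, lapse = 0, p_hard = 0) {
  lapply(seq_len(n), function(i)
    observer_profile(sprintf("lab%02d", i), rating_noise_sd = sigma,
                     lapse_rate = lapse, p_hard = p_hard))
}

#' Rate every image with every observer
#'
#' @param manifest stimulus manifest (`image_id`, `a`).
#' @param observers list of [observer_profile()].
#' @param seed master seed.
#' @param n_trials ratings per observer per image.
#' @return response table (`image_id`, `observer_id`, `task`, `value`,
#'   `trial_index`).
#' @export
rate_all <- function(manifest, observers, seed, n_trials = 1L) {
  rows <- list()
  k <- 0L
  for (tr in seq_len(n_trials)) for (o in seq_along(observers)) {
    k <- k + 1L
    ratings <- vapply(seq_len(nrow(manifest)), function(i)
      simulate_rating(manifest$a[i], observers[[o]],
                      derive_seed(seed, k * 1000000L + i)), integer(1))
    rows[[k]] <- data.frame(image_id = manifest$image_id,
                            observer_id = observers[[o]]$observer_id,
                            task = "rating5", value = ratings,
                            trial_index = tr, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' World for round A1: three-way screening of a large rendering pool
#'
#' Plants `n_per_cell` images in each of the four cells of true class x
#' appearance class, simulates one three-way judgment per image with the
#' configured "hard to recognize" rate, and runs the round-A1 quota
#' selection.
#'
#' @param seed master seed.
#' @param n_per_cell planted pool size per cell (default 3000).
#' @param quota per-cell sampling quota (default 2744).
#' @param p_hard probability of a "hard" judgment (default 0.029).
#' @return list with `selected` ids, `manifest` and the `threeway` table.
#' @export
world_round_a1 <- function(seed = 1L, n_per_cell = 3000L, quota = 2744L,
                           p_hard = 0.029) {
  mk <- function(label, bins, conflict, tag, s) {
    n <- n_per_cell
    a <- a_in_bin(n, sample(bins, n, replace = TRUE) , derive_seed(seed, s))
    data.frame(image_id = sprintf("a1_%s_%05d", tag, seq_len(n)),
               class_label = label, a = a, conflict = conflict,
               stringsAsFactors = FALSE)
  }
  manifest <- with_rng(derive_seed(seed, 1L), rbind(
    mk("mirror", 4:5, FALSE, "mm", 11L),
    mk("mirror", 1:2, TRUE, "mg", 12L),
    mk("glass", 1:2, FALSE, "gg", 13L),
    mk("glass", 4:5, TRUE, "gm", 14L)))
  obs <- observer_profile("a1_obs", rating_noise_sd = 0, lapse_rate = 0,
                          p_hard = p_hard)
  judgment <- vapply(seq_len(nrow(manifest)), function(i)
    simulate_threeway(manifest$a[i], obs, derive_seed(seed, 200000L + i)),
    character(1))
  threeway <- data.frame(image_id = manifest$image_id,
                         class_label = manifest$class_label,
                         judgment = judgment, stringsAsFactors = FALSE)
  selected <- round_a1_select(threeway, quota, seed = derive_seed(seed, 3L))
  list(selected = selected, manifest = manifest, threeway = threeway)
}

#' World for round A2: crowdsourced rating of A1 survivors
#'
#' Plants a pool in which exactly `n_conflict` mirror images look glass-like
#' (appearance in bins 1-2) and `n_conflict` glass images look mirror-like
#' (bins 4-5); the remainder are veridical.  Noiseless crowd-workers rate
#' the pool in balanced passes so every image receives `n_passes` accepted
#' ratings.
#'
#' @param seed master seed.
#' @param n_conflict planted conflicts per class (default 261).
#' @param n_filler_per_class veridical images per class (default 719,
#'   giving a pool of 1,960 = 20 workers' worth per pass).
#' @param n_passes rating passes (default 3, the minimum analyzable count).
#' @return list with the round-A2 selection (`mirror_conflicts`,
#'   `glass_conflicts`, `selected`, `summaries`), `manifest`, `responses`
#'   and `workers`.
#' @export
world_round_a2 <- function(seed = 1L, n_conflict = 261L,
                           n_filler_per_class = 719L, n_passes = 3L) {
  mk <- function(label, bins, conflict, tag, n, s) {
    a <- a_in_bin(n, with_rng(derive_seed(seed, s + 50L),
                              sample(bins, n, replace = TRUE)),
                  derive_seed(seed, s))
    data.frame(image_id = sprintf("a2_%s_%05d", tag, seq_len(n)),
               class_label = label, a = a, conflict = conflict,
               stringsAsFactors = FALSE)
  }
  manifest <- rbind(
    mk("mirror", 1:2, TRUE, "conf_m", n_conflict, 21L),
    mk("glass", 4:5, TRUE, "conf_g", n_conflict, 22L),
    mk("mirror", 4:5, FALSE, "ver_m", n_filler_per_class, 23L),
    mk("glass", 1:2, FALSE, "ver_g", n_filler_per_class, 24L))
  n_img <- nrow(manifest)
  n_test <- 98L
  workers_per_pass <- n_img %/% n_test
  if (n_img %% n_test != 0) {
    stop("world_round_a2: pool size must be a multiple of 98")
  }
  workers <- lapply(seq_len(workers_per_pass * n_passes), function(i)
    observer_profile(sprintf("crowd%03d", i), rating_noise_sd = 0,
                     lapse_rate = 0))
  sess <- simulate_crowd_session(manifest, workers, n_per_worker = 100L,
                                 n_catch = 2L, seed = derive_seed(seed, 31L))
  sel <- round_a2_select(sess$responses, manifest, min_ratings = 3L)
  c(sel, list(manifest = manifest, responses = sess$responses,
              workers = sess$workers))
}

#' World for round A3: laboratory re-rating of A2 conflicts
#'
#' Plants 522 candidates of which exactly `n_keep` mirror images are rated
#' in bins 1-3 (seen as glass or ambiguous) and `n_keep` glass images in
#' bins 3-5, split evenly over those bins so the downstream assembly is
#' flat; the remaining candidates revert to veridical appearance under
#' laboratory viewing.  Ten noiseless observers rate each image three times.
#'
#' @param seed master seed.
#' @param n_keep retained illusory images per class (default 51; must be a
#'   multiple of 3 for even bin allocation).
#' @param n_revert candidates per class whose laboratory rating agrees with
#'   ground truth (default 210).
#' @param sigma laboratory observer rating noise (default 0).
#' @return list with `selected`, `summaries`, `manifest`, `ratings`.
#' @export
world_round_a3 <- function(seed = 1L, n_keep = 51L, n_revert = 210L,
                           sigma = 0) {
  stopifnot(n_keep %% 3 == 0)
  per_bin <- n_keep %/% 3L
  mk <- function(label, bins, tag, s) {
    bins_vec <- rep(bins, each = per_bin)
    a <- a_in_bin(length(bins_vec), bins_vec, derive_seed(seed, s))
    data.frame(image_id = sprintf("a3_%s_%05d", tag, seq_along(bins_vec)),
               class_label = label, a = a,
               conflict = TRUE, stringsAsFactors = FALSE)
  }
  mkrev <- function(label, bins, tag, s) {
    b <- with_rng(derive_seed(seed, s + 5L),
                  sample(bins, n_revert, replace = TRUE))
    a <- a_in_bin(n_revert, b, derive_seed(seed, s))
    data.frame(image_id = sprintf("a3_%s_%05d", tag, seq_len(n_revert)),
               class_label = label, a = a, conflict = FALSE,
               stringsAsFactors = FALSE)
  }
  manifest <- rbind(
    mk("mirror", 1:3, "ill_m", 41L),
    mk("glass", 3:5, "ill_g", 42L),
    mkrev("mirror", 4:5, "rev_m", 43L),
    mkrev("glass", 1:2, "rev_g", 44L))
  ratings <- rate_all(manifest, lab_panel(10L, sigma = sigma),
                      derive_seed(seed, 45L), n_trials = 3L)
  sel <- round_a3_select(ratings, manifest)
  c(sel, list(manifest = manifest, ratings = ratings))
}

#' World for rounds B1-B2: generative-model (ambiguous) images
#'
#' Plants `n_pool` ambiguous images of which `n_recog` are recognizable
#' (planted recognizability probability 1, the rest 0) with appearance
#' spread evenly over all five bins; 10 observers vote on recognizability,
#' then rate the B1 survivors three times each.
#'
#' @param seed master seed.
#' @param n_pool pool size (default 1400).
#' @param n_recog recognizable images (default 500; multiple of 5).
#' @param per_bin_quota round-B2 quota per bin (default 19).
#' @return list with `b1_selected`, `b2_selected`, `summaries`, `manifest`,
#'   `recog_table`, `ratings`.
#' @export
world_round_b <- function(seed = 1L, n_pool = 1400L, n_recog = 500L,
                          per_bin_quota = 19L) {
  stopifnot(n_recog %% 5 == 0, n_recog <= n_pool)
  bins_vec <- rep(1:5, each = n_recog %/% 5L)
  cls <- rep(c("amb_mirror", "amb_glass"), length.out = n_pool)
  a <- c(a_in_bin(n_recog, bins_vec, derive_seed(seed, 51L)),
         with_rng(derive_seed(seed, 52L),
                  stats::runif(n_pool - n_recog, 0.3, 0.7)))
  manifest <- data.frame(
    image_id = sprintf("gan_%05d", seq_len(n_pool)),
    class_label = cls, a = a, conflict = FALSE,
    p_recog = c(rep(1, n_recog), rep(0, n_pool - n_recog)),
    stringsAsFactors = FALSE)
  panel <- lab_panel(10L)
  recog_rows <- lapply(seq_along(panel), function(o) {
    votes <- vapply(seq_len(n_pool), function(i)
      simulate_recognizability(manifest$p_recog[i], panel[[o]],
                               derive_seed(seed, o * 100000L + i)),
      logical(1))
    data.frame(image_id = manifest$image_id,
               observer_id = panel[[o]]$observer_id, vote = votes,
               stringsAsFactors = FALSE)
  })
  recog_table <- do.call(rbind, recog_rows)
  b1 <- round_b1_select(recog_table, min_votes = 6L, n_observers = 10L)
  kept <- manifest[manifest$image_id %in% b1, , drop = FALSE]
  ratings <- rate_all(kept, panel, derive_seed(seed, 53L), n_trials = 3L)
  b2 <- round_b2_select(ratings, per_bin_quota,
                        seed = derive_seed(seed, 54L))
  list(b1_selected = b1, b2_selected = b2,
       summaries = summarize_ratings(ratings),
       manifest = manifest, recog_table = recog_table, ratings = ratings)
}

#' Veridical component: consistent, correctly judged renderings
#'
#' Simulates an Experiment-1-style rating study and selects, per class and
#' bin cell, images whose 10 observers all agree on the bin and whose bin
#' matches the ground-truth class (mirror in bins 4-5, glass in bins 1-2).
#'
#' @param seed master seed.
#' @param per_cell images per (class, bin) cell (default 17, giving 68).
#' @param n_extra_per_class additional pool images per class so the cells
#'   are over-full (default 50).
#' @param sigma observer rating noise (default 0).
#' @return list with `selected`, `summaries`, `manifest`, `ratings`.
#' @export
world_veridical <- function(seed = 1L, per_cell = 17L,
                            n_extra_per_class = 50L, sigma = 0) {
  mk <- function(label, bins, tag, n, s) {
    b <- with_rng(derive_seed(seed, s + 5L), sample(bins, n, replace = TRUE))
    data.frame(image_id = sprintf("ver_%s_%05d", tag, seq_len(n)),
               class_label = label, a = a_in_bin(n, b, derive_seed(seed, s)),
               conflict = FALSE, stringsAsFactors = FALSE)
  }
  n_per_class <- 2L * per_cell + n_extra_per_class
  manifest <- rbind(mk("mirror", 4:5, "m", n_per_class, 61L),
                    mk("glass", 1:2, "g", n_per_class, 62L))
  ratings <- rate_all(manifest, lab_panel(10L, sigma = sigma),
                      derive_seed(seed, 63L), n_trials = 1L)
  s <- summarize_ratings(ratings)
  cons <- consistency_filter(
    data.frame(image_id = ratings$image_id,
               bin = bin_of(normalize_rating(ratings$value))), 10L)
  s$consistent10 <- unname(cons[s$image_id])
  cls <- manifest$class_label[match(s$image_id, manifest$image_id)]
  eligible <- s$consistent10 &
    ((cls == "mirror" & s$bin %in% 4:5) | (cls == "glass" & s$bin %in% 1:2))
  sel <- character(0)
  for (cl in c("mirror", "glass")) {
    bins <- if (cl == "mirror") 4:5 else 1:2
    for (b in bins) {
      ids <- s$image_id[eligible & cls == cl & s$bin == b]
      if (length(ids) < per_cell) {
        stop("veridical cell ", cl, "/bin ", b, " underfull (",
             length(ids), " < ", per_cell, ")")
      }
      sel <- c(sel, with_rng(derive_seed(seed, 70L + b + 10L * (cl == "glass")),
                             sample(ids, per_cell)))
    }
  }
  list(selected = sel, summaries = s, manifest = manifest, ratings = ratings)
}

#' End-to-end diagnostic-set construction on planted worlds
#'
#' Runs the veridical selection, the A-track illusory confirmation and the
#' B-track ambiguous screening on planted simulated responses, balances the
#' illusory component to `per_cell` per (class, bin) cell, and assembles the
#' certified diagnostic set.
#'
#' @param seed master seed.
#' @param per_cell rendering images per (class, bin) cell (default 17).
#' @param per_bin_ambiguous ambiguous images per bin (default 19).
#' @param sigma laboratory observer noise for the veridical/illusory
#'   ratings (default 0).
#' @return list with the `diagnostic_set` plus the component worlds.
#' @export
build_diagnostic_world <- function(seed = 1L, per_cell = 17L,
                                   per_bin_ambiguous = 19L, sigma = 0) {
  # with noisy observers the candidate pools are planted over-full so every
  # measured (class, bin) cell still covers its quota
  overfill <- if (sigma > 0) 3L else 1L
  ver <- world_veridical(derive_seed(seed, 81L), per_cell = per_cell,
                         n_extra_per_class = if (sigma > 0) 300L else 50L,
                         sigma = sigma)
  a3 <- world_round_a3(derive_seed(seed, 82L),
                       n_keep = 3L * per_cell * overfill,
                       n_revert = 210L, sigma = sigma)
  bb <- world_round_b(derive_seed(seed, 83L),
                      per_bin_quota = per_bin_ambiguous)
  # balance the illusory component: per_cell per (class, bin) cell
  s3 <- a3$summaries
  cls3 <- a3$manifest$class_label[match(s3$image_id, a3$manifest$image_id)]
  ill <- character(0)
  for (cl in c("mirror", "glass")) {
    bins <- if (cl == "mirror") 1:3 else 3:5
    for (b in bins) {
      ids <- intersect(s3$image_id[cls3 == cl & s3$bin == b], a3$selected)
      if (length(ids) < per_cell) {
        stop("illusory cell ", cl, "/bin ", b, " underfull (",
             length(ids), " < ", per_cell, ")")
      }
      ill <- c(ill, with_rng(derive_seed(seed, 90L + b + 10L * (cl == "glass")),
                             sample(ids, per_cell)))
    }
  }
  summaries <- rbind(
    ver$summaries[, c("image_id", "n_ratings", "mean_norm_rating", "bin",
                      "consistent")],
    s3[, c("image_id", "n_ratings", "mean_norm_rating", "bin", "consistent")],
    bb$summaries[, c("image_id", "n_ratings", "mean_norm_rating", "bin",
                     "consistent")])
  manifest <- rbind(ver$manifest[, c("image_id", "class_label", "a", "conflict")],
                    a3$manifest[, c("image_id", "class_label", "a", "conflict")],
                    bb$manifest[, c("image_id", "class_label", "a", "conflict")])
  set <- assemble_diagnostic(ver$selected, ill, bb$b2_selected,
                             summaries, manifest)
  list(set = set, veridical = ver, a3 = a3, b = bb, manifest = manifest,
       summaries = summaries)
}
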