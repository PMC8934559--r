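# Multi-round construction of the diagnostic image set: exclusion of
# hard-to-recognize images, quota sampling, conflict selection,
# recognizability screening, consistency filtering, and final assembly with
# flatness and decorrelation certificates.
#
# Interval conventions (committed once, used everywhere): ratings are
# normalized to [0,1]; bins are fifths [(k-1)/5, k/5), half-open with the
# last bin upper-inclusive.  Printed ranges like "0.0-0.4" are read as
# [0, 0.4) and "0.6-1.0" as [0.6, 1.0].

#' Fifths bin of a normalized rating
#'
#' @param value numeric in `[0,1]`.
#' @return integer 1..5; `value` in `[(k-1)/5, k/5)`, with 1.0 -> 5.
#' @export
bin_of <- function(value) {
  if (any(value < 0 | value > 1)) stop("normalized ratings must be in [0,1]")
  pmin(as.integer(floor(value * 5)) + 1L, 5L)
}

#' Round A1: exclusion of hard images and per-cell quota sampling
#'
#' Images whose majority three-way judgment is "hard" are excluded; the
#' remaining images are grouped into the 4 cells of true class x majority
#' judged class, and `quota_per_bin` images are sampled uniformly without
#' replacement from each cell.
#'
#' @param threeway_table data frame with columns `image_id`, `class_label`
#'   (true class) and `judgment` (`"mirror"`/`"glass"`/`"hard"`, possibly
#'   several rows per image).
#' @param quota_per_bin images to sample from each of the 4 cells.
#' @param seed sampling seed.
#' @return character vector of selected image ids (length `4 * quota`).
#' @export
round_a1_select <- function(threeway_table, quota_per_bin, seed = 1L) {
  if (quota_per_bin == 0L) return(character(0))
  maj <- function(j) {
    tab <- sort(table(j), decreasing = TRUE)
    names(tab)[1]
  }
  sp <- split(threeway_table$judgment, threeway_table$image_id)
  judged <- vapply(sp, maj, character(1))
  truth <- threeway_table$class_label[!duplicated(threeway_table$image_id)]
  names(truth) <- threeway_table$image_id[!duplicated(threeway_table$image_id)]
  truth <- truth[names(judged)]
  keep <- judged != "hard"
  cells <- split(names(judged)[keep],
                 paste(truth[keep], judged[keep], sep = ":"))
  expected <- as.vector(outer(c("mirror", "glass"), c("mirror", "glass"),
                              paste, sep = ":"))
  out <- character(0)
  for (cell in expected) {
    ids <- cells[[cell]] %||% character(0)
    if (length(ids) < quota_per_bin) {
      stop("round A1: cell '", cell, "' holds ", length(ids),
           " images, fewer than the quota ", quota_per_bin)
    }
    out <- c(out, with_rng(derive_seed(seed, match(cell, expected)),
                           sample(ids, quota_per_bin)))
  }
  out
}

#' Round A2: crowdsourced conflict selection
#'
#' Images with fewer than `min_ratings` accepted crowd ratings are dropped;
#' among the rest, mirror images with mean normalized rating in `[0, 0.4)`
#' (seen as glass) and glass images with mean in `[0.6, 1.0]` (seen as
#' mirror) are selected.
#'
#' @param crowd_responses response table from [simulate_crowd_session()]
#'   (rejected workers' rows carry `excluded = TRUE`).
#' @param manifest stimulus manifest with `image_id`, `class_label`.
#' @param min_ratings minimum accepted ratings per image (default 3).
#' @return list with `mirror_conflicts`, `glass_conflicts`, `selected`
#'   (their union) and `summaries` (analyzed-image rating summaries).
#' @export
round_a2_select <- function(crowd_responses, manifest, min_ratings = 3L) {
  s <- summarize_ratings(crowd_responses)
  s <- s[s$n_ratings >= min_ratings, , drop = FALSE]
  cls <- manifest$class_label[match(s$image_id, manifest$image_id)]
  mirror_conflicts <- s$image_id[cls == "mirror" & s$mean_norm_rating < 0.4]
  glass_conflicts <- s$image_id[cls == "glass" & s$mean_norm_rating >= 0.6]
  list(mirror_conflicts = mirror_conflicts, glass_conflicts = glass_conflicts,
       selected = c(mirror_conflicts, glass_conflicts), summaries = s)
}

#' Round A3: laboratory confirmation of illusory images
#'
#' Mirror images with mean normalized rating in `[0, 0.6)` (seen as glass or
#' ambiguous) and glass images with mean in `[0.4, 1.0]` are selected.
#'
#' @param lab_ratings response table (3 trials x 10 observers per image).
#' @param manifest manifest with true classes.
#' @return list with `selected` ids and `summaries`.
#' @export
round_a3_select <- function(lab_ratings, manifest) {
  s <- summarize_ratings(lab_ratings)
  cls <- manifest$class_label[match(s$image_id, manifest$image_id)]
  sel <- s$image_id[(cls == "mirror" & s$mean_norm_rating < 0.6) |
                      (cls == "glass" & s$mean_norm_rating >= 0.4)]
  list(selected = sel, summaries = s)
}

#' Round B1: recognizability screening
#'
#' @param recog_table data frame `image_id`, `vote` (logical), exactly
#'   `n_observers` rows per image.
#' @param min_votes keep iff yes-votes `>= min_votes` (default 6).
#' @param n_observers required votes per image (default 10).
#' @return character vector of retained image ids.
#' @export
round_b1_select <- function(recog_table, min_votes = 6L, n_observers = 10L) {
  sp <- split(recog_table$vote, recog_table$image_id)
  nv <- vapply(sp, length, integer(1))
  if (any(nv != n_observers)) {
    stop("round B1: every image needs exactly ", n_observers, " votes")
  }
  yes <- vapply(sp, sum, numeric(1))
  names(yes)[yes >= min_votes]
}

#' Round B2: per-bin quota sampling of consistent images
#'
#' Among images passing the consistency criterion, sample `per_bin_quota`
#' uniformly from each of the 5 bins.
#'
#' @param ratings response table (3 trials x 10 observers per image).
#' @param per_bin_quota images per bin (default 19).
#' @param seed sampling seed.
#' @return character vector of `5 * per_bin_quota` image ids.
#' @export
round_b2_select <- function(ratings, per_bin_quota = 19L, seed = 1L) {
  if (per_bin_quota == 0L) return(character(0))
  s <- summarize_ratings(ratings)
  s <- s[s$consistent, , drop = FALSE]
  out <- character(0)
  for (b in 1:5) {
    ids <- s$image_id[s$bin == b]
    if (length(ids) < per_bin_quota) {
      stop("round B2: bin ", b, " holds ", length(ids),
           " consistent images, fewer than the quota ", per_bin_quota)
    }
    out <- c(out, with_rng(derive_seed(seed, b), sample(ids, per_bin_quota)))
  }
  out
}

#' Consistency criterion: all observers in the same bin
#'
#' @param per_observer_bins data frame `image_id`, `bin` with exactly
#'   `n_required` rows per image (one bin per observer).
#' @param n_required required observer count (default 10).
#' @return named logical vector per image.
#' @export
consistency_filter <- function(per_observer_bins, n_required = 10L) {
  sp <- split(per_observer_bins$bin, per_observer_bins$image_id)
  bad <- vapply(sp, length, integer(1)) != n_required
  if (any(bad)) {
    stop("consistency_filter: every image needs exactly ", n_required,
         " observer bins")
  }
  vapply(sp, function(b) length(unique(b)) == 1L, logical(1))
}

#' Assemble and certify the diagnostic image set
#'
#' Combines veridical, illusory and ambiguous components, computes per-class
#' per-bin counts for the rendering components (veridical + illusory),
#' asserts flatness (equal bin counts within each rendering class) and
#' reports the decorrelation certificate: the Pearson correlation between the
#' binary true class and the mean normalized rating over renderings only.
#'
#' @param veridical_ids,illusory_ids,ambiguous_ids disjoint id vectors.
#' @param summaries rating summaries covering all members (`image_id`,
#'   `mean_norm_rating`, `bin`).
#' @param manifest manifest with true classes.
#' @return a `diagnostic_set`: list with `members` (data frame image_id,
#'   component, true_class, bin, mean_norm_rating), `bin_counts` (class x bin
#'   for renderings), `decorrelation_r`, `n_total`, `n_renderings`.
#' @export
assemble_diagnostic <- function(veridical_ids, illusory_ids, ambiguous_ids,
                                summaries, manifest) {
  ids <- c(veridical_ids, illusory_ids, ambiguous_ids)
  if (anyDuplicated(ids)) stop("component lists must be disjoint")
  comp <- c(rep("veridical", length(veridical_ids)),
            rep("illusory", length(illusory_ids)),
            rep("ambiguous", length(ambiguous_ids)))
  m <- match(ids, summaries$image_id)
  if (anyNA(m)) stop("summaries missing for some members")
  members <- data.frame(
    image_id = ids, component = comp,
    true_class = manifest$class_label[match(ids, manifest$image_id)],
    bin = summaries$bin[m],
    mean_norm_rating = summaries$mean_norm_rating[m],
    stringsAsFactors = FALSE)
  rend <- members[members$component != "ambiguous", , drop = FALSE]
  bin_counts <- table(factor(rend$true_class, c("mirror", "glass")),
                      factor(rend$bin, 1:5))
  if (any(apply(bin_counts, 1, function(r) length(unique(r)) != 1L))) {
    stop("flatness violation in rendering bins:\n",
         paste(utils::capture.output(print(bin_counts)), collapse = "\n"))
  }
  truth01 <- as_binary_label(rend$true_class)
  decorrelation_r <- suppressWarnings(
    stats::cor(truth01, rend$mean_norm_rating))
  if (is.na(decorrelation_r)) decorrelation_r <- 0
  structure(list(members = members, bin_counts = bin_counts,
                 decorrelation_r = decorrelation_r,
                 n_total = nrow(members), n_renderings = nrow(rend)),
            class = "diagnostic_set")
}
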