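# Two-stage representational similarity analysis.
#
# First stage: an image-by-image representational dissimilarity matrix
# (RDM) from scalar prediction scores (absolute score differences) or, for
# network layers, Euclidean distances between flattened activation vectors.
# Second stage: the classifier dissimilarity matrix (CDM), one minus the
# Pearson correlation between the upper triangles of two first-stage RDMs.

#' First-stage RDM from scalar scores
#'
#' @param scores per-image numeric vector (named or with `ids`).
#' @param ids image ordering (defaults to names).
#' @param source label for the source (classifier name, "human", ...).
#' @return an `rdm`: symmetric matrix `|s_i - s_j|` with zero diagonal.
#' @export
build_rdm <- function(scores, ids = names(scores), source = "scores") {
  n <- length(scores)
  if (n < 2L) stop("an RDM needs at least 2 images")
  ids <- ids %||% as.character(seq_len(n))
  m <- abs(outer(as.numeric(scores), as.numeric(scores), `-`))
  dimnames(m) <- list(ids, ids)
  structure(list(mat = m, source = source, ids = ids), class = "rdm")
}

#' First-stage RDM from activation vectors
#'
#' @param act matrix (rows = images) or array whose 4th dimension indexes
#'   images; flattened rows are compared with Euclidean distance.
#' @inheritParams build_rdm
#' @return an `rdm`.
#' @export
build_rdm_activations <- function(act, ids = NULL, source = "layer") {
  if (!is.null(dim(act)) && length(dim(act)) == 4L) {
    n <- dim(act)[4]
    act <- t(matrix(act, ncol = n))
  }
  act <- as.matrix(act)
  m <- as.matrix(stats::dist(act))
  ids <- ids %||% rownames(act) %||% as.character(seq_len(nrow(act)))
  dimnames(m) <- list(ids, ids)
  structure(list(mat = m, source = source, ids = ids), class = "rdm")
}

upper_vec <- function(rdm) rdm$mat[upper.tri(rdm$mat)]

#' Second-stage classifier dissimilarity matrix
#'
#' Entry (i, j) is one minus the Pearson correlation between the upper
#' triangles of RDMs i and j, hence in `[0, 2]`.  `n_random_controls`
#' RDMs built from i.i.d. uniform scores are appended for the chance
#' reference.
#'
#' @param rdms named list of `rdm` objects sharing one image ordering.
#' @param n_random_controls number of random control RDMs (default 10).
#' @param seed seed for the controls.
#' @return a `cdm`: list with `mat` and `sources`.
#' @export
build_cdm <- function(rdms, n_random_controls = 10L, seed = 1L) {
  ids <- rdms[[1]]$ids
  for (r in rdms) {
    if (!identical(r$ids, ids)) stop("RDM image orderings differ")
  }
  if (n_random_controls > 0L) {
    n_img <- length(ids)
    for (k in seq_len(n_random_controls)) {
      s <- with_rng(derive_seed(seed, k), stats::runif(n_img))
      rdms[[sprintf("random%02d", k)]] <-
        build_rdm(s, ids = ids, source = sprintf("random%02d", k))
    }
  }
  srcs <- vapply(rdms, function(r) r$source, character(1))
  v <- vapply(rdms, upper_vec, numeric(length(ids) * (length(ids) - 1) / 2))
  m <- 1 - suppressWarnings(stats::cor(v))
  m[is.na(m)] <- 1
  diag(m) <- 0
  dimnames(m) <- list(srcs, srcs)
  structure(list(mat = m, sources = srcs), class = "cdm")
}

#' Classical multidimensional scaling of a CDM
#'
#' Metric MDS via eigendecomposition of the double-centred squared-distance
#' matrix; the explained-variance fraction is the retained share of the
#' positive eigenvalues.
#'
#' @param cdm a `cdm` (or plain symmetric matrix).
#' @param n_dims requested dimensions (default 3; truncated with a message
#'   if fewer positive eigenvalues exist).
#' @return list with `coords` (sources x dims), `explained_var` (cumulative
#'   fraction for the retained dims) and `eig`.
#' @export
mds_embed <- function(cdm, n_dims = 3L) {
  m <- if (inherits(cdm, "cdm")) cdm$mat else as.matrix(cdm)
  mds <- stats::cmdscale(m, k = min(n_dims, nrow(m) - 1L), eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-12]
  k_avail <- ncol(mds$points)
  if (k_avail < n_dims) {
    message("mds_embed: only ", k_avail, " positive dimensions available; ",
            "truncating from ", n_dims)
  }
  k <- min(n_dims, k_avail)
  coords <- mds$points[, seq_len(k), drop = FALSE]
  explained <- sum(pos[seq_len(min(k, length(pos)))]) / sum(pos)
  list(coords = coords, explained_var = explained, eig = mds$eig)
}

#' Leave-one-out noise ceiling of inter-observer correlation
#'
#' For each observer, the Pearson correlation between their ratings and the
#' mean of the remaining observers.
#'
#' @param rating_matrix observers x images numeric matrix.
#' @return list with `per_observer`, `mean`, `min`, `max`.
#' @export
noise_ceiling <- function(rating_matrix) {
  m <- as.matrix(rating_matrix)
  if (nrow(m) < 3L) stop("noise ceiling needs at least 3 observers")
  r <- vapply(seq_len(nrow(m)), function(i)
    pearson_strict(m[i, ], colMeans(m[-i, , drop = FALSE]),
                   what = "observer ratings"), numeric(1))
  list(per_observer = r, mean = mean(r), min = min(r), max = max(r))
}

#' Layer-wise dissimilarity of a CNN to the human RDM
#'
#' Builds a stage RDM from Euclidean distances between flattened
#' activations at each requested stage and reports `1 - r` against the
#' human RDM (computed from mean normalized ratings).
#'
#' @param model a trained `cnn_model`.
#' @param x image batch `(64, 64, 3, n)` in diagnostic order.
#' @param human_ratings per-image mean normalized ratings, same order.
#' @param stages stage names from [cnn_activations()]; default all.
#' @return data frame `stage`, `dissimilarity`.
#' @export
layerwise_dissimilarity <- function(model, x, human_ratings, stages = NULL) {
  acts <- cnn_activations(model, x)
  stages <- stages %||% names(acts)
  missing <- setdiff(stages, names(acts))
  if (length(missing)) stop("unknown stages: ", paste(missing, collapse = ", "))
  hum <- build_rdm(human_ratings, ids = as.character(seq_along(human_ratings)),
                   source = "human")
  hv <- upper_vec(hum)
  d <- vapply(stages, function(st) {
    a <- acts[[st]]
    r <- if (is.null(dim(a)) || length(dim(a)) <= 2L) {
      if (is.null(dim(a))) build_rdm(a, ids = hum$ids, source = st)
      else build_rdm_activations(a, ids = hum$ids, source = st)
    } else build_rdm_activations(a, ids = hum$ids, source = st)
    1 - pearson_strict(upper_vec(r), hv, what = st)
  }, numeric(1))
  data.frame(stage = stages, dissimilarity = unname(d),
             stringsAsFactors = FALSE)
}
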