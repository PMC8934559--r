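# Hand-engineered features: colour-histogram moments, z-scoring, PCA.

#' Colour-histogram features (8 moments)
#'
#' The first four moments (mean, population variance, skewness, excess
#' kurtosis) of the intensity plane followed by the same four moments of the
#' saturation plane.  Intensity is `(R + G + B) / 3`; saturation is the
#' HSV-style `(max - min) / max` with 0 where `max = 0`.  Zero-variance
#' planes yield skewness 0 and kurtosis 0 by convention.
#'
#' @param image a `stimulus_image` or a 64 x 64 x 3 array in `[0,1]`.
#' @return named numeric vector of length 8.
#' @export
colorhist_features <- function(image) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 image array")
  intensity <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  v <- c(moment_stats(as.vector(intensity)), moment_stats(as.vector(sat)))
  names(v) <- c("int_mean", "int_var", "int_skew", "int_kurt",
                "sat_mean", "sat_var", "sat_skew", "sat_kurt")
  v
}

#' Fit a z-score transform (population standard deviation)
#'
#' @param x numeric matrix (rows = images).
#' @return a `feature_transform` with `center` and `scale`; constant columns
#'   get scale 1 so they map to exactly 0.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("z-scoring requires at least 2 rows")
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  constant <- scale <= .Machine$double.eps
  scale[constant] <- 1
  structure(list(kind = "zscore", center = center, scale = scale,
                 constant = constant), class = "feature_transform")
}

#' Apply a fitted z-score transform
#'
#' @param transform result of [zscore_fit()].
#' @param x matrix with the same columns as the fit data.
#' @return standardized matrix; constant columns are all zero.
#' @export
zscore_apply <- function(transform, x) {
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2, transform$center), 2, transform$scale, `/`)
  z[, transform$constant] <- 0
  z
}

#' Fit a PCA reduction retaining a cumulative-variance threshold
#'
#' Retains the smallest number of leading components whose cumulative
#' explained variance reaches `cum_var_threshold`.  The projection is
#' recorded so held-out rows can be mapped with [pca_apply()].
#'
#' @param x numeric matrix (rows = images), typically already z-scored.
#' @param cum_var_threshold in `(0, 1]`.
#' @return list with `scores` (reduced matrix) and `transform` (a
#'   `feature_transform` holding center, rotation, explained-variance
#'   fractions and the retained dimension).
#' @export
pca_reduce <- function(x, cum_var_threshold = 0.99) {
  if (!(cum_var_threshold > 0 && cum_var_threshold <= 1)) {
    stop("cum_var_threshold must be in (0, 1]")
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  cum <- cumsum(frac)
  k <- which(cum >= cum_var_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  transform <- structure(
    list(kind = "pca", center = p$center, rotation = p$rotation[, seq_len(k),
                                                                drop = FALSE],
         explained_var = frac, retained = k,
         cum_var_threshold = cum_var_threshold),
    class = "feature_transform")
  list(scores = p$x[, seq_len(k), drop = FALSE], transform = transform)
}

#' Apply a fitted PCA projection
#'
#' @param transform the `transform` element of [pca_reduce()].
#' @param x matrix (or single row) in the original feature space.
#' @return projected matrix with `retained` columns.
#' @export
pca_apply <- function(transform, x) {
  x <- matrix(as.matrix(x), ncol = length(transform$center))
  sweep(x, 2, transform$center) %*% transform$rotation
}

#' Feature matrix for a list of images
#'
#' @param images list of `stimulus_image`.
#' @param extractor `"colorhist"` or `"texture"`.
#' @param config pyramid configuration for the texture extractor, see
#'   [texture_config()].
#' @return numeric matrix, rows named by image id.
#' @export
feature_matrix <- function(images, extractor = c("colorhist", "texture"),
                           config = texture_config()) {
  extractor <- match.arg(extractor)
  f <- switch(extractor,
    colorhist = lapply(images, colorhist_features),
    texture = lapply(images, texture_features, config = config))
  m <- do.call(rbind, f)
  rownames(m) <- names(images)
  m
}
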