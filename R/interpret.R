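# Interpretability and robustness analyses: class activation maps and the
# vertical-bias profile, noise-robustness curves, and the inversion test.

# bilinear upsampling of a small map to `out` x `out`
bilinear_upsample <- function(m, out = 64L) {
  n <- nrow(m); p <- ncol(m)
  if (n == out && p == out) return(m)
  # map output pixel centres into input coordinates
  grid1 <- function(v, k) {
    lo <- pmin(pmax(floor(v - 0.5) + 1, 1), k)
    hi <- pmin(lo + 1, k)
    w <- pmin(pmax(v - 0.5 - (lo - 1), 0), 1)
    list(lo = lo, hi = hi, w = w)
  }
  gx <- grid1((seq_len(out) - 0.5) * n / out, n)
  gy <- grid1((seq_len(out) - 0.5) * p / out, p)
  a <- m[gx$lo, gy$lo] * outer(1 - gx$w, 1 - gy$w) +
    m[gx$hi, gy$lo] * outer(gx$w, 1 - gy$w) +
    m[gx$lo, gy$hi] * outer(1 - gx$w, gy$w) +
    m[gx$hi, gy$hi] * outer(gx$w, gy$w)
  a
}

#' Class activation map
#'
#' For a network with a global-average-pooling head, the CAM for a class is
#' the weighted sum of the final convolutional feature maps under that
#' class unit's weights, bilinearly upsampled to the input resolution.
#'
#' @param model a trained `cnn_model` built with `gap_head = TRUE`.
#' @param image a single image (64 x 64 x 3 array or `stimulus_image`).
#' @param class `"mirror"` or `"glass"`.
#' @return a 64 x 64 matrix (class `cam`).
#' @export
compute_cam <- function(model, image, class = c("mirror", "glass")) {
  class <- match.arg(class)
  if (!isTRUE(model$spec$gap_head)) {
    stop("unsupported architecture: CAM requires a model built with ",
         "gap_head = TRUE")
  }
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  x <- array(px, dim = c(dim(px), 1L))
  fw <- cnn_forward(model, x)
  fm <- fw$last_conv                          # (H, W, 1, C) internal layout
  w <- model$head$w2[, if (class == "mirror") 2L else 1L]
  d <- dim(fm)
  dim(fm) <- c(d[1] * d[2], d[4])
  cam_small <- matrix(fm %*% w, d[1], d[2])
  structure(bilinear_upsample(cam_small, model$input_size), class = "cam")
}

#' Per-class mean CAMs and their difference
#'
#' With a two-unit softmax head the per-unit CAMs are defined only up to a
#' component shared by both class units (adding any vector to both columns
#' of the head leaves the classifier unchanged), so mean maps built from
#' raw per-unit weights depend on the initialization.  The class means here
#' therefore use the gauge-invariant discriminant weights
#' `w_mirror - w_glass` ("net mirror evidence"): the mirror map averages
#' the discriminant map over mirror images, the glass map over glass
#' images, and the difference is mirror minus glass.  Identical image sets
#' for the two classes give an exactly zero difference.
#'
#' @param model a GAP-head `cnn_model`.
#' @param images named list of `stimulus_image` (classes read from specs)
#'   or a 4-D array with `labels`.
#' @param labels class labels if `images` is a plain array.
#' @return list with `mean_mirror`, `mean_glass`, `difference`
#'   (mirror - glass), each 64 x 64.
#' @export
class_mean_cam_difference <- function(model, images, labels = NULL) {
  if (is.list(images)) {
    if (is.null(labels)) {
      labels <- vapply(images, function(im) im$spec$class_label, character(1))
    }
    pix <- lapply(images, function(im)
      if (inherits(im, "stimulus_image")) im$pixels else im)
  } else {
    pix <- lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  }
  y <- as_binary_label(labels)
  if (!any(y == 1) || !any(y == 0)) stop("need at least 1 image per class")
  # discriminant gauge: mirror-unit minus glass-unit weights
  dmodel <- model
  d <- model$head$w2[, 2] - model$head$w2[, 1]
  dmodel$head$w2 <- cbind(-d, d)
  acc <- function(idx) {
    s <- matrix(0, model$input_size, model$input_size)
    for (i in idx) s <- s + unclass(compute_cam(dmodel, pix[[i]], "mirror"))
    s / length(idx)
  }
  mm <- acc(which(y == 1))
  mg <- acc(which(y == 0))
  list(mean_mirror = mm, mean_glass = mg, difference = mm - mg)
}

#' Vertical profile (row means) of a map
#'
#' @param map a 64 x 64 matrix (CAM, difference map or intensity plane).
#' @return numeric vector of row means, top row first.
#' @export
vertical_profile <- function(map) {
  m <- unclass(map)
  if (is.null(dim(m)) || length(dim(m)) != 2L) stop("expected a 2-D map")
  rowMeans(m)
}

#' Correlation between two vertical profiles
#'
#' @param cam_diff_profile,pixel_diff_profile equal-length numeric vectors.
#' @return Pearson correlation.
#' @export
profile_correlation <- function(cam_diff_profile, pixel_diff_profile) {
  pearson_strict(cam_diff_profile, pixel_diff_profile, what = "profile")
}

#' Mean intensity-plane difference between classes
#'
#' Companion to [class_mean_cam_difference()] on raw pixels: per-class mean
#' intensity images and their difference.
#'
#' @inheritParams class_mean_cam_difference
#' @return list with `mean_mirror`, `mean_glass`, `difference`.
#' @export
class_mean_pixel_difference <- function(images, labels = NULL) {
  if (is.list(images)) {
    if (is.null(labels)) {
      labels <- vapply(images, function(im) im$spec$class_label, character(1))
    }
    pix <- lapply(images, function(im)
      if (inherits(im, "stimulus_image")) im$pixels else im)
  } else {
    pix <- lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  }
  y <- as_binary_label(labels)
  intensity <- lapply(pix, function(p) (p[, , 1] + p[, , 2] + p[, , 3]) / 3)
  avg <- function(idx) Reduce(`+`, intensity[idx]) / length(idx)
  mm <- avg(which(y == 1)); mg <- avg(which(y == 0))
  list(mean_mirror = mm, mean_glass = mg, difference = mm - mg)
}

#' Noise-robustness curve
#'
#' For each sigma, i.i.d. Gaussian noise is added per channel in [0,1]
#' units, pixels are clipped to [0,1], the model scores the perturbed
#' images and the Pearson correlation with the reference (unperturbed)
#' ratings is averaged over `n_reps` noise draws.
#'
#' @param model a trained `cnn_model`.
#' @param x image batch `(64, 64, 3, n)`.
#' @param reference_ratings human ratings of the unperturbed images.
#' @param sigmas noise standard deviations (default log grid 1e-3..1).
#' @param n_reps noise draws per sigma (default 3).
#' @param seed master seed.
#' @return data frame `sigma`, `r` (mean correlation), `mc_sd`.
#' @export
noise_robustness_curve <- function(model, x, reference_ratings,
                                   sigmas = 10^seq(-3, 0, length.out = 9),
                                   n_reps = 3L, seed = 1L) {
  rows <- lapply(seq_along(sigmas), function(si) {
    sg <- sigmas[si]
    rs <- vapply(seq_len(n_reps), function(rep) {
      xn <- if (sg > 0) {
        noise <- with_rng(derive_seed(seed, si * 1000L + rep),
                          array(stats::rnorm(length(x), 0, sg), dim = dim(x)))
        pmin(pmax(x + noise, 0), 1)
      } else x
      s <- predict_cnn(model, xn)
      if (stats::sd(s) == 0) 0 else stats::cor(s, reference_ratings)
    }, numeric(1))
    data.frame(sigma = sg, r = mean(rs),
               mc_sd = if (n_reps > 1L) stats::sd(rs) else 0)
  })
  do.call(rbind, rows)
}

#' Inversion (upside-down) test
#'
#' @param model a trained `cnn_model`.
#' @param x image batch.
#' @param labels true classes.
#' @return list `accuracy_upright`, `accuracy_flipped`, `delta`
#'   (upright - flipped).
#' @export
inversion_test <- function(model, x, labels) {
  up <- accuracy(predict_cnn(model, x), labels)
  fl <- accuracy(predict_cnn(model, flip_vertical(x)), labels)
  list(accuracy_upright = up, accuracy_flipped = fl, delta = up - fl)
}
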