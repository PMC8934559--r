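# Synthetic stimulus generation.
#
# Stimuli are 64 x 64 RGB images in [0,1].  Each image carries a latent
# appearance parameter a in [0,1] (0 = fully glass-like, 1 = fully
# mirror-like) that drives three plantable low-level cues on top of a
# band-pass noise texture:
#   * a vertical luminance gradient (top brighter for mirror-like a),
#   * a contrast multiplier,
#   * a saturation (colourfulness) offset,
# plus a small mean-luminance offset.  These are exactly the class-conditional
# regularities the downstream classifiers and interpretability analyses are
# designed to discover.

IMG_SIZE <- 64L

#' Stimulus specification
#'
#' @param image_id opaque identifier (character scalar).
#' @param class_label one of `"mirror"`, `"glass"`, `"amb_mirror"`,
#'   `"amb_glass"`.
#' @param a latent appearance in `[0,1]`; 0 = fully glass-like, 1 = fully
#'   mirror-like.
#' @param conflict logical; `TRUE` when the ground-truth label and the
#'   appearance cues disagree (an "illusory" stimulus).  Requires
#'   `class_label = "mirror"` with `a < 0.5` or `class_label = "glass"` with
#'   `a >= 0.5`.
#' @param texture_seed integer seed for the carrier noise texture.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(image_id, class_label, a, conflict = FALSE,
                          texture_seed = 1L) {
  class_label <- match.arg(class_label,
                           c("mirror", "glass", "amb_mirror", "amb_glass"))
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 1)
  if (isTRUE(conflict)) {
    ok <- (class_label == "mirror" && a < 0.5) ||
      (class_label == "glass" && a >= 0.5)
    if (!ok) stop("conflict=TRUE requires label and appearance to disagree")
  }
  structure(
    list(image_id = as.character(image_id), class_label = class_label,
         a = as.numeric(a), conflict = isTRUE(conflict),
         texture_seed = as.integer(texture_seed)),
    class = "stimulus_spec"
  )
}

#' Default cue gains of the generator
#'
#' `gradient` scales the vertical luminance ramp, `contrast` the multiplicative
#' texture-contrast cue, `saturation` the red/blue colour offset and `luminance`
#' a global mean-luminance shift.  All four are multiplied by the signed
#' appearance `2a - 1`.
#'
#' @param gradient,contrast,saturation,luminance nonnegative gains.
#' @param texture_amp amplitude (luminance sd) of the band-pass carrier
#'   texture before the contrast cue is applied.
#' @return named list of gains.
#' @export
cue_gains <- function(gradient = 0.12, contrast = 0.5, saturation = 0.2,
                      luminance = 0.05, texture_amp = 0.15) {
  list(gradient = gradient, contrast = contrast,
       saturation = saturation, luminance = luminance,
       texture_amp = texture_amp)
}

# Band-pass filtered Gaussian noise, zero mean, fixed spatial scale.
# Deterministic in `seed`.
bandpass_texture <- function(seed, size = IMG_SIZE) {
  with_rng(seed, {
    z <- matrix(stats::rnorm(size * size), size, size)
    f <- stats::fft(z)
    fx <- c(0:(size / 2), -(size / 2 - 1):-1) / size
    r <- sqrt(outer(fx^2, fx^2, `+`))           # cycles/pixel
    # log-Gaussian annulus centred on 8 cycles/image
    r0 <- 8 / size
    h <- exp(-(log(pmax(r, 1e-8) / r0))^2 / (2 * 0.7^2))
    h[1, 1] <- 0
    t <- Re(stats::fft(f * h, inverse = TRUE)) / (size * size)
    t <- t - mean(t)
    sdt <- stats::sd(as.vector(t))
    if (sdt > 0) t <- t / sdt
    t
  })
}

#' Render a stimulus image from its specification
#'
#' The pixel grid is a deterministic function of the spec and the cue gains:
#' regeneration from an identical spec is bit-identical.  The `conflict` flag
#' never changes the pixels; cues are always driven by the appearance `a`.
#'
#' @param spec a [stimulus_spec()].
#' @param gains cue gains, see [cue_gains()].
#' @return an object of class `stimulus_image`: a list with `spec` and
#'   `pixels`, a 64 x 64 x 3 array in `[0,1]`.
#' @export
generate_stimulus <- function(spec, gains = cue_gains()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  size <- IMG_SIZE
  t <- bandpass_texture(spec$texture_seed, size)
  sgn <- 2 * spec$a - 1
  # antisymmetric vertical ramp: +0.5 at the top row, -0.5 at the bottom,
  # so mirror-like images are brighter in the upper half and glass-like
  # images brighter in the lower half; the separate luminance gain gives
  # mirror-like images a slightly higher mean luminance
  ramp <- seq(0.5, -0.5, length.out = size)
  contrast <- 1 + gains$contrast * sgn
  amp <- gains$texture_amp %||% 0.15
  lum <- 0.5 + gains$luminance * sgn +
    amp * contrast * t +
    gains$gradient * sgn * matrix(ramp, size, size)
  sat <- gains$saturation * sgn
  px <- array(0, dim = c(size, size, 3L))
  px[, , 1] <- lum * (1 + sat)
  px[, , 2] <- lum
  px[, , 3] <- lum * (1 - sat)
  px[px < 0] <- 0
  px[px > 1] <- 1
  structure(list(spec = spec, pixels = px), class = "stimulus_image")
}

#' Class-mix configuration for dataset generation
#'
#' Each class maps to the support of a uniform distribution from which the
#' appearance `a` is drawn.  Defaults: mirror on `[0.6, 1]`, glass on
#' `[0, 0.4]`, ambiguous classes on the mid-range `[0.3, 0.7]` (the stand-in
#' for generative-model images of intermediate appearance).  A per-class
#' `conflict_rate` fraction of mirror/glass images instead draws `a` from the
#' opposite class's support, producing label/appearance conflicts.
#'
#' @param classes character vector of class labels to generate.
#' @param a_range named list mapping class to `c(lo, hi)` for `a`.
#' @param conflict_rate named numeric, fraction of conflicting images per
#'   class (only meaningful for mirror/glass).
#' @return a `class_mix` list.
#' @export
class_mix <- function(classes = c("mirror", "glass"),
                      a_range = list(mirror = c(0.6, 1), glass = c(0, 0.4),
                                     amb_mirror = c(0.3, 0.7),
                                     amb_glass = c(0.3, 0.7)),
                      conflict_rate = c(mirror = 0, glass = 0)) {
  bad <- setdiff(classes, c("mirror", "glass", "amb_mirror", "amb_glass"))
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  if (!all(classes %in% names(a_range))) {
    stop("class_mix: a_range missing for some classes")
  }
  structure(list(classes = classes, a_range = a_range,
                 conflict_rate = conflict_rate), class = "class_mix")
}

#' Generate a balanced stimulus dataset
#'
#' @param n_per_class images per class.
#' @param mix a [class_mix()].
#' @param master_seed integer; all randomness derives from it.
#' @param gains cue gains.
#' @param render if `FALSE`, only the manifest is produced (used by the
#'   response-simulation rounds, which operate on the latent appearance and do
#'   not need pixels).
#' @return list with `manifest` (data frame: image_id, class_label, a,
#'   conflict, texture_seed, master_seed) and `images` (named list of
#'   `stimulus_image`, or `NULL` when `render = FALSE`).
#' @export
generate_dataset <- function(n_per_class, mix = class_mix(),
                             master_seed = 1L, gains = cue_gains(),
                             render = TRUE) {
  stopifnot(n_per_class >= 1)
  rows <- list()
  idx <- 0L
  for (cl in mix$classes) {
    rng <- mix$a_range[[cl]]
    cr <- unname(mix$conflict_rate[cl])
    cr <- if (is.na(cr) || is.null(cr)) 0 else cr
    a <- with_rng(derive_seed(master_seed, idx + 1L),
                  stats::runif(n_per_class, rng[1], rng[2]))
    conflict <- rep(FALSE, n_per_class)
    if (cr > 0 && cl %in% c("mirror", "glass")) {
      n_conf <- round(cr * n_per_class)
      if (n_conf > 0) {
        opp <- mix$a_range[[setdiff(c("mirror", "glass"), cl)]]
        a[seq_len(n_conf)] <- with_rng(
          derive_seed(master_seed, idx + 2L),
          stats::runif(n_conf, opp[1], opp[2]))
        conflict[seq_len(n_conf)] <- TRUE
      }
    }
    rows[[cl]] <- data.frame(
      image_id = sprintf("%s_%05d", cl, seq_len(n_per_class)),
      class_label = cl, a = a, conflict = conflict,
      texture_seed = vapply(seq_len(n_per_class), function(i)
        derive_seed(master_seed, idx * 1000003L + i), integer(1)),
      stringsAsFactors = FALSE)
    idx <- idx + 10L
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest$master_seed <- as.integer(master_seed)
  images <- NULL
  if (render) {
    images <- lapply(seq_len(nrow(manifest)), function(i) {
      sp <- stimulus_spec(manifest$image_id[i], manifest$class_label[i],
                          manifest$a[i], manifest$conflict[i],
                          manifest$texture_seed[i])
      generate_stimulus(sp, gains)
    })
    names(images) <- manifest$image_id
  }
  list(manifest = manifest, images = images)
}

#' Stack a list of stimulus images into a 4-D array
#'
#' @param images list of `stimulus_image`.
#' @return array of dim `c(64, 64, 3, n)`.
#' @export
stack_images <- function(images) {
  n <- length(images)
  x <- array(0, dim = c(IMG_SIZE, IMG_SIZE, 3L, n))
  for (i in seq_len(n)) x[, , , i] <- images[[i]]$pixels
  dimnames(x) <- list(NULL, NULL, NULL, names(images))
  x
}

#' Vertically flip images (the inversion manipulation)
#'
#' @param x a 64 x 64 x 3 array or a 4-D batch array.
#' @return array of the same shape with row order reversed.
#' @export
flip_vertical <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    x[rev(seq_len(d[1])), , , drop = FALSE]
  } else if (length(d) == 4L) {
    x[rev(seq_len(d[1])), , , , drop = FALSE]
  } else stop("expected a 3-D image or 4-D batch array")
}
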