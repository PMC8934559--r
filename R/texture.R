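# Steerable-pyramid texture statistics.
#
# A complex steerable pyramid is built in the frequency domain at full
# resolution (no downsampling), which makes every spatially averaged
# statistic exactly invariant to circular shifts of the input.  From the
# subbands we emit the classic texture-statistic families: pixel marginals,
# central autocorrelations, subband magnitude means and autocorrelations,
# cross-orientation and cross-scale magnitude correlations, and cross-scale
# phase statistics.  The vector length is a closed-form function of the
# configuration (see texture_feature_length()).

#' Pyramid configuration for texture features
#'
#' @param n_scales number of dyadic band-pass scales (>= 2 for the
#'   cross-scale families to be nonempty).
#' @param n_orientations number of orientation bands per scale.
#' @param neighborhood odd side length of the central autocorrelation window.
#' @return a `texture_config` list.
#' @export
texture_config <- function(n_scales = 3L, n_orientations = 4L,
                           neighborhood = 7L) {
  stopifnot(n_scales >= 1, n_orientations >= 1,
            neighborhood >= 1, neighborhood %% 2 == 1)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 neighborhood = as.integer(neighborhood)),
            class = "texture_config")
}

#' Closed-form length of the texture feature vector
#'
#' With S scales, O orientations and an n x n autocorrelation window the
#' families contribute: 6 pixel marginals; 1 high-pass variance; 2 low-pass
#' skew/kurtosis; n^2 low-pass autocorrelation; S*O magnitude means;
#' S*O*n^2 magnitude autocorrelations; S*O*(O-1)/2 cross-orientation
#' correlations; (S-1)*O^2 cross-scale magnitude correlations; (S-1)*O
#' cross-scale phase statistics.
#'
#' @param config a [texture_config()].
#' @return integer vector length.
#' @export
texture_feature_length <- function(config) {
  S <- config$n_scales; O <- config$n_orientations; n <- config$neighborhood
  as.integer(6 + 1 + 2 + n^2 + S * O + S * O * n^2 +
               S * O * (O - 1) / 2 + (S - 1) * O^2 + (S - 1) * O)
}

# --- frequency-domain filters -------------------------------------------

# raised-cosine low-pass transition on [pi/4, pi/2] in radial frequency
rc_low <- function(r) {
  v <- numeric(length(r))
  v[r <= pi / 4] <- 1
  tr <- r > pi / 4 & r < pi / 2
  v[tr] <- cos(pi / 2 * log2(4 * r[tr] / pi))
  v
}

# polar frequency grids for an N x N image (unshifted FFT layout)
freq_polar <- function(n) {
  f <- c(0:(n / 2), -(n / 2 - 1):-1) * 2 * pi / n   # radians/pixel
  fx <- matrix(f, n, n)          # varies over rows
  fy <- matrix(f, n, n, byrow = TRUE)
  r <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx)
  list(r = r, theta = theta)
}

# Build the full set of frequency masks for a config and image size:
# high-pass residual, oriented band-pass masks per (scale, orientation)
# (analytic, single-sided) and the final low-pass residual.
steerable_masks <- function(n, config) {
  S <- config$n_scales; O <- config$n_orientations
  g <- freq_polar(n)
  L1 <- matrix(rc_low(g$r / 2), n, n)         # transition [pi/2, pi]
  H0 <- sqrt(pmax(0, 1 - L1^2))
  ang <- vector("list", O)
  K <- O
  for (o in seq_len(O)) {
    th0 <- (o - 1) * pi / K
    dth <- ((g$theta - th0 + pi) %% (2 * pi)) - pi
    m <- matrix(0, n, n)
    keep <- abs(dth) < pi / 2
    m[keep] <- (2 * cos(dth[keep]))^(K - 1)   # analytic, one-sided
    ang[[o]] <- m
  }
  bands <- vector("list", S)
  low_acc <- L1
  for (s in seq_len(S)) {
    rs <- g$r * 2^(s - 1)
    Ls <- matrix(rc_low(rs), n, n)
    Hs <- sqrt(pmax(0, 1 - Ls^2))
    radial <- low_acc * Hs
    bands[[s]] <- lapply(ang, function(a) radial * a)
    low_acc <- low_acc * Ls
  }
  list(highpass = H0, bands = bands, lowpass = low_acc)
}

# central n x n window of the circular autocorrelation of a real map
central_autocorr <- function(x, n_win) {
  n <- nrow(x)
  x <- x - mean(x)
  f <- stats::fft(x)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / (n * n)
  ac <- ac / (n * n)                          # -> covariances
  half <- (n_win - 1) / 2
  idx <- c(n - half + seq_len(half) - 1, 1:(half + 1)) # lags -half..half
  ac[idx, idx]
}

pearson0 <- function(x, y) {
  # zero-lag Pearson correlation between two maps; 0 when degenerate
  x <- x - mean(x); y <- y - mean(y)
  d <- sqrt(mean(x^2) * mean(y^2))
  if (d <= .Machine$double.eps) 0 else mean(x * y) / d
}

#' Steerable-pyramid texture features
#'
#' @param image a `stimulus_image` or an H x W x 3 (or H x W) array; the
#'   intensity plane (mean of RGB) is analysed.
#' @param config a [texture_config()].
#' @return named numeric vector of length [texture_feature_length()].
#' @export
texture_features <- function(image, config = texture_config()) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  x <- if (length(dim(px)) == 3L) (px[, , 1] + px[, , 2] + px[, , 3]) / 3 else px
  n <- nrow(x)
  if (n != ncol(x)) stop("texture_features expects a square image")
  S <- config$n_scales
  if (n / 2^(S + 1) < 2) stop("image too small for ", S, " scales")
  nw <- config$neighborhood
  O <- config$n_orientations
  masks <- steerable_masks(n, config)
  f <- stats::fft(x)
  sub <- lapply(masks$bands, function(scale_masks)
    lapply(scale_masks, function(m) stats::fft(f * m, inverse = TRUE) / (n * n)))
  hp <- Re(stats::fft(f * masks$highpass, inverse = TRUE)) / (n * n)
  lp <- Re(stats::fft(f * masks$lowpass, inverse = TRUE)) / (n * n)

  out <- c()
  # 1. pixel marginals
  ms <- moment_stats(as.vector(x))
  out <- c(out, px_mean = unname(ms[1]), px_var = unname(ms[2]),
           px_skew = unname(ms[3]), px_kurt = unname(ms[4]),
           px_min = min(x), px_max = max(x))
  # 2. high-pass variance
  out <- c(out, hp_var = mean((hp - mean(hp))^2))
  # 3. low-pass skew/kurt + autocorrelation
  lpm <- moment_stats(as.vector(lp))
  out <- c(out, lp_skew = unname(lpm[3]), lp_kurt = unname(lpm[4]))
  acl <- central_autocorr(lp, nw)
  names_ac <- function(tag) sprintf("%s_ac%02d", tag, seq_len(nw * nw))
  out <- c(out, stats::setNames(as.vector(acl), names_ac("lp")))
  # 4./5. magnitude means and autocorrelations
  mags <- lapply(sub, function(sc) lapply(sc, Mod))
  for (s in seq_len(S)) for (o in seq_len(O)) {
    m <- mags[[s]][[o]]
    out <- c(out, stats::setNames(mean(m), sprintf("mag_mean_s%d_o%d", s, o)))
  }
  for (s in seq_len(S)) for (o in seq_len(O)) {
    acm <- central_autocorr(mags[[s]][[o]], nw)
    out <- c(out, stats::setNames(as.vector(acm),
                                  sprintf("mag_ac_s%d_o%d_%02d", s, o,
                                          seq_len(nw * nw))))
  }
  # 6. cross-orientation magnitude correlations (within scale)
  for (s in seq_len(S)) {
    for (o1 in seq_len(O - 1)) for (o2 in (o1 + 1):O) {
      out <- c(out, stats::setNames(pearson0(mags[[s]][[o1]], mags[[s]][[o2]]),
                                    sprintf("xori_s%d_o%d_o%d", s, o1, o2)))
    }
  }
  # 7. cross-scale magnitude correlations (adjacent scales, all pairs)
  if (S >= 2) for (s in seq_len(S - 1)) {
    for (o1 in seq_len(O)) for (o2 in seq_len(O)) {
      out <- c(out,
               stats::setNames(pearson0(mags[[s]][[o1]], mags[[s + 1]][[o2]]),
                               sprintf("xscl_s%d_o%d_o%d", s, o1, o2)))
    }
  }
  # 8. cross-scale phase statistics: real part of the normalized correlation
  #    between the fine subband and the phase-doubled coarse subband
  if (S >= 2) for (s in seq_len(S - 1)) {
    for (o in seq_len(O)) {
      fine <- sub[[s]][[o]]
      coarse <- sub[[s + 1]][[o]]
      mc <- Mod(coarse)
      c2 <- ifelse(mc > .Machine$double.eps, coarse^2 / mc, 0 + 0i)
      num <- Re(mean(fine * Conj(c2)))
      den <- sqrt(mean(Mod(fine)^2) * mean(Mod(c2)^2))
      val <- if (den <= .Machine$double.eps) 0 else num / den
      out <- c(out, stats::setNames(val, sprintf("phase_s%d_o%d", s, o)))
    }
  }
  stopifnot(length(out) == texture_feature_length(config))
  out
}
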