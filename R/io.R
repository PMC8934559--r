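# Persistence: manifests and response tables as CSV (lossless round-trips
# at full precision), images as plain-text PPM, configs and diagnostic
# sets as JSON.

#' Write a table as CSV at full numeric precision
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  out <- x
  for (j in which(num)) out[[j]] <- sprintf("%.17g", x[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a manifest CSV written by [write_manifest()]
#'
#' @param path file path.
#' @param numeric_cols columns to parse as numeric (auto-detected
#'   otherwise).
#' @return data frame.
#' @export
read_manifest <- function(path, numeric_cols = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                       fileEncoding = "UTF-8")
  for (j in names(x)) {
    vals <- x[[j]]
    present <- !(vals %in% c("NA", ""))
    if (all(vals[present] %in% c("TRUE", "FALSE"))) {
      x[[j]] <- as.logical(ifelse(present, vals, NA))
      next
    }
    want_numeric <- if (is.null(numeric_cols)) {
      length(vals[present]) > 0 &&
        !anyNA(suppressWarnings(as.numeric(vals[present])))
    } else j %in% numeric_cols
    if (want_numeric) {
      x[[j]] <- suppressWarnings(as.numeric(ifelse(present, vals, NA)))
    }
  }
  x
}

#' Write an image as plain-text PPM (portable pixmap, P3)
#'
#' PPM is used instead of PNG so the whole pipeline stays text-only; any
#' standard image viewer or converter reads P3.
#'
#' @param image `stimulus_image` or 64 x 64 x 3 array in `[0,1]`.
#' @param path output file (conventionally `.ppm`).
#' @param maxval sample depth (default 255, i.e. 8-bit).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, maxval = 255L) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  d <- dim(px)
  q <- round(px * maxval)
  # interleave RGB per pixel, row-major
  rows <- vapply(seq_len(d[1]), function(i) {
    paste(as.vector(rbind(q[i, , 1], q[i, , 2], q[i, , 3])), collapse = " ")
  }, character(1))
  writeLines(c("P3", paste(d[2], d[1]), as.character(maxval), rows), path)
  invisible(path)
}

#' Read a P3 PPM image
#'
#' @param path file path.
#' @return H x W x 3 array in `[0,1]`.
#' @export
read_ppm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  stopifnot(tok[1] == "P3")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  v <- as.numeric(tok[-(1:4)]) / maxval
  px <- array(0, dim = c(h, w, 3L))
  m <- matrix(v, nrow = 3L)           # channels x (w*h), pixel-major
  for (ch in 1:3) px[, , ch] <- matrix(m[ch, ], h, w, byrow = TRUE)
  px
}

#' Serialize a diagnostic set to JSON
#'
#' @param set a `diagnostic_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagnostic_json <- function(set, path) {
  jsonlite::write_json(list(
    members = set$members,
    bin_counts = as.data.frame.matrix(unclass(set$bin_counts)),
    decorrelation_r = set$decorrelation_r,
    n_total = set$n_total, n_renderings = set$n_renderings),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
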