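## Image pre-processing: grayscale conversion, face crop, resize, equalization.
## Images are integer matrices (H x W) or arrays (H x W x 3) in 0..255.

#' Age-group bracket labels
#'
#' The eight age brackets used throughout the package, in index order
#' 0 to 7: 0-5, 6-10, 11-20, 21-30, 31-40, 41-50, 51-60 and over 60.
#' Folder names in a corpus directory are these labels prefixed with the
#' group index so an alphabetical listing preserves the order.
#'
#' @return Character vector of length 8.
#' @export
age_group_labels <- function() {
  c("0-5", "6-10", "11-20", "21-30", "31-40", "41-50", "51-60", "60plus")
}

#' Directory names for the eight age groups
#' @return Character vector of length 8, e.g. "g0_0-5".
#' @export
age_group_dirs <- function() {
  paste0("g", 0:7, "_", age_group_labels())
}

check_pixels <- function(px, what = "image") {
  if (is.null(px) || length(px) == 0) {
    stop(sprintf("invalid %s: empty pixel matrix", what), call. = FALSE)
  }
  d <- dim(px)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop(sprintf("invalid %s: expected an H x W matrix or H x W x 3 array", what),
         call. = FALSE)
  }
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L))) {
    stop(sprintf("invalid %s: channel count must be 1 or 3", what), call. = FALSE)
  }
  invisible(px)
}

#' Convert an image to grayscale
#'
#' Colour images are reduced with the ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to integers. A single-channel
#' input is returned unchanged.
#'
#' @param img Integer matrix (H x W) or array (H x W x 3), intensities 0-255.
#' @return Integer matrix H x W.
#' @export
to_grayscale <- function(img) {
  check_pixels(img)
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (d[3] == 1L) return(matrix(img[, , 1], d[1], d[2]))
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(round(g), d[1], d[2])
}

#' Detect and crop the face region
#'
#' Applies an optional face detector and crops the largest returned box,
#' then resizes the crop to an `size` x `size` square. The detector is any
#' function taking the grayscale matrix and returning a data frame / matrix
#' with columns (row, col, height, width) of candidate boxes, or NULL.
#' When no detector is supplied, or it returns no box, a deterministic
#' fallback is used: the central square of side min(H, W).
#'
#' @param img Grayscale matrix.
#' @param detector Optional detector function (see Details), or NULL.
#' @param size Output side length in pixels (default 100).
#' @return Integer matrix `size` x `size`.
#' @export
detect_and_crop <- function(img, detector = NULL, size = 100L) {
  check_pixels(img, "face image")
  if (length(dim(img)) != 2L) stop("detect_and_crop expects a single-channel image",
                                   call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  box <- NULL
  if (!is.null(detector)) {
    cand <- detector(img)
    if (!is.null(cand) && NROW(cand) > 0) {
      cand <- as.data.frame(cand)
      areas <- cand$height * cand$width
      box <- cand[which.max(areas), , drop = FALSE]
    }
  }
  if (is.null(box)) {
    side <- min(h, w)
    r0 <- floor((h - side) / 2) + 1L
    c0 <- floor((w - side) / 2) + 1L
    crop <- img[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
  } else {
    r0 <- max(1L, round(box$row))
    c0 <- max(1L, round(box$col))
    r1 <- min(h, r0 + round(box$height) - 1L)
    c1 <- min(w, c0 + round(box$width) - 1L)
    crop <- img[r0:r1, c0:c1, drop = FALSE]
  }
  resize_image(crop, size, size)
}

#' Resize an image with bilinear interpolation
#'
#' Align-corners bilinear resampling: output pixel centres map linearly onto
#' the input grid so that the four image corners are fixed points. Resizing
#' to the input's own size is the identity. Output is rounded to integers.
#'
#' @param img Grayscale matrix.
#' @param out_h,out_w Output dimensions.
#' @return Integer matrix `out_h` x `out_w`.
#' @export
resize_image <- function(img, out_h, out_w) {
  check_pixels(img, "image")
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  ry <- if (out_h > 1) seq(1, h, length.out = out_h) else (h + 1) / 2
  rx <- if (out_w > 1) seq(1, w, length.out = out_w) else (w + 1) / 2
  y0 <- pmin(floor(ry), h - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(rx), w - 1L); x0 <- pmax(x0, 1L)
  fy <- ry - y0
  fx <- rx - x0
  a <- img[y0, x0, drop = FALSE]
  b <- img[y0 + 1L, x0, drop = FALSE]
  cc <- img[y0, x0 + 1L, drop = FALSE]
  d <- img[y0 + 1L, x0 + 1L, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  out <- a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) +
    cc * (1 - wy) * wx + d * wy * wx
  round(out)
}

#' Histogram equalization
#'
#' Standard cumulative-histogram remap of an 8-bit grayscale image to the
#' full 0-255 range: each level v maps to
#' round(255 * (cdf(v) - cdf_min) / (N - cdf_min)). The map is monotone, so
#' the intensity rank order of pixels is preserved (ties may merge). An
#' image with a single intensity level is returned unchanged.
#'
#' @param img Grayscale matrix, intensities 0-255.
#' @return Equalized integer matrix of the same size.
#' @export
histogram_equalize <- function(img) {
  check_pixels(img, "image")
  v <- as.integer(round(img))
  if (any(v < 0 | v > 255)) stop("intensities must lie in 0..255", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) <= 1L) return(img)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(v)
  lut <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  lut <- pmax(pmin(lut, 255), 0)
  matrix(lut[v + 1L], nrow(img), ncol(img))
}

#' Full pre-processing pipeline for one image
#'
#' Grayscale conversion, face detection/crop (with deterministic centre-crop
#' fallback), resize to a square of side `size`, then histogram
#' equalization. Equalization is applied after the resize.
#'
#' @param img Raw image matrix or array.
#' @inheritParams detect_and_crop
#' @return Integer matrix `size` x `size`.
#' @export
preprocess_image <- function(img, detector = NULL, size = 100L) {
  histogram_equalize(detect_and_crop(to_grayscale(img), detector, size))
}

#' Read a PNG image as 0-255 intensities
#'
#' @param path Path to a PNG file.
#' @return Integer matrix (grayscale file) or H x W x 3 array (colour file;
#'   an alpha channel, if present, is dropped).
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  d <- dim(px)
  if (length(d) == 3L && d[3] >= 3L) px <- px[, , 1:3] else
    if (length(d) == 3L) px <- px[, , 1]
  round(px * 255)
}

#' Write a grayscale image to PNG
#' @param img Grayscale matrix, 0-255.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmax(pmin(img, 255), 0) / 255, path)
  invisible(path)
}

#' Load a labeled corpus from a directory tree
#'
#' Expects the layout `<root>/<group_dir>/<image>.png` with the eight group
#' directories named as in [age_group_dirs()]. Unreadable files are skipped
#' with a warning; an entirely unreadable corpus is an error.
#'
#' @param root Corpus root directory.
#' @return List with `images` (list of matrices), `labels` (integer 0-7)
#'   and `paths`.
#' @export
load_corpus <- function(root) {
  dirs <- age_group_dirs()
  images <- list(); labels <- integer(0); paths <- character(0)
  skipped <- 0L
  for (g in seq_along(dirs)) {
    d <- file.path(root, dirs[g])
    if (!dir.exists(d)) next
    files <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, g - 1L)
      paths <- c(paths, f)
    }
  }
  if (length(images) == 0L) {
    stop("no readable images found under ", root, call. = FALSE)
  }
  list(images = images, labels = labels, paths = paths, skipped = skipped)
}
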