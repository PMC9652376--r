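## Local binary pattern codes and block-histogram texture descriptors.

## Neighbor offsets, clockwise from the top-left pixel; bit i carries 2^i.
LBP_OFFSETS <- matrix(c(
  -1L, -1L,  # i = 0 top-left
  -1L,  0L,  # i = 1 top
  -1L,  1L,  # i = 2 top-right
   0L,  1L,  # i = 3 right
   1L,  1L,  # i = 4 bottom-right
   1L,  0L,  # i = 5 bottom
   1L, -1L,  # i = 6 bottom-left
   0L, -1L   # i = 7 left
), ncol = 2, byrow = TRUE)

#' LBP threshold function
#'
#' The sign threshold applied to the difference between a neighbor and the
#' centre pixel. Under the default `"strict"` mode the bit is 1 iff the
#' difference is strictly positive (ties go to 0); `"geq"` sets the bit for
#' differences >= 0, the convention common elsewhere in the LBP literature.
#'
#' @param x Numeric vector of intensity differences.
#' @param mode `"strict"` (default) or `"geq"`.
#' @return Integer vector of 0/1 bits.
#' @export
lbp_threshold <- function(x, mode = c("strict", "geq")) {
  mode <- match.arg(mode)
  if (any(!is.finite(x))) stop("non-finite difference", call. = FALSE)
  if (mode == "strict") as.integer(x > 0) else as.integer(x >= 0)
}

#' LBP code of a 3x3 neighborhood
#'
#' Thresholds the 8 neighbors against the centre and sums the bits weighted
#' by powers of two, bit i = 2^i with neighbors ordered clockwise from the
#' top-left.
#'
#' @param patch 3x3 numeric matrix; the centre entry is the reference pixel.
#' @param mode Threshold mode, see [lbp_threshold()].
#' @return Integer code in 0..255.
#' @export
lbp_code <- function(patch, mode = c("strict", "geq")) {
  if (!is.matrix(patch) || any(dim(patch) != c(3L, 3L))) {
    stop("lbp_code expects a 3x3 patch", call. = FALSE)
  }
  mode <- match.arg(mode)
  gc <- patch[2, 2]
  gi <- patch[cbind(2L + LBP_OFFSETS[, 1], 2L + LBP_OFFSETS[, 2])]
  bits <- lbp_threshold(gi - gc, mode)
  sum(bits * 2L^(0:7))
}

#' LBP code map of an image
#'
#' Applies [lbp_code()] at every interior pixel (valid-interior policy, no
#' padding), so an S x S input yields an (S-2) x (S-2) code map.
#'
#' @param img Grayscale matrix with both sides >= 3.
#' @param mode Threshold mode, see [lbp_threshold()].
#' @return Integer matrix of codes in 0..255.
#' @export
lbp_map <- function(img, mode = c("strict", "geq")) {
  mode <- match.arg(mode)
  h <- nrow(img); w <- ncol(img)
  if (is.null(h) || h < 3L || w < 3L) {
    stop("lbp_map needs an image of at least 3x3", call. = FALSE)
  }
  centre <- img[2:(h - 1), 2:(w - 1), drop = FALSE]
  codes <- matrix(0L, h - 2L, w - 2L)
  for (i in seq_len(8L)) {
    dr <- LBP_OFFSETS[i, 1]; dc <- LBP_OFFSETS[i, 2]
    nb <- img[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc), drop = FALSE]
    d <- nb - centre
    bit <- if (mode == "strict") d > 0 else d >= 0
    codes <- codes + bit * 2L^(i - 1L)
  }
  codes
}

#' Block-wise LBP histogram feature vector
#'
#' Partitions the code map into a rows x cols grid of near-equal blocks
#' (remainder pixels go to the last row/column of blocks), computes a
#' 256-bin code histogram per block and concatenates the histograms in
#' row-major block order. Each block's bins sum to its pixel count.
#'
#' @param codes Integer code-map matrix (entries 0..255).
#' @param grid Integer vector c(rows, cols).
#' @return Numeric vector of length rows * cols * 256.
#' @export
block_histogram_features <- function(codes, grid = c(7L, 7L)) {
  gr <- as.integer(grid[1]); gc <- as.integer(grid[2])
  h <- nrow(codes); w <- ncol(codes)
  if (gr < 1L || gc < 1L) stop("grid must be at least 1x1", call. = FALSE)
  if (gr > h || gc > w) stop("grid larger than the code map", call. = FALSE)
  rb <- rep(h %/% gr, gr); rb[gr] <- rb[gr] + h %% gr
  cb <- rep(w %/% gc, gc); cb[gc] <- cb[gc] + w %% gc
  re <- cumsum(rb); rs <- re - rb + 1L
  ce <- cumsum(cb); cs <- ce - cb + 1L
  out <- numeric(gr * gc * 256L)
  k <- 0L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      block <- codes[rs[i]:re[i], cs[j]:ce[j]]
      out[k + 1:256] <- tabulate(as.integer(block) + 1L, nbins = 256L)
      k <- k + 256L
    }
  }
  out
}

#' LBP block-histogram features for a list of images
#'
#' Convenience wrapper mapping each pre-processed image through [lbp_map()]
#' and [block_histogram_features()], returning a feature matrix with one
#' row per image.
#'
#' @param images List of grayscale matrices.
#' @param grid Block grid c(rows, cols).
#' @param mode Threshold mode.
#' @return Numeric matrix, nrow = length(images).
#' @export
lbp_features <- function(images, grid = c(7L, 7L), mode = c("strict", "geq")) {
  mode <- match.arg(mode)
  rows <- lapply(images, function(im) {
    block_histogram_features(lbp_map(im, mode), grid)
  })
  do.call(rbind, rows)
}
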