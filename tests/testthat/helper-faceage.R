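# Shared fixtures and independent oracles.

# Naive per-pixel double-loop LBP oracle, kept independent of lbp_map().
naive_lbp_map <- function(img, mode = "strict") {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0L, h - 2L, w - 2L)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      code <- 0L
      for (i in seq_along(offs)) {
        d <- img[r + offs[[i]][1], c + offs[[i]][2]] - img[r, c]
        bit <- if (mode == "strict") d > 0 else d >= 0
        code <- code + as.integer(bit) * 2L^(i - 1L)
      }
      out[r - 1L, c - 1L] <- code
    }
  }
  out
}

# Dense full-covariance PCA oracle (1/M normalization, no Gram trick).
dense_pca_oracle <- function(features) {
  m <- nrow(features)
  phi <- sweep(features, 2, colMeans(features))
  eg <- eigen(crossprod(phi) / m, symmetric = TRUE)
  keep <- eg$values > max(eg$values[1], 0) * 1e-10
  list(values = eg$values[keep], vectors = eg$vectors[, keep, drop = FALSE])
}

# Two well-separated Gaussian clouds in 2-D; labels 0/1.
two_gaussian_toy <- function(n_per = 20, sep = 6, sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_per, -sep / 2, sd), rnorm(n_per, 0, sd)),
             cbind(rnorm(n_per, sep / 2, sd), rnorm(n_per, 0, sd)))
  list(x = x, labels = rep(0:1, each = n_per))
}

# Energy of a grayscale image in a radial spatial-frequency band
# (cycles per image), via the 2-D FFT power spectrum.
fft_band_energy <- function(img, r_lo, r_hi) {
  s <- nrow(img)
  p <- Mod(stats::fft(img - mean(img)))^2
  fr <- pmin(0:(s - 1), s - (0:(s - 1)))   # wrap-around frequency index
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  sum(p[rad >= r_lo & rad < r_hi])
}

# The scaled-down end-to-end study runs (3 seeds, GA and fixed-config
# networks on the same corpus). Computed once and cached for reuse.
.scaled_cache <- new.env(parent = emptyenv())
scaled_study_runs <- function() {
  if (!is.null(.scaled_cache$runs)) return(.scaled_cache$runs)
  runs <- lapply(1:3, function(s) {
    corpus <- generate_corpus(synth_spec(factor = 0.1, side = 64,
                                         seed = 100 + s))
    ga_fit <- faceage(corpus, config = faceage_config(
      size = 64, grid = c(4, 4), k = 20, method = "ga",
      ga = ga_config(ps = 6, ngen = 3), seed = s))
    ann_fit <- faceage(corpus, config = faceage_config(
      size = 64, grid = c(4, 4), k = 20, method = "ann", seed = s))
    list(ga = ga_fit, ann = ann_fit)
  })
  .scaled_cache$runs <- runs
  runs
}

# Table-shaped fixture: per-group held-out counts and correct counts for
# the two reference systems (GA-evolved vs plain network).
reference_counts <- function() {
  list(n = c(20, 20, 30, 30, 20, 20, 15, 15),
       ga_correct = c(18, 18, 30, 27, 19, 18, 13, 13),
       ann_correct = c(17, 17, 28, 24, 17, 16, 12, 13))
}

# Expand per-group (n, correct) counts into predicted/actual label vectors.
counts_to_labels <- function(n, correct) {
  actual <- rep(seq_along(n) - 1L, n)
  predicted <- unlist(lapply(seq_along(n), function(g) {
    wrong <- n[g] - correct[g]
    c(rep(g - 1L, correct[g]),
      rep((g %% length(n)), wrong))  # misclassified into the next group
  }))
  list(predicted = predicted, actual = actual)
}
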