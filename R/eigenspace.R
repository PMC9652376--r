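## Eigenface-style PCA on LBP feature vectors.
##
## The covariance surrogate uses the 1/M normalization. When the feature
## dimension D exceeds the sample count M the eigenvectors are recovered
## from the M x M Gram matrix (the small-matrix trick) and mapped back to
## length D, which is the standard eigenface computation.

#' Fit an eigenface basis to a feature matrix
#'
#' Computes the mean feature vector, the deviations from it, and the
#' leading eigenvectors of the covariance surrogate C = (1/M) sum phi phi'.
#' Eigenvectors are unit-norm, mutually orthogonal, ordered by
#' non-increasing eigenvalue, and sign-fixed so the largest-magnitude entry
#' of each is positive.
#'
#' @param features M x D numeric matrix, one training feature vector per row.
#' @param k Number of components to retain. `NULL` (default) keeps the
#'   smallest K whose cumulative eigenvalue mass reaches `var_target`,
#'   capped at M-1.
#' @param var_target Cumulative variance fraction for automatic K (default
#'   0.95).
#' @return Object of class `"eigenbasis"`: list with `mean` (length D),
#'   `components` (D x K, columns u_k), `values` (length K), `k`, `d`.
#' @export
fit_eigenspace <- function(features, k = NULL, var_target = 0.95) {
  features <- as.matrix(features)
  m <- nrow(features); d <- ncol(features)
  if (m < 2L) stop("need at least 2 training vectors", call. = FALSE)
  psi <- colMeans(features)
  phi <- sweep(features, 2L, psi)          # M x D deviations
  if (d > m) {
    gram <- tcrossprod(phi) / m            # M x M
    eg <- eigen(gram, symmetric = TRUE)
    vals <- eg$values
    keep <- which(vals > max(vals[1], 0) * 1e-12 & vals > 0)
    u <- crossprod(phi, eg$vectors[, keep, drop = FALSE])  # D x r
    u <- sweep(u, 2L, sqrt(colSums(u^2)), "/")
    vals <- vals[keep]
  } else {
    covm <- crossprod(phi) / m             # D x D
    eg <- eigen(covm, symmetric = TRUE)
    vals <- eg$values
    keep <- which(vals > max(vals[1], 0) * 1e-12 & vals > 0)
    u <- eg$vectors[, keep, drop = FALSE]
    vals <- vals[keep]
  }
  r <- length(vals)
  if (r == 0L) {  # zero-variance data: a single null component
    u <- matrix(0, d, 1); u[1, 1] <- 1
    vals <- 0
    r <- 1L
  }
  kmax <- min(m - 1L, r)
  if (is.null(k)) {
    if (sum(vals) <= 0) {
      k <- 1L
    } else {
      cum <- cumsum(vals) / sum(vals)
      k <- min(which(cum >= var_target), kmax)
    }
  }
  if (k < 1L || k > min(m - 1L, d)) {
    stop("k must lie in 1..min(M-1, D)", call. = FALSE)
  }
  k <- min(k, r)
  u <- u[, seq_len(k), drop = FALSE]
  # sign convention: largest-|entry| coordinate positive
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  structure(list(mean = psi, components = u, values = vals[seq_len(k)],
                 k = k, d = d, m = m),
            class = "eigenbasis")
}

#' Project feature vectors into an eigenface basis
#'
#' Subtracts the training mean and takes dot products with the retained
#' eigenvectors: omega_k = u_k . (I - psi).
#'
#' @param basis An `"eigenbasis"` from [fit_eigenspace()].
#' @param features Length-D vector or N x D matrix.
#' @return Length-K weight vector, or N x K matrix for matrix input.
#' @export
eigen_project <- function(basis, features) {
  stopifnot(inherits(basis, "eigenbasis"))
  if (is.null(dim(features))) {
    if (length(features) != basis$d) {
      stop("feature length does not match the basis dimension", call. = FALSE)
    }
    return(drop(crossprod(basis$components, features - basis$mean)))
  }
  features <- as.matrix(features)
  if (ncol(features) != basis$d) {
    stop("feature length does not match the basis dimension", call. = FALSE)
  }
  sweep(features, 2L, basis$mean) %*% basis$components
}

#' Reconstruct a feature vector from its projection weights
#'
#' @param basis An `"eigenbasis"`.
#' @param weights Length-K weight vector.
#' @return Length-D reconstruction psi + sum omega_k u_k.
#' @export
eigen_reconstruct <- function(basis, weights) {
  stopifnot(inherits(basis, "eigenbasis"), length(weights) == basis$k)
  drop(basis$mean + basis$components %*% weights)
}

#' @export
print.eigenbasis <- function(x, ...) {
  cat(sprintf("Eigenface basis: %d components of dimension %d (fit on %d samples)\n",
              x$k, x$d, x$m))
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(utils::head(x$values, 5), 4), collapse = ", ")))
  invisible(x)
}
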