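## Single hidden-layer perceptron trained by damped second-order
## backpropagation (Levenberg-Marquardt style): step
## dw = -(J'J + mu I)^-1 J'e, with mu decreased on accepted steps and
## increased on rejected ones. A plain gradient-descent-with-momentum
## trainer is available as a configuration alternative.

#' Network training configuration
#'
#' Defaults follow the common damped-second-order trainer settings:
#' initial damping mu = 0.001, decrease factor 0.1, increase factor 10,
#' MSE goal 1e-3, at most 200 epochs, 10 hidden neurons. `learning_rate`
#' is used only by the `"gdm"` (gradient descent with momentum) trainer;
#' the `"lm"` trainer's step size is governed entirely by mu.
#'
#' @param hidden_size Hidden-layer width (positive integer).
#' @param learning_rate Learning rate for the `"gdm"` trainer.
#' @param mu Initial damping term (> 0).
#' @param mu_dec Multiplicative mu decrease on accepted steps, in (0, 1).
#' @param mu_inc Multiplicative mu increase on rejected steps, > 1.
#' @param goal MSE stopping threshold.
#' @param max_epochs Epoch cap.
#' @param trainer `"lm"` or `"gdm"`.
#' @return List of class `"network_config"`.
#' @export
network_config <- function(hidden_size = 10L, learning_rate = 0.01,
                           mu = 1e-3, mu_dec = 0.1, mu_inc = 10,
                           goal = 1e-3, max_epochs = 200L,
                           trainer = c("lm", "gdm")) {
  trainer <- match.arg(trainer)
  stopifnot(hidden_size >= 1, learning_rate > 0, mu > 0,
            mu_dec > 0, mu_dec < 1, mu_inc > 1, goal > 0, max_epochs >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate, mu = mu, mu_dec = mu_dec,
                 mu_inc = mu_inc, goal = goal,
                 max_epochs = as.integer(max_epochs), trainer = trainer),
            class = "network_config")
}

#' Initialize a multilayer perceptron
#'
#' Weights and biases are drawn uniformly from (-0.5, 0.5) using the
#' current RNG state (seed it for reproducibility). Hidden activation is
#' tanh; outputs are linear and scored by argmax.
#'
#' @param n_in Input dimension (eigen-weight length).
#' @param n_hidden Hidden-layer width.
#' @param n_out Output dimension (number of classes).
#' @return List of class `"mlp"` with `w1`, `b1`, `w2`, `b2`.
#' @export
mlp_init <- function(n_in, n_hidden, n_out = 8L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  structure(list(
    w1 = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    b1 = stats::runif(n_hidden, -0.5, 0.5),
    w2 = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
    b2 = stats::runif(n_out, -0.5, 0.5),
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
    n_out = as.integer(n_out)), class = "mlp")
}

#' Forward pass
#'
#' @param net An `"mlp"` network.
#' @param x Length-`n_in` vector or N x `n_in` matrix.
#' @return Length-`n_out` score vector, or N x `n_out` matrix.
#' @export
mlp_forward <- function(net, x) {
  single <- is.null(dim(x))
  x <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(x) != net$n_in) stop("input dimension mismatch", call. = FALSE)
  h <- tanh(x %*% t(net$w1) + matrix(net$b1, nrow(x), net$n_hidden, byrow = TRUE))
  y <- h %*% t(net$w2) + matrix(net$b2, nrow(x), net$n_out, byrow = TRUE)
  if (single) drop(y) else y
}

#' Mean squared error of a network on a dataset
#'
#' Mean over samples and output units of the squared difference between
#' scores and (one-hot) targets.
#'
#' @param net An `"mlp"`.
#' @param x N x `n_in` input matrix.
#' @param targets N x `n_out` target matrix.
#' @return Scalar MSE.
#' @export
mlp_mse <- function(net, x, targets) {
  x <- as.matrix(x); targets <- as.matrix(targets)
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  y <- mlp_forward(net, x)
  mean((y - targets)^2)
}

#' One-hot target coding
#' @param labels Integer class labels, 0-based.
#' @param n_classes Number of classes (default 8 age groups).
#' @return N x `n_classes` 0/1 matrix.
#' @export
one_hot <- function(labels, n_classes = 8L) {
  t <- matrix(0, length(labels), n_classes)
  t[cbind(seq_along(labels), labels + 1L)] <- 1
  t
}

#' Contiguous block train/test split
#'
#' The first `train_frac` fraction of the sample order forms the training
#' block and the remainder the test block; the blocks are contiguous,
#' disjoint and cover all indices.
#'
#' @param n Number of samples.
#' @param train_frac Training fraction (default 0.8).
#' @return List with integer vectors `train` and `test`.
#' @export
divide_block <- function(n, train_frac = 0.8) {
  stopifnot(n >= 1, train_frac > 0, train_frac < 1)
  n_train <- max(1L, min(n - 1L, floor(n * train_frac)))
  if (n == 1L) return(list(train = 1L, test = integer(0)))
  list(train = seq_len(n_train), test = seq.int(n_train + 1L, n))
}

## --- internal parameter (un)packing and Jacobian -------------------------

pack_params <- function(net) c(as.vector(net$w1), net$b1, as.vector(net$w2), net$b2)

unpack_params <- function(net, w) {
  nh <- net$n_hidden; ni <- net$n_in; no <- net$n_out
  i <- 0L
  net$w1 <- matrix(w[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  net$b1 <- w[i + seq_len(nh)]; i <- i + nh
  net$w2 <- matrix(w[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  net$b2 <- w[i + seq_len(no)]
  net
}

#' Residual Jacobian of an MLP
#'
#' Residuals are stacked output-fastest: row (n-1)*n_out + o holds sample
#' n, output unit o. Columns follow the parameter packing
#' (vec(w1), b1, vec(w2), b2). Exposed mainly for diagnostics and for
#' verifying the damped update against its gradient-descent limit.
#'
#' @param net An `"mlp"`.
#' @param x N x `n_in` matrix.
#' @param targets N x `n_out` matrix.
#' @return List with `J` (residual Jacobian) and `e` (residual vector).
#' @export
mlp_jacobian <- function(net, x, targets) {
  x <- as.matrix(x); targets <- as.matrix(targets)
  n <- nrow(x); nh <- net$n_hidden; ni <- net$n_in; no <- net$n_out
  h1 <- tanh(x %*% t(net$w1) + matrix(net$b1, n, nh, byrow = TRUE))
  y <- h1 %*% t(net$w2) + matrix(net$b2, n, no, byrow = TRUE)
  e <- as.vector(t(y - targets))                   # output-fastest
  s <- 1 - h1^2                                    # tanh'
  p <- nh * ni + nh + no * nh + no
  jac <- matrix(0, n * no, p)
  xexp <- x[rep(seq_len(n), each = no), , drop = FALSE]
  off_b1 <- nh * ni
  off_w2 <- off_b1 + nh
  off_b2 <- off_w2 + no * nh
  for (h in seq_len(nh)) {
    vecm <- as.vector(outer(net$w2[, h], s[, h]))  # length n*no
    jac[, (h - 1L) + seq.int(1L, nh * ni, by = nh)] <- vecm * xexp
    jac[, off_b1 + h] <- vecm
    for (o in seq_len(no)) {
      jac[seq.int(o, n * no, by = no), off_w2 + (h - 1L) * no + o] <- h1[, h]
    }
  }
  for (o in seq_len(no)) {
    jac[seq.int(o, n * no, by = no), off_b2 + o] <- 1
  }
  list(J = jac, e = e)
}

lm_delta <- function(jac, e, mu) {
  p <- ncol(jac); r <- nrow(jac)
  res <- tryCatch({
    if (p <= r) {
      a <- crossprod(jac)
      diag(a) <- diag(a) + mu
      -solve(a, crossprod(jac, e))
    } else {
      a <- tcrossprod(jac)
      diag(a) <- diag(a) + mu
      -crossprod(jac, solve(a, e))
    }
  }, error = function(err) NULL)
  if (is.null(res)) NULL else as.vector(res)
}

## --- training ------------------------------------------------------------

#' Train an MLP
#'
#' The default `"lm"` trainer applies damped Gauss-Newton updates
#' dw = -(J'J + mu I)^-1 J'e. A step that lowers the training MSE is
#' accepted and mu is multiplied by `mu_dec`; otherwise the step is
#' rejected and mu is multiplied by `mu_inc`, retrying until mu exceeds
#' 1e10 (which ends training). Training also stops when the MSE reaches
#' `goal` or at `max_epochs`. The `"gdm"` trainer is classic batch
#' backpropagation with momentum 0.9 and step size `learning_rate`.
#'
#' @param net An `"mlp"` (see [mlp_init()]).
#' @param x Training inputs, N x `n_in`.
#' @param targets Training targets, N x `n_out` (one-hot for
#'   classification).
#' @param config A [network_config()].
#' @return List of class `"mlp_fit"`: `net` (trained), `trace`
#'   (data.frame epoch/mse/mu), `mse` (final), `converged`.
#' @export
mlp_train <- function(net, x, targets, config = network_config()) {
  x <- as.matrix(x); targets <- as.matrix(targets)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(nrow(x) == nrow(targets))
  if (config$trainer == "lm") {
    fit <- train_lm(net, x, targets, config)
  } else {
    fit <- train_gdm(net, x, targets, config)
  }
  fit
}

diverged <- function(msg) {
  stop(structure(class = c("faceage_divergence", "error", "condition"),
                 list(message = msg, call = NULL)))
}

train_lm <- function(net, x, targets, config) {
  mu <- config$mu
  mse <- mlp_mse(net, x, targets)
  if (!is.finite(mse)) diverged("non-finite initial loss")
  trace <- list(data.frame(epoch = 0L, mse = mse, mu = mu))
  epoch <- 0L
  while (mse > config$goal && epoch < config$max_epochs && mu <= 1e10) {
    jm <- mlp_jacobian(net, x, targets)
    w <- pack_params(net)
    accepted <- FALSE
    while (mu <= 1e10) {
      delta <- lm_delta(jm$J, jm$e, mu)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- unpack_params(net, w + delta)
        mse_new <- mlp_mse(cand, x, targets)
        if (is.finite(mse_new) && mse_new < mse) {
          net <- cand
          mse <- mse_new
          mu <- max(mu * config$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) break
    epoch <- epoch + 1L
    trace[[length(trace) + 1L]] <- data.frame(epoch = epoch, mse = mse, mu = mu)
  }
  if (!is.finite(mse)) diverged("non-finite loss during training")
  structure(list(net = net, trace = do.call(rbind, trace), mse = mse,
                 converged = mse <= config$goal, config = config),
            class = "mlp_fit")
}

train_gdm <- function(net, x, targets, config) {
  n <- nrow(x); momentum <- 0.9
  vel <- rep(0, length(pack_params(net)))
  mse <- mlp_mse(net, x, targets)
  trace <- list(data.frame(epoch = 0L, mse = mse, mu = NA_real_))
  for (epoch in seq_len(config$max_epochs)) {
    if (mse <= config$goal) break
    h1 <- tanh(x %*% t(net$w1) + matrix(net$b1, n, net$n_hidden, byrow = TRUE))
    y <- h1 %*% t(net$w2) + matrix(net$b2, n, net$n_out, byrow = TRUE)
    dy <- 2 * (y - targets) / length(y)
    gw2 <- crossprod(dy, h1)
    gb2 <- colSums(dy)
    dh <- (dy %*% net$w2) * (1 - h1^2)
    gw1 <- crossprod(dh, x)
    gb1 <- colSums(dh)
    grad <- c(as.vector(gw1), gb1, as.vector(gw2), gb2)
    vel <- momentum * vel - config$learning_rate * grad
    net <- unpack_params(net, pack_params(net) + vel)
    mse <- mlp_mse(net, x, targets)
    if (!is.finite(mse)) diverged("non-finite loss during training")
    trace[[length(trace) + 1L]] <- data.frame(epoch = epoch, mse = mse,
                                              mu = NA_real_)
  }
  structure(list(net = net, trace = do.call(rbind, trace), mse = mse,
                 converged = mse <= config$goal, config = config),
            class = "mlp_fit")
}

#' Predict the age-group index for inputs
#'
#' Argmax over the network's output scores; ties break toward the lowest
#' index. Indices are 0-based (0-7 for the eight age groups).
#'
#' @param net An `"mlp"` or `"mlp_fit"`.
#' @param x Input vector or matrix.
#' @return Integer vector of 0-based class indices.
#' @export
predict_group <- function(net, x) {
  if (inherits(net, "mlp_fit")) net <- net$net
  y <- mlp_forward(net, x)
  if (is.null(dim(y))) return(which.max(y) - 1L)
  max.col(y, ties.method = "first") - 1L
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("MLP fit (%s): %d-%d-%d, final MSE %.4g after %d epochs%s\n",
              x$config$trainer, x$net$n_in, x$net$n_hidden, x$net$n_out,
              x$mse, max(x$trace$epoch),
              if (x$converged) " (goal reached)" else ""))
  invisible(x)
}
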