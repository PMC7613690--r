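#' NCA configuration
#'
#' @param lambda Ridge penalty on the feature weights (default 3e-5).
#' @param threshold_frac Selection threshold as a fraction of the maximum
#'   weight (default 0.10).
#' @param sigma Softmax kernel width on the weighted-L1 distances (default
#'   1, i.e. raw distances between standardized features, so that nearest
#'   neighbors dominate the reference probabilities).
#' @param learning_rate,epochs,batch_size SGD parameters.
#' @param seed RNG seed for batching and initialization.
#' @return An `nca_config` list.
#' @export
nca_config <- function(lambda = 3e-5, threshold_frac = 0.10, sigma = 1,
                       learning_rate = 0.2, epochs = 40, batch_size = 96,
                       seed = 1L) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  structure(list(lambda = lambda, threshold_frac = threshold_frac,
                 sigma = sigma, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, seed = seed),
            class = "nca_config")
}

#' Neighborhood components analysis feature weights
#'
#' Diagonal (per-feature) NCA for feature selection: maximizes the expected
#' leave-one-out stochastic nearest-neighbor classification accuracy
#'
#'   F(w) = (1/n) sum_i sum_{j in class(i)} p_ij  -  lambda * sum_l w_l^2
#'
#' where p_ij = exp(-d_ij / s) / sum_{k != i} exp(-d_ik / s) and
#' d_ij = sum_l w_l^2 |x_il - x_jl| is a weighted-L1 distance over
#' standardized features with squared per-feature weights (the squared
#' parameterization makes the updates multiplicative in w, so irrelevant
#' weights decay geometrically) and `s = cfg$sigma`. Optimization is
#' minibatch stochastic gradient ascent over anchor points; weights are
#' clipped nonnegative after every update. Deterministic given
#' `cfg$seed`.
#'
#' @param X Numeric matrix (rows = samples); features are standardized
#'   internally.
#' @param y Binary labels (factor/logical/0-1), both classes present.
#' @param cfg An [nca_config()].
#' @return An `nca_weights` object: `w` (nonnegative per-feature weights),
#'   `selected` (logical mask `w >= threshold_frac * max(w)`), `objective`
#'   (per-epoch trace) and the scaling used.
#' @export
nca_feature_weights <- function(X, y, cfg = nca_config()) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  w <- rep(1, p)
  s_width <- cfg$sigma

  anchor_grad <- function(i, w) {
    A <- abs(sweep(Z, 2, Z[i, ], `-`))       # n x p
    d <- as.numeric(A %*% (w^2)) / s_width
    ker <- exp(-(d - min(d[-i])))            # shift for stability
    ker[i] <- 0
    Zk <- sum(ker)
    if (Zk <= 0) return(list(p_i = 0, grad = rep(0, p)))
    pr <- ker / Zk
    same <- as.numeric(y == y[i]); same[i] <- 0
    p_i <- sum(pr * same)
    # d/dw_l of p_i; the squared parameterization contributes 2 w_l
    g <- 2 * w * (p_i * colSums(pr * A) - colSums((pr * same) * A)) / s_width
    list(p_i = p_i, grad = g)
  }

  obj_trace <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1L, {
    lr <- cfg$learning_rate
    for (ep in seq_len(cfg$epochs)) {
      batch <- sample.int(n, min(cfg$batch_size, n))
      grad <- rep(0, p); acc <- 0
      for (i in batch) {
        ag <- anchor_grad(i, w)
        grad <- grad + ag$grad
        acc <- acc + ag$p_i
      }
      grad <- grad / length(batch) - 2 * cfg$lambda * w
      w <- pmax(w + lr * grad, 0)
      obj_trace[ep] <- acc / length(batch) - cfg$lambda * sum(w^2)
      lr <- cfg$learning_rate / (1 + ep / cfg$epochs)
    }
  })

  sel <- w >= cfg$threshold_frac * max(w)
  structure(list(w = w, selected = sel, objective = obj_trace,
                 threshold_frac = cfg$threshold_frac,
                 center = mu, scale = sdv, s_width = s_width, cfg = cfg),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  cat(sprintf("<nca_weights> %d features, %d selected (threshold %.0f%% of max weight %.3f)\n",
              length(x$w), sum(x$selected), 100 * x$threshold_frac, max(x$w)))
  invisible(x)
}
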