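# 60 / 20 / 20 train / validation / hold-out split, seeded
split_indices <- function(n, split_seed) {
  with_seed(split_seed, {
    ix <- sample.int(n)
    n_tr <- floor(0.6 * n); n_va <- floor(0.2 * n)
    list(train = ix[seq_len(n_tr)],
         val = ix[n_tr + seq_len(n_va)],
         test = ix[(n_tr + n_va + 1):n])
  })
}

#' Train the AIS-relocation status detector
#'
#' Random-forest classifier (100 trees, sqrt(p) features per split) on
#' NCA-selected delta features, separating valid relocation vectors from
#' shams. Rows are split 60/20/20 into training, validation and hold-out
#' sets; the confusion matrix and rates are reported on the hold-out set
#' only. For small (detailed-profile) datasets, `cv_folds` switches to
#' k-fold cross-validation instead.
#'
#' @param X_selected Feature matrix (NCA-selected columns).
#' @param y Logical/binary labels (`TRUE` = valid relocation).
#' @param split_seed Seed controlling the split and forest.
#' @param n_trees Number of trees.
#' @param cv_folds If > 1, evaluate by k-fold cross-validation (pooled
#'   confusion over folds) instead of the hold-out protocol.
#' @return A `trained_detector`: fitted forest, hold-out `confusion`,
#'   `tpr`, `fpr`, `accuracy`, and the split indices.
#' @export
train_detector <- function(X_selected, y, split_seed = 1, n_trees = 100,
                           cv_folds = 1) {
  X <- as.matrix(X_selected)
  if (ncol(X) == 0) stop("empty selected-feature mask")
  y <- factor(as.logical(y), levels = c(FALSE, TRUE))
  fit_rf <- function(Xtr, ytr) {
    randomForest::randomForest(x = Xtr, y = ytr, ntree = n_trees)
  }
  if (cv_folds > 1) {
    folds <- with_seed(split_seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
    pred <- factor(rep(NA, nrow(X)), levels = levels(y))
    model <- NULL
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      model <- with_seed(split_seed + k, fit_rf(X[tr, , drop = FALSE], y[tr]))
      pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
    }
    truth <- y; idx <- list(cv_folds = folds)
  } else {
    idx <- split_indices(nrow(X), split_seed)
    model <- with_seed(split_seed,
                       fit_rf(X[idx$train, , drop = FALSE], y[idx$train]))
    pred <- predict(model, X[idx$test, , drop = FALSE])
    truth <- y[idx$test]
  }
  cm <- table(truth = truth, pred = pred)
  tp <- cm["TRUE", "TRUE"]; fn <- cm["TRUE", "FALSE"]
  fp <- cm["FALSE", "TRUE"]; tn <- cm["FALSE", "FALSE"]
  structure(list(model = model, confusion = cm,
                 tpr = tp / (tp + fn), fpr = fp / (fp + tn),
                 accuracy = (tp + tn) / sum(cm), split = idx),
            class = "trained_detector")
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf("<trained_detector> hold-out TPR %.3f, FPR %.3f, accuracy %.3f\n",
              x$tpr, x$fpr, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Predict relocation status for new delta vectors
#' @param detector A `trained_detector`.
#' @param X New rows (same columns as training).
#' @return Logical vector (`TRUE` = valid relocation).
#' @export
predict_relocation <- function(detector, X) {
  as.logical(predict(detector$model, as.matrix(X)))
}

# ---- wide single-hidden-layer ReLU network ---------------------------------

#' Fit a wide single-hidden-layer ReLU network
#'
#' 100 rectified-linear hidden units, linear output, mean-squared-error
#' loss, Adam updates with minibatches, early stopping on a validation
#' set (restores the best validation weights). Inputs and targets are
#' standardized internally. Deterministic given `seed`.
#'
#' @param X,y Training inputs/targets.
#' @param Xval,yval Validation set for early stopping (optional).
#' @param hidden Hidden width (default 100).
#' @param max_epochs,batch_size,lr,patience Optimizer settings.
#' @param seed RNG seed (init + batching).
#' @return An `mlp_model` with `predict`-able weights.
#' @export
fit_mlp <- function(X, y, Xval = NULL, yval = NULL, hidden = 100,
                    max_epochs = 500, batch_size = 32, lr = 1e-3,
                    patience = 30, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  ymu <- mean(y); ysd <- sd(y); if (ysd == 0 || is.na(ysd)) ysd <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`); t_ <- (y - ymu) / ysd
  Zv <- if (!is.null(Xval)) sweep(sweep(as.matrix(Xval), 2, mu), 2, sdv, `/`)
  tv <- if (!is.null(yval)) (as.numeric(yval) - ymu) / ysd
  p <- ncol(Z); n <- nrow(Z)

  with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    adam <- function() list(m = 0, v = 0)
    st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
    b1_ <- 0.9; b2_ <- 0.999; eps <- 1e-8; tstep <- 0
    upd <- function(sl, g) {
      sl$m <- b1_ * sl$m + (1 - b1_) * g
      sl$v <- b2_ * sl$v + (1 - b2_) * g^2
      sl
    }
    step_of <- function(sl) {
      mhat <- sl$m / (1 - b1_^tstep); vhat <- sl$v / (1 - b2_^tstep)
      lr * mhat / (sqrt(vhat) + eps)
    }
    fwd <- function(Zm) {
      H <- pmax(Zm %*% W1 + matrix(b1, nrow(Zm), hidden, byrow = TRUE), 0)
      list(H = H, out = as.numeric(H %*% W2 + b2))
    }
    best <- list(err = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    wait <- 0
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, n)]
        Zb <- Z[bi, , drop = FALSE]; tb <- t_[bi]
        f <- fwd(Zb)
        err <- f$out - tb                       # d(MSE/2)/dout
        gW2 <- crossprod(f$H, err) / length(bi)
        gb2 <- mean(err)
        dH <- (matrix(err, ncol = 1) %*% t(W2)) * (f$H > 0)
        gW1 <- crossprod(Zb, dH) / length(bi)
        gb1 <- colMeans(dH)
        tstep <- tstep + 1
        st$W1 <- upd(st$W1, gW1); st$b1 <- upd(st$b1, gb1)
        st$W2 <- upd(st$W2, gW2); st$b2 <- upd(st$b2, gb2)
        W1 <- W1 - step_of(st$W1); b1 <- b1 - step_of(st$b1)
        W2 <- W2 - step_of(st$W2); b2 <- b2 - step_of(st$b2)
      }
      if (!is.null(Zv)) {
        verr <- mean((fwd(Zv)$out - tv)^2)
        if (verr < best$err - 1e-7) {
          best <- list(err = verr, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
          wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= patience) break
        }
      }
    }
    if (!is.null(Zv) && is.finite(best$err)) {
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   center = mu, scale = sdv, y_center = ymu, y_scale = ysd,
                   hidden = hidden),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, `/`)
  H <- pmax(Z %*% object$W1 +
              matrix(object$b1, nrow(Z), object$hidden, byrow = TRUE), 0)
  as.numeric(H %*% object$W2 + object$b2) * object$y_scale + object$y_center
}

#' Train the relocation-magnitude regressor
#'
#' Wide neural network (single hidden layer of 100 ReLU units, linear
#' output) regressing the AIS relocation magnitude (um) on the full
#' delta-amplitude feature vector of valid relocation rows. 60/20/20
#' split: trained on 60%, early-stopped on the 20% validation split,
#' metrics reported on the 20% hold-out only.
#'
#' @param X_full Delta-amplitude feature matrix (valid rows only).
#' @param magnitudes Relocation magnitudes, um.
#' @param split_seed Seed for split and initialization.
#' @return A `trained_regressor`: the fitted network, hold-out `r2`,
#'   `rmse`, predictions and truth. A constant target is flagged
#'   (`degenerate = TRUE`, `r2 = NA`).
#' @export
train_magnitude_regressor <- function(X_full, magnitudes, split_seed = 1) {
  X <- as.matrix(X_full); y <- as.numeric(magnitudes)
  if (anyNA(y)) stop("magnitudes must be defined for all (valid) rows")
  idx <- split_indices(nrow(X), split_seed)
  if (length(idx$train) < 50)
    stop("refusing to train on fewer than 50 rows")
  degenerate <- sd(y) == 0
  model <- fit_mlp(X[idx$train, , drop = FALSE], y[idx$train],
                   X[idx$val, , drop = FALSE], y[idx$val],
                   seed = split_seed)
  pred <- predict(model, X[idx$test, , drop = FALSE])
  truth <- y[idx$test]
  ss_res <- sum((pred - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  structure(list(model = model,
                 r2 = if (degenerate || ss_tot == 0) NA_real_ else
                   1 - ss_res / ss_tot,
                 rmse = sqrt(mean((pred - truth)^2)),
                 predictions = pred, truth = truth,
                 degenerate = degenerate, split = idx),
            class = "trained_regressor")
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat(sprintf("<trained_regressor> hold-out R^2 %s, RMSE %.3f um%s\n",
              format(x$r2, digits = 4), x$rmse,
              if (x$degenerate) " [degenerate target]" else ""))
  invisible(x)
}
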