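test_that("the convolution matrix realizes the convolution sum exactly", {
  # unit impulse: X is the first L columns of the identity
  x <- c(1, rep(0, 9))
  X <- build_convolution_matrix(x, 3)
  expect_equal(X, diag(10)[, 1:3])
  # identity kernel reproduces the input
  set.seed(1)
  x <- rnorm(50)
  X <- build_convolution_matrix(x, 8)
  expect_equal(as.numeric(X %*% c(1, rep(0, 7))), x)
  # matrix product vs the direct convolution-sum loop
  h <- rnorm(8)
  direct <- vapply(seq_along(x), function(n)
    sum(vapply(seq_along(h), function(m)
      if (n - m + 1 >= 1) h[m] * x[n - m + 1] else 0, numeric(1))),
    numeric(1))
  expect_lt(max(abs(as.numeric(X %*% h) - direct)), 1e-10)
  expect_error(build_convolution_matrix(rnorm(5), 10), "shorter")
})

test_that("kernel estimation inverts known transformations", {
  set.seed(2)
  x <- rnorm(96)                              # white input: well-conditioned
  # identity
  k_id <- estimate_kernel(x, x, L = 25)
  expect_lt(max(abs(k_id$h - c(1, rep(0, 24)))), 1e-6)
  # known kernel recovery
  h_true <- c(0.4, -0.2, 0.8, 0.1, rep(0, 21))
  y <- predict_waveform(x, h_true)
  k <- estimate_kernel(x, y, L = 25)
  expect_lt(max(abs(k$h - h_true)), 1e-8)
  # scaled unit delay
  y2 <- 2 * c(0, x[-96])
  k2 <- estimate_kernel(x, y2, L = 25)
  expect_lt(max(abs(k2$h - c(0, 2, rep(0, 23)))), 1e-6)
  expect_error(estimate_kernel(rep(0, 96), y, 25), "zero")
})

test_that("ill-conditioned inputs fall back to the ridge pseudoinverse", {
  x <- ((1:96) / 96)^3                        # very smooth: shifts collinear
  y <- 2 * x
  k <- estimate_kernel(x, y, L = 25)
  expect_true(k$ridge)
  expect_true(all(is.finite(k$h)))
  set.seed(3)
  k2 <- estimate_kernel(rnorm(60), rnorm(60), L = 10)
  expect_false(k2$ridge)
})

test_that("normalized RMS error matches hand calculations", {
  set.seed(4)
  y <- rnorm(96)
  expect_equal(normalized_rms_error(y, y), 0)
  # constant offset: E = |c| / range
  c0 <- 0.37
  yhat <- y + c0
  expect_equal(normalized_rms_error(yhat, y), c0 / (max(yhat) - min(yhat)))
  # joint scaling leaves E unchanged
  yh2 <- y + rnorm(96, sd = 0.1)
  expect_equal(normalized_rms_error(2 * yh2, 2 * y),
               normalized_rms_error(yh2, y))
  flat <- normalized_rms_error(rep(1, 96), y)
  expect_true(is.na(flat))
  expect_true(attr(flat, "flat"))
})

test_that("prediction error shrinks with kernel length on simulated pairs", {
  fam <- reduced_family()
  pairs <- list()
  for (g in fam$groups[seq(1, 41, by = 2)]) {
    pairs[[length(pairs) + 1]] <- list(x = g$baseline$w[, 5],
                                       y = g$comparisons[["30"]]$w[, 5])
  }
  expect_gte(length(pairs), 20)
  meanE <- vapply(c(5, 10, 15, 20, 25), function(L) {
    mean(vapply(pairs, function(p) {
      k <- estimate_kernel(p$x, p$y, L = L)
      normalized_rms_error(predict_waveform(p$x, k), p$y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanE) <= 1e-12))      # non-increasing in L
})

test_that("the kernel library stores the full reduced grid", {
  lib <- reduced_library()
  expect_equal(lib$L, 25)
  expect_equal(lib$M, 26)
  expect_equal(lib$d_grid, seq(5, 40, by = 5))
  expect_equal(length(lib$thetas), 24)
  expect_equal(nrow(lib$offsets), 2)
  # kernels per entry: L x 26
  H <- lib$entries[[1]]$kernels[["15"]]
  expect_equal(dim(H), c(25, 26))
  # baseline-vs-baseline kernels are identity-like: E ~ 0
  g <- reduced_family()$groups[[1]]
  H5 <- lib$entries[[1]]$kernels[["5"]]
  E <- normalized_rms_error(predict_waveform(g$baseline$w[, 1], H5[, 1]),
                            g$baseline$w[, 1])
  expect_lt(E, 1e-8)
})

test_that("electrode matching retrieves library entries exactly", {
  lib <- reduced_library()
  fam <- reduced_family()
  g <- fam$groups[[7]]
  m <- 4
  res <- match_electrode(lib, g$baseline$w[, m], g$comparisons[["20"]]$w[, m],
                         d_ais = 20)
  expect_equal(res$m_star, m)
  # the generating angle, up to the mirror symmetry of the straight
  # ball-and-stick geometry about the offset axis
  expect_true(res$theta %in% c(g$theta, (360 - g$theta) %% 360))
  # the entry's own least-squares kernel is the best available predictor
  H_own <- lib$entries[[7]]$kernels[["20"]]
  expect_equal(res$E, normalized_rms_error(
    predict_waveform(g$baseline$w[, m], H_own[, m]),
    g$comparisons[["20"]]$w[, m]), tolerance = 1e-12)
  # brute-force scan oracle on a cross-morphology target
  tgt <- detailed_targets()
  xb <- tgt$baseline$w[, 9]; yb <- tgt$comparisons[["15"]]$w[, 9]
  res2 <- match_electrode(lib, xb, yb, d_ais = 15)
  best <- Inf; arg <- NA
  for (en in lib$entries) {
    H <- en$kernels[["15"]]
    if (is.null(H)) next
    for (mm in seq_len(ncol(H))) {
      E <- normalized_rms_error(predict_waveform(xb, H[, mm]), yb)
      if (is.finite(E) && E < best) { best <- E; arg <- mm }
    }
  }
  expect_equal(res2$m_star, arg)
  expect_equal(res2$E, best, tolerance = 1e-12)
  expect_error(match_electrode(lib, xb, yb, d_ais = 13), "grid")
})

test_that("error curves are self-consistent for library-generated pairs", {
  lib <- reduced_library()
  g <- reduced_family()$groups[[3]]
  # construct the relocated footprint by convolving the baseline with the
  # stored kernels of one entry: the curve must vanish at that entry
  entry <- which(vapply(lib$entries, function(e)
    e$theta == g$theta && all(e$offset == g$offset), logical(1)))
  H <- lib$entries[[entry]]$kernels[["25"]]
  y_syn <- vapply(seq_len(26), function(m)
    predict_waveform(g$baseline$w[, m], H[, m]), numeric(96))
  est <- estimate_ais_position(lib, g$baseline$w, y_syn, offset_mode = "min")
  expect_lt(est$error_curve$E[est$error_curve$d_ais == 25], 1e-8)
  expect_true(all(est$error_curve$E[est$error_curve$d_ais != 25] > 1e-8))
  expect_equal(est$d_hat, 25, tolerance = 3)
})

test_that("an untransformed pair is estimated at the baseline end", {
  lib <- reduced_library()
  tgt <- detailed_targets()
  est <- estimate_ais_position(lib, tgt$baseline$w, tgt$baseline$w)
  expect_equal(est$d_hat, 5, tolerance = 2.5)
})
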