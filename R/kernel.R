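#' Convolution (Toeplitz) matrix of a waveform
#'
#' Builds the N x L lower-banded Toeplitz matrix `X` of a length-N
#' waveform, so that `X %*% h` equals the first N samples of the
#' convolution of `x` with a length-L kernel `h`:
#' `X[i, j] = x[i - j + 1]` for `i >= j`, 0 otherwise. The first column is
#' `x` itself.
#'
#' @param x Numeric waveform of length N.
#' @param L Kernel length (N >= L).
#' @return The N x L convolution matrix.
#' @export
build_convolution_matrix <- function(x, L) {
  N <- length(x)
  if (N < L) stop("waveform shorter than kernel length")
  X <- matrix(0, N, L)
  for (j in seq_len(L)) X[j:N, j] <- x[seq_len(N - j + 1)]
  X
}

#' Estimate the per-electrode impulse response (kernel)
#'
#' Least-squares solve of `X h = y`, where `X` is the convolution matrix
#' of the baseline waveform `x` and `y` the relocated waveform. When the
#' normal-equation matrix is ill-conditioned (condition number above
#' `cond_threshold`) the ridge-regularized pseudoinverse
#' `(X'X + delta I)^-1 X' y` with `delta = 0.01` is used instead.
#' Deterministic.
#'
#' @param x,y Baseline and transformed waveforms (equal length N >= L).
#' @param L Kernel length (default 25).
#' @param ridge_delta Ridge constant for ill-conditioned systems.
#' @param cond_threshold Condition-number threshold on `X'X`.
#' @return An `ais_kernel`: `h` (length L), `L`, and a `ridge` flag.
#' @export
estimate_kernel <- function(x, y, L = 25, ridge_delta = 0.01,
                            cond_threshold = 1e8) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (all(x == 0)) stop("singular input: baseline waveform is all zero")
  X <- build_convolution_matrix(x, L)
  XtX <- crossprod(X)
  cn <- kappa(XtX, exact = FALSE)
  if (is.finite(cn) && cn <= cond_threshold) {
    h <- qr.solve(X, y)
    ridge <- FALSE
  } else {
    h <- solve(XtX + ridge_delta * diag(L), crossprod(X, y))
    ridge <- TRUE
  }
  structure(list(h = as.numeric(h), L = L, ridge = ridge),
            class = "ais_kernel")
}

#' Predict the transformed waveform from a baseline and a kernel
#'
#' @param x Baseline waveform (length >= kernel length).
#' @param k An `ais_kernel` (or bare numeric kernel vector).
#' @return The convolution `X h`, truncated to `length(x)` samples.
#' @export
predict_waveform <- function(x, k) {
  h <- if (inherits(k, "ais_kernel")) k$h else as.numeric(k)
  as.numeric(build_convolution_matrix(x, length(h)) %*% h)
}

#' Normalized RMS error between estimated and actual waveforms
#'
#' RMS of the residual divided by the range of the estimated waveform:
#' `E = sqrt(mean((yhat - y)^2)) / (max(yhat) - min(yhat))`. A flat
#' estimate (zero range) is undefined and returns `NA` flagged with
#' `attr(, "flat")`.
#'
#' @param yhat,y Estimated and actual waveforms.
#' @return Scalar error `E` (dimensionless).
#' @export
normalized_rms_error <- function(yhat, y) {
  rng <- max(yhat) - min(yhat)
  if (rng <= 0) return(structure(NA_real_, flat = TRUE))
  sqrt(mean((yhat - y)^2)) / rng
}

#' Compile the kernel library from a simulated family
#'
#' For every (offset, rotation) group and every AIS position in the
#' family, a kernel is fit per selected electrode mapping the baseline
#' (d_ais = 5 um) waveform to the relocated waveform at the same
#' electrode. Kernels are stored per offset; queries average errors over
#' offsets.
#'
#' @param family An `ais_family` from [run_family()] (must contain the
#'   5 um baseline for every group).
#' @param L Kernel length (default 25).
#' @return A `kernel_library` keyed by (offset, theta, d_ais, electrode).
#' @export
build_kernel_library <- function(family, L = 25) {
  stopifnot(inherits(family, "ais_family"))
  d_grid <- as.numeric(names(family$groups[[1]]$comparisons))
  missing_base <- vapply(family$groups, function(g)
    !("5" %in% names(g$comparisons)), logical(1))
  if (any(missing_base))
    stop("build error: groups without the 5 um baseline: ",
         paste(which(missing_base), collapse = ", "))
  thetas <- sort(unique(vapply(family$groups, `[[`, numeric(1), "theta")))
  offsets <- unique(t(vapply(family$groups, function(g) as.numeric(g$offset),
                             numeric(2))))
  entries <- lapply(family$groups, function(g) {
    Xb <- g$baseline$w                       # N x M
    ks <- lapply(as.list(names(g$comparisons)), function(dn) {
      Yw <- g$comparisons[[dn]]$w
      H <- vapply(seq_len(ncol(Xb)), function(m)
        estimate_kernel(Xb[, m], Yw[, m], L = L)$h, numeric(L))
      H                                      # L x M
    })
    names(ks) <- names(g$comparisons)
    list(offset = as.numeric(g$offset), theta = g$theta, kernels = ks)
  })
  structure(list(entries = entries, d_grid = sort(d_grid), thetas = thetas,
                 offsets = offsets, L = L, M = family$n_electrodes,
                 baseline_d = family$baseline_d, profile = family$profile),
            class = "kernel_library")
}

#' @export
print.kernel_library <- function(x, ...) {
  cat(sprintf("<kernel_library> L = %d, %d electrodes x %d AIS positions x %d angles x %d offsets\n",
              x$L, x$M, length(x$d_grid), length(x$thetas),
              nrow(x$offsets)))
  invisible(x)
}

# per-(entry, d): error of predicting y_t from x_t with every stored
# kernel; returns the per-library-electrode error vector
errors_against_entry <- function(Xt, y_t, H) {
  P <- Xt %*% H                              # N x M predictions
  rng <- apply(P, 2, max) - apply(P, 2, min)
  res <- sqrt(colMeans((P - y_t)^2))
  ifelse(rng > 0, res / rng, Inf)
}

#' Match a library electrode to a target waveform pair
#'
#' Searches the kernel library over all electrodes and rotation angles
#' (at the given AIS position) for the kernel that best predicts
#' `y_target` from `x_target` in normalized RMS error.
#'
#' @param lib A `kernel_library`.
#' @param x_target,y_target Baseline and relocated waveforms at one
#'   target electrode.
#' @param d_ais Candidate AIS position (must be on the library grid).
#' @return List with `m_star` (library electrode index), `theta`,
#'   `offset`, and the error `E`.
#' @export
match_electrode <- function(lib, x_target, y_target, d_ais) {
  dn <- as.character(d_ais)
  Xt <- build_convolution_matrix(x_target, lib$L)
  best <- list(E = Inf, m_star = NA_integer_, theta = NA_real_,
               offset = c(NA, NA))
  for (en in lib$entries) {
    H <- en$kernels[[dn]]
    if (is.null(H)) next
    E <- errors_against_entry(Xt, y_target, H)
    j <- which.min(E)
    if (E[j] < best$E)
      best <- list(E = E[j], m_star = j, theta = en$theta,
                   offset = en$offset)
  }
  if (!is.finite(best$E) && is.na(best$m_star))
    stop("d_ais not on the library grid: ", d_ais)
  best
}

#' Estimate the AIS position of a footprint pair from the kernel library
#'
#' For every candidate AIS position on the library grid, each target
#' electrode is matched to the library electrode whose kernel best
#' predicts the relocated waveform from the baseline waveform; the
#' normalized RMS errors of the matched kernels are averaged over the M
#' target electrodes (and over library offsets), and minimized over
#' rotation angles, giving the error curve E(d_ais). A cubic polynomial
#' is fit to the curve and the estimate is the minimizing position of the
#' fit, clamped to the tested interval. An error curve without an
#' interior minimum returns the boundary estimate with a `non_convex`
#' flag.
#'
#' @param lib A `kernel_library`.
#' @param baseline_fp,relocated_fp N x M waveform matrices (columns =
#'   the M selected electrodes, shared ordering), e.g. `g$baseline$w`
#'   from a family group or `t(fp$waveforms[ids, ])`.
#' @param offset_mode How to combine library entries across soma
#'   offsets at each (d_ais, theta): `"average"` (default; robust for
#'   targets whose alignment to the lattice is unknown) or `"min"`
#'   (offset-matched queries, e.g. self-consistency checks).
#' @param rank_window Electrode matching is restricted to library
#'   electrodes whose latency rank lies within `rank_window` of the
#'   target electrode's rank (default 5). Both footprints order their
#'   electrodes by latency, so ranks correspond approximately across
#'   morphologies; the restriction keeps a coarse (reduced-resolution)
#'   library from matching spuriously well at wrong AIS positions. Use
#'   `Inf` for the unrestricted search.
#' @return A `position_estimate`: `d_hat` (um), `error_curve`
#'   (data.frame d_ais, E), `fit` (cubic coefficients), `non_convex`
#'   flag, and the per-candidate matching details.
#' @export
estimate_ais_position <- function(lib, baseline_fp, relocated_fp,
                                  offset_mode = c("average", "min"),
                                  rank_window = 5) {
  offset_mode <- match.arg(offset_mode)
  agg <- if (offset_mode == "average") mean else min
  if (!identical(dim(baseline_fp), dim(relocated_fp)))
    stop("footprint pair must share electrode ordering and length")
  M <- ncol(baseline_fp)
  Xts <- lapply(seq_len(M), function(m)
    build_convolution_matrix(baseline_fp[, m], lib$L))

  d_grid <- lib$d_grid
  curve <- numeric(length(d_grid))
  for (di in seq_along(d_grid)) {
    dn <- as.character(d_grid[di])
    # per entry (theta, offset): mean over target electrodes of the best
    # rank-windowed library kernel's error (Eq. 4 matching per entry);
    # offsets aggregated per theta, then minimized over theta (Eq. 5)
    matched <- numeric(); thetas <- numeric()
    for (en in lib$entries) {
      H <- en$kernels[[dn]]
      if (is.null(H)) next  # placement dropped for this entry
      Ml <- ncol(H)
      e_m <- vapply(seq_len(M), function(m) {
        cols <- which(abs(seq_len(Ml) - m) <= rank_window)
        min(errors_against_entry(Xts[[m]], relocated_fp[, m],
                                 H[, cols, drop = FALSE]))
      }, numeric(1))
      matched[length(matched) + 1L] <- mean(e_m)
      thetas[length(matched)] <- en$theta
    }
    curve[di] <- min(vapply(split(matched, thetas), agg, numeric(1)))
  }

  fit <- lm(E ~ poly(d, 3, raw = TRUE),
            data = data.frame(d = d_grid, E = curve))
  cf <- coef(fit)                      # c0 + c1 d + c2 d^2 + c3 d^3
  # stationary points of the cubic
  disc_roots <- if (abs(cf[4]) > 1e-12) {
    disc <- (2 * cf[3])^2 - 4 * 3 * cf[4] * cf[2]
    if (disc >= 0) (-2 * cf[3] + c(-1, 1) * sqrt(disc)) / (2 * 3 * cf[4])
    else numeric(0)
  } else if (abs(cf[3]) > 1e-12) -cf[2] / (2 * cf[3]) else numeric(0)
  cubic <- function(d) cf[1] + cf[2] * d + cf[3] * d^2 + cf[4] * d^3
  interior <- disc_roots[disc_roots > min(d_grid) & disc_roots < max(d_grid)]
  interior <- interior[6 * cf[4] * interior + 2 * cf[3] > 0]  # minima only
  cand <- c(interior, range(d_grid))
  d_hat <- cand[which.min(cubic(cand))]
  structure(list(d_hat = unname(d_hat),
                 error_curve = data.frame(d_ais = d_grid, E = curve),
                 fit = unname(cf),
                 non_convex = length(interior) == 0),
            class = "position_estimate")
}

#' @export
print.position_estimate <- function(x, ...) {
  cat(sprintf("<position_estimate> d_hat = %.2f um%s\n", x$d_hat,
              if (x$non_convex) " [non-convex error curve: boundary estimate]"
              else ""))
  invisible(x)
}
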