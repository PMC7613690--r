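#' Cut out the spike-aligned extracellular footprint
#'
#' Finds the electrode registering the earliest signal trough (below the
#' detection floor), computes a cutout window from that electrode's trough
#' sample and applies the same indices to every electrode. The window holds
#' one third of its samples before the anchor trough and two thirds after:
#' 96 samples (3 ms at 32 kHz) for the ball-and-stick profile, 177 samples
#' (ca. 5.5 ms) for the detailed profile.
#'
#' @param sim A `sim_result` from [simulate_neuron()], or any list with an
#'   `extracellular` matrix (electrodes x samples, uV) and `fs` (Hz).
#' @param profile `"bas"` (96 samples) or `"detailed"` (177 samples).
#' @param detection_floor Troughs above this value (uV) are ignored.
#' @return A `footprint`: `waveforms` (electrodes x N), `electrode_ids`,
#'   `fs`, `cutout_indices` (start, end), `anchor` (sample index of the
#'   earliest trough inside the cutout).
#' @export
extract_footprint <- function(sim, profile = c("bas", "detailed"),
                              detection_floor = -30) {
  profile <- match.arg(profile)
  V <- sim$extracellular
  fs <- sim$fs
  N <- if (profile == "bas") 96L else 177L
  n_samp <- ncol(V)
  if (n_samp < N) stop("trace shorter than the cutout window")

  col_min <- apply(V, 2, min)
  t_first <- which(col_min < detection_floor)[1]
  if (is.na(t_first)) stop("no spike: no trough below the detection floor")

  # restrict the trough search to the first spike
  region <- t_first:min(n_samp, t_first + round(2e-3 * fs))
  sub <- V[, region, drop = FALSE]
  trough_val <- apply(sub, 1, min)
  trough_rel <- apply(sub, 1, which.min)
  supra <- trough_val < detection_floor
  anchor_abs <- min(region[trough_rel[supra]])

  pre <- floor(N / 3)
  start <- anchor_abs - pre
  if (start < 1) start <- 1L
  if (start + N - 1 > n_samp) start <- n_samp - N + 1L
  idx <- start:(start + N - 1L)
  structure(list(waveforms = V[, idx, drop = FALSE],
                 electrode_ids = seq_len(nrow(V)),
                 fs = fs,
                 cutout_indices = c(start, start + N - 1L),
                 anchor = anchor_abs - start + 1L,
                 detection_floor = detection_floor,
                 profile = profile),
            class = "footprint")
}

# trough amplitude relative to the pre-spike baseline (mean of the first
# 10 samples of the cutout)
trough_amplitudes <- function(fp) {
  W <- fp$waveforms
  base <- rowMeans(W[, 1:10, drop = FALSE])
  apply(W, 1, min) - base
}

#' Select and order footprint electrodes
#'
#' The `n` electrodes with the largest trough amplitudes (absolute value)
#' are selected, then sorted by trough latency ascending, so that
#' electrodes near the AIS come first. Latency ties are broken by deeper
#' trough amplitude, then by lower electrode id.
#'
#' @param fp A [extract_footprint()] result.
#' @param n Number of electrodes to keep (default 26).
#' @return Integer vector of `n` electrode ids, latency-ordered.
#' @export
select_and_order_electrodes <- function(fp, n = 26) {
  if (nrow(fp$waveforms) < n)
    stop("footprint has fewer than ", n, " electrodes")
  amp <- trough_amplitudes(fp)
  top <- order(amp)[seq_len(n)]           # most negative first
  tr <- apply(fp$waveforms[top, , drop = FALSE], 1, which.min)
  ord <- order(tr, amp[top], top)          # latency, deeper amp, lower id
  fp$electrode_ids[top[ord]]
}

#' Per-electrode waveform features
#'
#' For each electrode (in the given order) the features are: trough
#' amplitude (uV, relative to the pre-spike baseline, always <= 0 for
#' spiking electrodes), latency to the footprint's earliest trough (ms),
#' half-width at half trough amplitude (ms), peak-to-peak amplitude (uV)
#' and the waveform slopes (uV/ms) at the two half-amplitude crossings
#' (falling into and rising out of the trough). Waveforms that never
#' recross half amplitude inside the window get `half_width` equal to the
#' window length and are flagged.
#'
#' @param fp A [extract_footprint()] result.
#' @param order Electrode ids from [select_and_order_electrodes()].
#' @return data.frame with columns `electrode`, `amp`, `latency`,
#'   `half_width`, `p2p`, `slope_fall`, `slope_rise`, `hw_flagged`.
#' @export
compute_features <- function(fp, order) {
  W <- fp$waveforms
  fs_ms <- fp$fs / 1000          # samples per ms
  N <- ncol(W)
  out <- lapply(order, function(e) {
    w <- W[match(e, fp$electrode_ids), ]
    base <- mean(w[1:10])
    tt <- which.min(w)
    amp <- w[tt] - base
    latency <- max(0, (tt - fp$anchor)) / fs_ms
    half <- base + amp / 2
    flag <- FALSE
    left <- which(w[seq_len(max(tt - 1, 1))] > half)
    right <- which(w[tt:N] > half)
    if (length(left) == 0 || length(right) == 0) {
      hw <- N / fs_ms; flag <- TRUE
      sf <- NA_real_; sr <- NA_real_
      i1 <- max(tt - 1, 1); i2 <- min(tt + 1, N)
    } else {
      i1 <- max(left)                       # last sample above half, pre-trough
      i2 <- tt + min(right) - 1L            # first sample above half, post-trough
      f1 <- (w[i1] - half) / (w[i1] - w[i1 + 1])
      f2 <- (half - w[i2 - 1]) / (w[i2] - w[i2 - 1])
      hw <- ((i2 - 1 + f2) - (i1 + f1)) / fs_ms
      sf <- (w[i1 + 1] - w[i1]) * fs_ms     # falling edge, uV/ms
      sr <- (w[i2] - w[i2 - 1]) * fs_ms     # rising edge
    }
    data.frame(electrode = e, amp = amp, latency = latency,
               half_width = hw, p2p = max(w) - min(w),
               slope_fall = sf, slope_rise = sr, hw_flagged = flag)
  })
  do.call(rbind, out)
}

#' Assemble the labeled delta-feature / sham dataset
#'
#' For every (offset, rotation) group in a simulated family, the feature
#' vector of each comparison footprint (electrode-id-wise, in the baseline
#' latency ordering) is subtracted from the baseline (d_ais = 5 um)
#' footprint's features, giving one valid vector per pair labeled with its
#' relocation magnitude (d_ais - 5 um). For each valid vector,
#' `sham_ratio` sham vectors are built by independently permuting the 26
#' electrode slots of each comparison feature (seeded; identity
#' permutations are redrawn) before subtraction; shams carry no magnitude
#' and are labeled invalid.
#'
#' @param family An `ais_family` from [run_family()].
#' @param feature_set Character vector of feature columns to use.
#' @param sham_ratio Integer; shams per valid vector (default 1).
#' @param seed Seed for the sham permutations.
#' @return List with `X` (rows = vectors, columns = M x features),
#'   `valid` (logical), `magnitude` (um, `NA` for shams), `group`
#'   (offset/theta/d_ais bookkeeping) and `feature_names`.
#' @export
build_delta_dataset <- function(family,
                                feature_set = c("amp", "latency",
                                                "half_width", "p2p",
                                                "slope_fall", "slope_rise"),
                                sham_ratio = 1, seed = 1) {
  stopifnot(inherits(family, "ais_family"))
  if (sham_ratio < 0 || sham_ratio != round(sham_ratio))
    stop("sham_ratio must be a nonnegative integer")
  rows <- list(); labels <- logical(); mags <- numeric(); grp <- list()
  with_seed(seed, {
    for (g in family$groups) {
      base_feat <- as.matrix(g$baseline$feat[, feature_set, drop = FALSE])
      M <- nrow(base_feat)
      for (dn in names(g$comparisons)) {
        cmp <- g$comparisons[[dn]]
        if (!identical(cmp$feat$electrode, g$baseline$feat$electrode))
          stop("pairing error: electrode orders differ between baseline and comparison")
        cmp_feat <- as.matrix(cmp$feat[, feature_set, drop = FALSE])
        delta <- cmp_feat - base_feat
        rows[[length(rows) + 1L]] <- as.numeric(delta)
        labels[length(labels) + 1L] <- TRUE
        mags[length(mags) + 1L] <- as.numeric(dn) - family$baseline_d
        grp[[length(grp) + 1L]] <- c(g$offset, g$theta, as.numeric(dn))
        for (s in seq_len(sham_ratio)) {
          shuffled <- apply(cmp_feat, 2, function(col) {
            p <- sample.int(M)
            while (all(p == seq_len(M))) p <- sample.int(M)
            col[p]
          })
          rows[[length(rows) + 1L]] <- as.numeric(shuffled - base_feat)
          labels[length(labels) + 1L] <- FALSE
          mags[length(mags) + 1L] <- NA_real_
          grp[[length(grp) + 1L]] <- c(g$offset, g$theta, as.numeric(dn))
        }
      }
    }
  })
  X <- do.call(rbind, rows)
  M <- nrow(family$groups[[1]]$baseline$feat)
  colnames(X) <- as.vector(outer(seq_len(M), feature_set,
                                 function(i, f) paste0(f, "_e", i)))
  grp <- do.call(rbind, grp)
  colnames(grp) <- c("offset_x", "offset_y", "theta", "d_ais")
  list(X = X, valid = labels, magnitude = mags,
       group = as.data.frame(grp), feature_names = feature_set)
}
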