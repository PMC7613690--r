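#' Run a family of simulations over the (offset, rotation, d_ais) grid
#'
#' Spawns the simulation family a baseline morphology defines: for every
#' AIS position in the grid the cable equations are solved once (rigid
#' placement does not enter the intracellular dynamics), and the
#' extracellular projection is recomputed for every soma offset and
#' rotation. For each (offset, theta) group the baseline footprint
#' (d_ais = 5 um) selects and orders the 26 analysis electrodes; cutout
#' waveforms and features at those electrodes are stored for every AIS
#' position.
#'
#' @param cfg A [sim_config()]. `ais_positions` must include the 5 um
#'   baseline.
#' @param probe An [build_probe()] result.
#' @param morph_builder Optional function `(d_ais) -> ais_morphology`
#'   (biophysics-assigned). Defaults to the profile's builder
#'   (ball-and-stick, or the seeded synthetic detailed morphology).
#' @param n_electrodes Electrodes kept per footprint (default 26).
#' @param progress Print per-position progress.
#' @return An `ais_family`: `groups` is a list over (offset, theta) with
#'   the ordered electrode ids, baseline waveforms/features and per-d_ais
#'   comparison waveforms/features; `stim_amp` records the resolved
#'   stimulus.
#' @export
run_family <- function(cfg, probe = build_probe(), morph_builder = NULL,
                       n_electrodes = 26, progress = FALSE) {
  if (!5 %in% cfg$ais_positions)
    stop("family requires the 5 um baseline AIS position in ais_positions")
  if (is.null(morph_builder)) {
    morph_builder <- if (cfg$profile == "bas") {
      function(d) assign_biophysics(build_ball_and_stick(ais_spec(d)))
    } else {
      function(d) assign_biophysics(
        build_synthetic_detailed(seed = cfg$seed, ais = ais_spec(d)))
    }
  }
  m0 <- morph_builder(5)
  stim <- resolve_stim(m0, cfg)
  angles <- seq(0, 360 - cfg$rotation_step_deg, by = cfg$rotation_step_deg)
  offsets <- cfg$soma_offsets

  # one cable solution per AIS position; local-coordinate compartments
  solutions <- list()
  for (d in cfg$ais_positions) {
    m <- morph_builder(d)
    comps <- morph_to_comps(m)
    sol <- run_cable(comps, cfg, stim)
    solutions[[as.character(d)]] <-
      list(comps = comps, imem = sol$imem, soma_center = m$soma_center)
    if (progress) message("solved d_ais = ", d)
  }

  place_comps <- function(comps, center, offset, theta) {
    P0 <- rotate_z(as.matrix(comps[, c("x0", "y0", "z0")]), theta, center)
    P1 <- rotate_z(as.matrix(comps[, c("x1", "y1", "z1")]), theta, center)
    shift <- c(offset[1], offset[2], cfg$z_height) - center
    comps[, c("x0", "y0", "z0")] <- sweep(P0, 2, shift, `+`)
    comps[, c("x1", "y1", "z1")] <- sweep(P1, 2, shift, `+`)
    comps
  }

  groups <- list()
  dropped <- list()
  for (oi in seq_len(nrow(offsets))) {
    for (th in angles) {
      # placements without a suprathreshold trough are dropped (recorded),
      # as an experimental pipeline would drop undetected units
      per_d <- lapply(solutions, function(sl) {
        pc <- place_comps(sl$comps, sl$soma_center, offsets[oi, ], th)
        G <- gain_matrix(pc, probe$centers, cfg$conductivity_sigma)
        tryCatch(extract_footprint(list(extracellular = G %*% sl$imem,
                                        fs = cfg$fs),
                                   profile = cfg$profile,
                                   detection_floor = cfg$detection_floor),
                 error = function(e) NULL)
      })
      lost <- names(per_d)[vapply(per_d, is.null, logical(1))]
      if (length(lost))
        dropped[[length(dropped) + 1L]] <-
          list(offset = offsets[oi, ], theta = th, d_ais = as.numeric(lost))
      if (is.null(per_d[["5"]])) next  # no baseline, whole group unusable
      per_d <- per_d[!vapply(per_d, is.null, logical(1))]
      base_fp <- per_d[["5"]]
      ids <- select_and_order_electrodes(base_fp, n_electrodes)
      pack <- function(fp) list(
        w = t(fp$waveforms[ids, , drop = FALSE]),   # N x M
        feat = compute_features(fp, ids))
      groups[[length(groups) + 1L]] <- list(
        offset = offsets[oi, ], theta = th, ids = ids,
        baseline = pack(base_fp),
        comparisons = lapply(per_d, pack))
      if (progress) message("placed offset ", oi, ", theta ", th)
    }
  }
  if (length(dropped))
    warning(sum(lengths(lapply(dropped, `[[`, "d_ais"))),
            " placement(s) without suprathreshold troughs were dropped")
  structure(list(cfg = cfg, profile = cfg$profile, stim_amp = stim,
                 baseline_d = 5, n_electrodes = n_electrodes,
                 groups = groups, dropped = dropped),
            class = "ais_family")
}

#' @export
print.ais_family <- function(x, ...) {
  cat(sprintf("<ais_family> %s profile, %d (offset, theta) groups x %d AIS positions, %d electrodes, stim %.2f nA\n",
              x$profile, length(x$groups),
              length(x$groups[[1]]$comparisons), x$n_electrodes, x$stim_amp))
  invisible(x)
}
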