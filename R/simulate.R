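#' Simulation configuration
#'
#' Defines the integration settings, the somatic step stimulus and the
#' simulation grid (soma jitter offsets x rotations x AIS positions).
#' Sampling runs at 32 kHz (dt = 2^-5 ms) for 30 ms, with a 20 ms somatic
#' current step. The soma jitter offsets tile half an electrode pitch
#' (8.75 um), exploiting the periodic symmetry of the array. The full
#' ball-and-stick grid uses 1 degree rotations and 1 um AIS steps over
#' 5..40 um (1,440 placements per AIS position, 36 positions); the full
#' detailed grid uses 5 degree rotations and 2 um steps over 5..39 um
#' (288 placements per position, 18 positions). The reduced grid (15 degree
#' rotations, 5 um AIS steps, 2 offsets) is first-class and sized for
#' desk-scale runs.
#'
#' @param profile `"bas"` (ball-and-stick) or `"detailed"`.
#' @param grid `"full"` or `"reduced"`.
#' @param dt Time step, ms.
#' @param duration Simulated time, ms.
#' @param stim_amplitude Somatic step amplitude, nA, or `NULL` to use
#'   1.5x rheobase found by bisection within `[0.3, 2]` nA.
#' @param stim_duration,stim_start Stimulus timing, ms.
#' @param soma_offsets Matrix/list of in-plane soma offsets (um).
#' @param rotation_step_deg Rotation increment, degrees.
#' @param ais_positions AIS positions d_ais (um).
#' @param conductivity_sigma Extracellular conductivity, S/m.
#' @param z_height Height of the neurite plane above the electrode plane,
#'   um. Adherent neurites in 2D cultures lie within a few um of the
#'   substrate; the default (2.5 um) reproduces the ~100 uV footprint
#'   amplitudes typical of HD-MEA recordings. The spherical soma's
#'   effective distance is bounded below by its radius in the forward
#'   model.
#' @param detection_floor Trough detection floor for footprints, uV.
#' @param seed Base seed for stochastic stages downstream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(profile = c("bas", "detailed"),
                       grid = c("reduced", "full"),
                       dt = 2^-5, duration = 30,
                       stim_amplitude = NULL,
                       stim_duration = 20, stim_start = 2,
                       soma_offsets = NULL,
                       rotation_step_deg = NULL,
                       ais_positions = NULL,
                       conductivity_sigma = 0.3,
                       z_height = 2.5,
                       detection_floor = -30,
                       seed = 1L) {
  profile <- match.arg(profile)
  grid <- match.arg(grid)
  all_offsets <- rbind(c(0, 0), c(8.75, 0), c(0, 8.75), c(8.75, 8.75))
  if (is.null(soma_offsets))
    soma_offsets <- if (grid == "full") all_offsets else all_offsets[1:2, , drop = FALSE]
  if (is.null(rotation_step_deg))
    rotation_step_deg <- if (grid == "reduced") 15 else
      if (profile == "bas") 1 else 5
  if (is.null(ais_positions))
    ais_positions <- if (grid == "reduced") seq(5, 40, by = 5) else
      if (profile == "bas") 5:40 else seq(5, 39, by = 2)
  if (!is.null(stim_amplitude) &&
      (stim_amplitude < 0.3 || stim_amplitude > 2))
    stop("stim_amplitude must lie in [0.3, 2] nA")
  structure(list(profile = profile, grid = grid, dt = dt,
                 duration = duration, stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, stim_start = stim_start,
                 soma_offsets = as.matrix(soma_offsets),
                 rotation_step_deg = rotation_step_deg,
                 ais_positions = ais_positions,
                 conductivity_sigma = conductivity_sigma,
                 z_height = z_height, detection_floor = detection_floor,
                 cutout_n = if (profile == "bas") 96L else 177L,
                 fs = 1000 / dt, seed = seed),
            class = "sim_config")
}

#' Enumerate the simulation grid
#'
#' Full Cartesian product of soma offsets, rotation angles and AIS
#' positions, in deterministic lexicographic order (offset, angle, d_ais).
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `offset_x`, `offset_y`, `theta`,
#'   `d_ais`.
#' @examples
#' nrow(enumerate_grid(sim_config("bas", "full")))  # 51840
#' @export
enumerate_grid <- function(cfg) {
  angles <- seq(0, 360 - cfg$rotation_step_deg, by = cfg$rotation_step_deg)
  off <- cfg$soma_offsets
  out <- expand.grid(d_ais = cfg$ais_positions, theta = angles,
                     offset = seq_len(nrow(off)))
  data.frame(offset_x = off[out$offset, 1], offset_y = off[out$offset, 2],
             theta = out$theta, d_ais = out$d_ais)[
               order(out$offset, out$theta, out$d_ais), ] -> res
  rownames(res) <- NULL
  res
}

#' Rigidly place a morphology over the probe
#'
#' Rotates the neuron about the vertical axis through the soma center by
#' `theta` degrees, then translates it so the soma center sits at
#' `(offset_x, offset_y, z)`. z coordinates (relative to the soma plane)
#' are unchanged by the rotation.
#'
#' @param m An `ais_morphology`.
#' @param offset Length-2 in-plane offset, um.
#' @param theta Rotation, degrees in `[0, 360)`.
#' @param z Height of the soma center above the electrode plane, um.
#' @return The placed `ais_morphology`.
#' @export
rotate_and_place <- function(m, offset = c(0, 0), theta = 0, z = 2.5) {
  ctr <- m$soma_center
  shift <- c(offset[1], offset[2], z) - ctr
  m$sections <- lapply(m$sections, function(s) {
    s$points <- sweep(rotate_z(s$points, theta, ctr), 2, shift, `+`)
    s
  })
  m$soma_center <- ctr + shift
  m$axon_orientation_deg <- (m$axon_orientation_deg + theta) %% 360
  m
}

# ---- volume-conductor forward model ----------------------------------------

#' Extracellular gain matrix (line/point source)
#'
#' Potential per unit membrane current at every electrode for every
#' compartment, under a homogeneous, isotropic volume conductor of
#' conductivity `sigma`. Cylindrical compartments use the analytic
#' line-source integral; the spherical soma uses a point source. The
#' radial distance is clamped at the compartment radius to avoid the
#' line/point singularity.
#'
#' @param comps Compartment table from the morphology (internal layout).
#' @param electrodes data.frame with `x`, `y`, `z` electrode centers (um).
#' @param sigma Conductivity, S/m.
#' @return Matrix `n_electrodes x n_compartments`, in uV/nA.
#' @export
gain_matrix <- function(comps, electrodes, sigma = 0.3) {
  ne <- nrow(electrodes); nc <- nrow(comps)
  G <- matrix(0, ne, nc)
  ex <- electrodes$x; ey <- electrodes$y; ez <- electrodes$z
  k <- 1000 / (4 * pi * sigma)  # uV um / nA
  for (j in seq_len(nc)) {
    p0 <- c(comps$x0[j], comps$y0[j], comps$z0[j])
    p1 <- c(comps$x1[j], comps$y1[j], comps$z1[j])
    L <- sqrt(sum((p1 - p0)^2))
    if (comps$tag[j] == "soma" || L < 1e-9) {
      r <- sqrt((ex - p0[1])^2 + (ey - p0[2])^2 + (ez - p0[3])^2)
      r <- pmax(r, comps$radius[j])
      G[, j] <- k / r
    } else {
      u <- (p1 - p0) / L
      ax <- ex - p0[1]; ay <- ey - p0[2]; az <- ez - p0[3]
      t <- ax * u[1] + ay * u[2] + az * u[3]
      rho2 <- pmax(ax^2 + ay^2 + az^2 - t^2, comps$radius[j]^2)
      num <- (L - t) + sqrt((L - t)^2 + rho2)
      den <- (-t) + sqrt(t^2 + rho2)
      G[, j] <- k / L * log(num / den)
    }
  }
  G
}

# run the compiled cable solver on a compartment table
run_cable <- function(comps, cfg, stim_amp) {
  pp <- attr(comps, "passive")
  dist <- attr(comps, "dist")
  n_steps <- round(cfg$duration / cfg$dt)
  res <- cable_solve_cpp(
    parent = as.integer(comps$parent) - 1L,
    cm_nF = comps$cm_nF,
    g_na_uS = comps$g_na, g_k_uS = comps$g_k, g_kv7_uS = comps$g_kv7,
    g_leak_uS = comps$g_leak,
    e_na = dist$e_na, e_k = dist$e_k, e_leak = pp$e_leak,
    r_axial_MOhm = ifelse(is.na(comps$r_axial), 0, comps$r_axial),
    v_init = -75,
    stim_comp = which(comps$tag == "soma")[1] - 1L,
    stim_amp_nA = stim_amp,
    stim_start_ms = cfg$stim_start, stim_dur_ms = cfg$stim_duration,
    dt_ms = cfg$dt, n_steps = n_steps, phi = pp$phi)
  res
}

# regenerative spike at the AIS: the trace crosses 0 mV during the
# stimulus and repolarizes below -30 mV within 3 ms of the crossing.
# A passive membrane charged past 0 mV by a strong step stays depolarized
# (no repolarization while the stimulus is on), so it is not flagged.
has_spike <- function(v_ais, dt, stim_start, stim_dur) {
  n <- length(v_ais)
  t <- (seq_len(n) - 1) * dt
  over <- which(v_ais > 0 & t >= stim_start & t <= stim_start + stim_dur)
  if (length(over) == 0) return(FALSE)
  i0 <- over[1]
  j <- i0:min(n, i0 + round(3 / dt))
  min(v_ais[j]) < -30
}

#' Find the rheobase of a model by bisection
#'
#' Smallest somatic step amplitude within `[0.3, 2]` nA that evokes a
#' regenerative action potential at the AIS (a 0 mV crossing during the
#' stimulus followed by repolarization below -30 mV within 3 ms), to a
#' tolerance of 0.05 nA.
#'
#' @param m A biophysics-assigned `ais_morphology`.
#' @param cfg A [sim_config()].
#' @return Rheobase in nA, or `NA` if 2 nA is still subthreshold.
#' @export
find_rheobase <- function(m, cfg = sim_config()) {
  comps <- morph_to_comps(m)
  ais_idx <- which(comps$tag == "ais")
  mid <- ais_idx[ceiling(length(ais_idx) / 2)]
  spikes_at <- function(a) {
    v <- run_cable(comps, cfg, a)$v[mid, ]
    has_spike(v, cfg$dt, cfg$stim_start, cfg$stim_duration)
  }
  lo <- 0.3; hi <- 2
  if (spikes_at(lo)) return(lo)
  if (!spikes_at(hi)) return(NA_real_)
  while (hi - lo > 0.05) {
    mid_a <- (lo + hi) / 2
    if (spikes_at(mid_a)) hi <- mid_a else lo <- mid_a
  }
  hi
}

# resolve the stimulus amplitude for a model under a config
resolve_stim <- function(m, cfg) {
  if (!is.null(cfg$stim_amplitude)) return(cfg$stim_amplitude)
  rb <- find_rheobase(m, cfg)
  if (is.na(rb)) return(2)  # run at ceiling; flagged subthreshold downstream
  min(max(1.5 * rb, 0.3), 2)
}

#' Simulate one placement: cable dynamics + extracellular potentials
#'
#' Solves the multi-compartment cable equations for a somatic current step
#' and superposes each compartment's transmembrane current under the
#' homogeneous-medium forward model (line source for cylinders, point
#' source for the soma) at every electrode.
#'
#' @param m A biophysics-assigned `ais_morphology` in local coordinates.
#' @param probe An [build_probe()] result.
#' @param cfg A [sim_config()].
#' @param offset,theta Placement (um, degrees); see [rotate_and_place()].
#' @param stim_amp Stimulus amplitude, nA; `NULL` resolves via rheobase.
#' @return A `sim_result` with `vm` (compartments x samples, mV),
#'   `extracellular` (electrodes x samples, uV), `comps`, `t` (ms) and
#'   `metadata` (placement, d_ais, stimulus, `subthreshold` flag).
#' @export
simulate_neuron <- function(m, probe, cfg = sim_config(),
                            offset = c(0, 0), theta = 0, stim_amp = NULL) {
  if (is.null(m$biophys)) stop("assign_biophysics() first")
  if (is.null(stim_amp)) stim_amp <- resolve_stim(m, cfg)
  placed <- rotate_and_place(m, offset, theta, z = cfg$z_height)
  comps <- morph_to_comps(placed)
  sol <- run_cable(comps, cfg, stim_amp)
  G <- gain_matrix(comps, probe$centers, cfg$conductivity_sigma)
  extra <- G %*% sol$imem
  ais_idx <- which(comps$tag == "ais")
  mid <- ais_idx[ceiling(length(ais_idx) / 2)]
  sub <- !has_spike(sol$v[mid, ], cfg$dt, cfg$stim_start, cfg$stim_duration)
  structure(list(vm = sol$v, imem = sol$imem, extracellular = extra,
                 comps = comps, t = seq(0, by = cfg$dt,
                                        length.out = ncol(sol$v)),
                 fs = cfg$fs,
                 metadata = list(offset = offset, theta = theta,
                                 d_ais = m$d_ais, model = m$model,
                                 stim_amp = stim_amp, subthreshold = sub)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s model, d_ais = %s um, theta = %.1f deg, %d comps, %d electrodes x %d samples%s\n",
              x$metadata$model, format(x$metadata$d_ais), x$metadata$theta,
              nrow(x$vm), nrow(x$extracellular), ncol(x$extracellular),
              if (x$metadata$subthreshold) " [subthreshold]" else ""))
  invisible(x)
}
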