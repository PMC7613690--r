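test_that("grid enumeration matches the full-scale simulation-family sizes", {
  g_bas <- enumerate_grid(sim_config("bas", "full"))
  expect_equal(sum(g_bas$d_ais == 5), 1440)          # 4 offsets x 360 angles
  expect_equal(length(unique(g_bas$d_ais)), 36)
  expect_equal(nrow(g_bas), 51840)
  g_det <- enumerate_grid(sim_config("detailed", "full"))
  expect_equal(sum(g_det$d_ais == 5), 288)           # 4 offsets x 72 angles
  expect_equal(length(unique(g_det$d_ais)), 18)
  # degenerate single-placement grid
  g1 <- enumerate_grid(sim_config("bas", soma_offsets = matrix(c(0, 0), 1),
                                  rotation_step_deg = 360,
                                  ais_positions = 5))
  expect_equal(nrow(g1), 1)
})

test_that("point-source gain matches the closed-form 1/(4 pi sigma r)", {
  comps <- data.frame(x0 = 0, y0 = 0, z0 = 10, x1 = 0, y1 = 0, z1 = 10,
                      radius = 1, length = 0, area = 1, tag = "soma",
                      parent = 0)
  el <- data.frame(x = c(0, 30), y = 0, z = 0)
  G <- gain_matrix(comps, el, sigma = 0.3)
  r <- c(10, sqrt(30^2 + 10^2))
  expect_equal(as.numeric(G), 1000 / (4 * pi * 0.3 * r), tolerance = 1e-12)
})

test_that("line-source gain approaches the point source far away", {
  comps <- data.frame(x0 = -1, y0 = 0, z0 = 0, x1 = 1, y1 = 0, z1 = 0,
                      radius = 0.5, length = 2, area = 1, tag = "axon",
                      parent = 1)
  el <- data.frame(x = 5, y = 0, z = 300)
  G <- gain_matrix(comps, el, sigma = 0.3)
  expect_equal(as.numeric(G), 1000 / (4 * pi * 0.3 * sqrt(5^2 + 300^2)),
               tolerance = 1e-3)
})

test_that("rigid placement behaves as a rotation group action", {
  m <- build_ball_and_stick(ais_spec(12))
  pts <- function(x) do.call(rbind, lapply(x$sections, `[[`, "points"))
  # identity
  m0 <- rotate_and_place(m, c(0, 0), 0, z = 0)
  expect_equal(pts(m0), pts(m), tolerance = 1e-12)
  # composing rotations that sum to 360 degrees returns the original
  m1 <- rotate_and_place(rotate_and_place(m, c(0, 0), 123.4, z = 0),
                         c(0, 0), 236.6, z = 0)
  expect_equal(pts(m1), pts(m), tolerance = 1e-9)
  # 30 degrees moves the distal axon tip to the hand-rotated location
  m30 <- rotate_and_place(m, c(0, 0), 30, z = 0)
  tip <- pts(m)[nrow(pts(m)), ]
  th <- 30 * pi / 180
  expected <- c(cos(th) * tip[1] - sin(th) * tip[2],
                sin(th) * tip[1] + cos(th) * tip[2], tip[3])
  expect_equal(unname(pts(m30)[nrow(pts(m30)), ]), unname(expected),
               tolerance = 1e-9)
})

test_that("transmembrane currents sum to zero at every time step", {
  sim <- default_sim()
  expect_lt(max(abs(colSums(sim$imem))), 1e-10)
})

test_that("the AP initiates at the AIS and back-propagates", {
  sim <- default_sim()
  comps <- sim$comps
  ais <- which(comps$tag == "ais")
  mid <- ais[ceiling(length(ais) / 2)]
  soma <- which(comps$tag == "soma")[1]
  dend <- which(comps$tag == "dend")[3]
  distal <- max(ais) + 3                       # just beyond the AIS
  t_peak <- function(i) which.max(sim$vm[i, ])
  expect_lt(t_peak(mid), t_peak(soma))
  expect_lt(t_peak(mid), t_peak(dend))
  expect_lt(t_peak(mid), t_peak(distal))
})

test_that("peak depolarization rate at the AIS far exceeds the soma's", {
  sim <- default_sim()
  comps <- sim$comps
  ais <- which(comps$tag == "ais")
  mid <- ais[ceiling(length(ais) / 2)]
  soma <- which(comps$tag == "soma")[1]
  dt <- diff(sim$t[1:2])
  ratio <- max(diff(sim$vm[mid, ])) / max(diff(sim$vm[soma, ]))
  expect_gt(ratio, 2)
  expect_gt(max(diff(sim$vm[mid, ])) / dt, 300)  # a genuine AP upstroke
})

test_that("a passive membrane shows no regenerative event", {
  passive <- channel_distribution(
    soma = c(g_na = 0, g_k = 0, g_kv7 = 0),
    ais = c(g_na = 1e-9, g_k = 1e-9, g_kv7 = 0),
    dend = c(g_na = 0, g_k = 0, g_kv7 = 0),
    hillock = c(g_na = 0, g_k = 0, g_kv7 = 0),
    axon = c(g_na = 0, g_k = 0, g_kv7 = 0))
  m <- assign_biophysics(build_ball_and_stick(ais_spec(15)), passive)
  cfg <- sim_config("bas", "reduced")
  s1 <- simulate_neuron(m, build_probe(12, 12), cfg, stim_amp = 0.3)
  expect_true(s1$metadata$subthreshold)
  expect_lt(max(s1$vm), 0)                    # 0.3 nA stays subthreshold
  # exact superposition of a linear membrane: v(2A) - 2 v(A) + v(0) = 0
  # (an active cell violates this grossly)
  s2 <- simulate_neuron(m, build_probe(12, 12), cfg, stim_amp = 0.6)
  s0 <- simulate_neuron(m, build_probe(12, 12), cfg, stim_amp = 0)
  expect_lt(max(abs(s2$vm - 2 * s1$vm + s0$vm)), 1e-6)
})

test_that("the earliest extracellular trough tracks the AIS", {
  sim <- default_sim()
  probe <- build_probe()
  comps <- sim$comps
  ais <- which(comps$tag == "ais")
  mid <- ais[ceiling(length(ais) / 2)]
  ais_xy <- c((comps$x0[mid] + comps$x1[mid]) / 2,
              (comps$y0[mid] + comps$y1[mid]) / 2)
  fp <- extract_footprint(sim, "bas")
  supra <- apply(fp$waveforms, 1, min) < -30
  tr <- apply(fp$waveforms, 1, which.min)
  e_first <- which(supra)[which.min(tr[supra])]
  d <- sqrt((probe$centers$x[e_first] - ais_xy[1])^2 +
              (probe$centers$y[e_first] - ais_xy[2])^2)
  expect_lt(d, 2 * probe$pitch)
})

test_that("the earliest-trough electrode moves monotonically with d_ais", {
  probe <- build_probe()
  cfg <- sim_config("bas", "reduced")
  proj <- vapply(seq(5, 40, by = 5), function(d) {
    m <- assign_biophysics(build_ball_and_stick(ais_spec(d)))
    sim <- simulate_neuron(m, probe, cfg, theta = 0, stim_amp = 0.45)
    fp <- extract_footprint(sim, "bas")
    supra <- apply(fp$waveforms, 1, min) < -30
    tr <- apply(fp$waveforms, 1, which.min)
    e <- which(supra)[which.min(tr[supra])]
    probe$centers$x[e]                        # axon points along +x at theta 0
  }, numeric(1))
  # non-decreasing within half-pitch lattice quantization
  expect_true(all(diff(proj) > -probe$pitch / 2))
  expect_gt(proj[8], proj[1])                 # net distal movement
})
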