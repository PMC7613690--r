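test_that("ball-and-stick geometry follows the model specification", {
  m <- build_ball_and_stick(ais_spec(5))
  len <- section_lengths(m)
  expect_equal(unname(len["dend"]), 1000)
  # axon pieces (pre + AIS + post) sum to the full 1 mm axon
  expect_equal(unname(len["ais"] + len["axon"]), 1000)
  expect_equal(unname(len["ais"]), 30)
  soma <- m$sections[[1]]
  expect_equal(soma$radii[1], 8)  # 16 um diameter

  # AIS span: proximal end at d_ais from the soma surface
  ais_sec <- m$sections[[which(vapply(m$sections, `[[`, "", "tag") == "ais")]]
  d_start <- sqrt(sum((ais_sec$points[1, ] - c(8, 0, 0))^2))
  expect_equal(d_start, 5)
  m40 <- build_ball_and_stick(ais_spec(40))
  ais40 <- m40$sections[[which(vapply(m40$sections, `[[`, "", "tag") == "ais")]]
  expect_equal(sqrt(sum((ais40$points[1, ] - c(8, 0, 0))^2)), 40)
  expect_equal(sqrt(sum((ais40$points[nrow(ais40$points), ] - c(8, 0, 0))^2)), 70)
})

test_that("moving the AIS relabels a sub-span without changing cable length", {
  lens <- vapply(c(5, 17, 28, 40), function(d) {
    sum(section_lengths(build_ball_and_stick(ais_spec(d))))
  }, numeric(1))
  expect_true(all(abs(lens - lens[1]) < 1e-9))
  # radii are unchanged too
  for (d in c(5, 40)) {
    m <- build_ball_and_stick(ais_spec(d))
    radii <- sort(unique(unlist(lapply(m$sections, `[[`, "radii"))))
    expect_equal(radii, c(0.5, 1, 8))
  }
})

test_that("AIS spec enforces its domain", {
  expect_error(ais_spec(4.9), "5")
  expect_error(ais_spec(41), "5")
  expect_error(ais_spec(20, length = 25), "fixed")
  expect_silent(ais_spec(5))
  expect_silent(ais_spec(40))
})

test_that("synthetic detailed morphology is deterministic and seed-sensitive", {
  m1 <- build_synthetic_detailed(seed = 1, hillock_angle_deg = -115.6)
  m2 <- build_synthetic_detailed(seed = 1, hillock_angle_deg = -115.6)
  expect_identical(m1, m2)
  m3 <- build_synthetic_detailed(seed = 2, hillock_angle_deg = -115.6)
  d1 <- m1$sections[[2]]$points
  d3 <- m3$sections[[2]]$points
  expect_false(isTRUE(all.equal(d1, d3)))

  # axon leaves the soma at the requested orientation
  ax <- m1$sections[[length(m1$sections)]]
  u <- ax$points[nrow(ax$points), ] - m1$soma_center
  ang <- atan2(u[2], u[1]) * 180 / pi
  wrapped_diff <- ((ang - (-115.6) + 180) %% 360) - 180
  expect_equal(wrapped_diff, 0, tolerance = 1e-6)

  tags <- vapply(m1$sections, `[[`, "", "tag")
  expect_gte(sum(tags == "dend"), 5)          # branched tree
  expect_equal(sum(tags == "hillock"), 1)
  expect_equal(sum(tags == "ais"), 1)
})

test_that("seeded builders leave the caller's RNG stream untouched", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(build_synthetic_detailed(seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("SWC round-trip preserves points and radii", {
  m <- build_synthetic_detailed(seed = 3)
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- load_swc(f, smooth = FALSE)
  # same point set within the writer's 1e-6 precision; section traversal
  # (and hence anchor duplication at unbranched junctions) may differ
  pts1 <- unique(do.call(rbind, lapply(m$sections, `[[`, "points")))
  pts2 <- unique(do.call(rbind, lapply(m2$sections, `[[`, "points")))
  nn <- function(a, b) vapply(seq_len(nrow(a)), function(i)
    min(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1))
  expect_lt(max(nn(pts1, pts2)), 1e-5)
  expect_lt(max(nn(pts2, pts1)), 1e-5)
})

test_that("SWC loader repairs radii: interpolation and moving average", {
  # 3-point path with an invalid middle radius
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 8 -1",
               "2 3 10 0 0 1.0 1",
               "3 3 20 0 0 0.05 2",
               "4 3 30 0 0 1.0 3"), f)
  m <- load_swc(f, smooth = TRUE)
  r <- m$sections[[2]]$radii
  expect_true(all(r > 0.1))  # interpolated + smoothed away from 0.05

  # constant radii are a fixed point of the smoother
  writeLines(c("1 1 0 0 0 8 -1",
               paste(2:12, 3, seq(10, 110, 10), 0, 0, 1.0, 1:11)), f)
  mc <- load_swc(f, smooth = TRUE)
  expect_equal(mc$sections[[2]]$radii, rep(1, 11))

  # 30-point alternating path equals a direct moving-average loop
  n <- 30
  radii <- rep(c(1, 2), length.out = n)
  writeLines(c("1 1 0 0 0 8 -1",
               paste(2:(n + 1), 3, seq(10, by = 5, length.out = n), 0, 0,
                     radii, 1:n)), f)
  ms <- load_swc(f, smooth = TRUE)
  oracle <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 7); hi <- min(n, i + 7)
    mean(radii[lo:hi])
  }, numeric(1))
  expect_equal(ms$sections[[2]]$radii, oracle)
})

test_that("SWC parse errors carry the offending line number", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 8 -1", "2 3 10 0"), f)
  expect_error(load_swc(f), "line 3")
})

test_that("biophysics defaults match the density table and validate input", {
  dist <- channel_distribution()
  expect_equal(dist$ais[["g_na"]] / dist$soma[["g_na"]], 140)
  expect_equal(dist$dend[["g_kv7"]], 1)
  expect_equal(dist$e_na, 55)
  expect_equal(dist$e_k, -98)
  expect_error(channel_distribution(soma = c(g_na = -1, g_k = 100, g_kv7 = 1)),
               "negative")
  # AIS must be denser than the soma
  expect_error(channel_distribution(ais = c(g_na = 10, g_k = 10, g_kv7 = 1)),
               "exceed")
  expect_error(assign_biophysics(build_ball_and_stick(ais_spec(10)),
                                 dist = list()), "channel_distribution")
})
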