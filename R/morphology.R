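#' AIS placement specification
#'
#' Describes where the axon initial segment (AIS) sits along the proximal
#' axon: `d_ais` is the path distance (um) from the soma surface to the
#' proximal end of the AIS. The AIS itself is a fixed 30 um span.
#'
#' @param d_ais Soma-to-proximal-AIS distance in um, in `[5, 40]`.
#' @param length AIS length in um; fixed at 30.
#' @return An object of class `ais_spec`.
#' @examples
#' ais_spec(5)   # baseline position
#' ais_spec(40)  # most distal position considered
#' @export
ais_spec <- function(d_ais, length = 30) {
  if (!is.numeric(d_ais) || length(d_ais) != 1 || is.na(d_ais) ||
      d_ais < 5 || d_ais > 40)
    stop("d_ais must be a single value in [5, 40] um")
  if (length != 30)
    stop("the AIS length is fixed at 30 um")
  structure(list(d_ais = d_ais, length = length), class = "ais_spec")
}

new_section <- function(tag, points, radii, parent = 0L) {
  tag <- match.arg(tag, c("soma", "dend", "hillock", "ais", "axon"))
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(length(radii) == nrow(points), all(radii > 0))
  if (tag != "soma" && nrow(points) < 2)
    stop("cylindrical sections need at least 2 points")
  list(tag = tag, points = points, radii = as.numeric(radii), parent = parent)
}

new_morphology <- function(sections, soma_center = c(0, 0, 0),
                           axon_orientation_deg = 0, d_ais = NA_real_,
                           model = "custom") {
  tags <- vapply(sections, `[[`, "", "tag")
  if (sum(tags == "soma") != 1) stop("exactly one soma section required")
  structure(list(sections = sections,
                 soma_center = as.numeric(soma_center),
                 axon_orientation_deg = axon_orientation_deg %% 360,
                 d_ais = d_ais, ais_length = 30, model = model),
            class = "ais_morphology")
}

#' @export
print.ais_morphology <- function(x, ...) {
  tags <- vapply(x$sections, `[[`, "", "tag")
  cat(sprintf("<ais_morphology: %s> %d sections (%s), d_ais = %s um, axon at %.1f deg\n",
              x$model, length(x$sections),
              paste(sprintf("%s:%d", names(table(tags)), table(tags)), collapse = ", "),
              format(x$d_ais), x$axon_orientation_deg))
  invisible(x)
}

# interpolate points/radii of a straight run between two path positions
straight_run <- function(origin, direction, s0, s1, radius, step = 10) {
  n <- max(2, ceiling((s1 - s0) / step) + 1)
  s <- seq(s0, s1, length.out = n)
  pts <- t(vapply(s, function(si) origin + si * direction, numeric(3)))
  list(points = pts, radii = rep(radius, n))
}

#' Build the minimal ball-and-stick neuron
#'
#' Geometry: spherical soma of 16 um diameter, a 1 mm cylindrical dendrite of
#' 2 um diameter extending in the -x direction, and a 1 mm axon of 1 um
#' diameter in the +x direction. A contiguous 30 um span of the proximal
#' axon, starting `d_ais` um from the soma surface, is tagged as the AIS.
#' Moving the AIS relabels a sub-span of the axon; it never changes total
#' cable length or diameters.
#'
#' @param ais An [ais_spec()].
#' @return An `ais_morphology` in local coordinates (soma at the origin,
#'   axon along +x, in the z = 0 plane).
#' @export
build_ball_and_stick <- function(ais = ais_spec(5)) {
  if (!inherits(ais, "ais_spec")) ais <- ais_spec(ais)
  r_soma <- 8; r_dend <- 1; r_axon <- 0.5
  axon_len <- 1000; dend_len <- 1000
  u <- c(1, 0, 0)
  d0 <- ais$d_ais; d1 <- d0 + ais$length
  origin <- c(r_soma, 0, 0)  # axon departs the soma surface
  secs <- list(
    new_section("soma", c(0, 0, 0), r_soma),
    new_section("dend", rbind(c(-r_soma, 0, 0), c(-r_soma - dend_len, 0, 0)),
                c(r_dend, r_dend), parent = 1L),
    {r <- straight_run(origin, u, 0, d0, r_axon)
     new_section("axon", r$points, r$radii, parent = 1L)},
    {r <- straight_run(origin, u, d0, d1, r_axon)
     new_section("ais", r$points, r$radii, parent = 3L)},
    {r <- straight_run(origin, u, d1, axon_len, r_axon)
     new_section("axon", r$points, r$radii, parent = 4L)}
  )
  new_morphology(secs, axon_orientation_deg = 0, d_ais = d0, model = "bas")
}

#' Build a procedurally generated detailed morphology
#'
#' Stand-in for reconstructed cultured/cortical neurons: a branched
#' dendritic tree (at least five branch sections) around a spherical soma,
#' a 5 um tapering axon hillock, a 30 um AIS, and a straight 500 um axon
#' leaving the soma at `hillock_angle_deg` (measured counter-clockwise from
#' the +x axis, in the plane of the array). Deterministic given `seed`.
#'
#' @param seed Integer seed controlling the dendritic tree.
#' @param hillock_angle_deg Axon orientation in degrees.
#' @param ais An [ais_spec()]; the detailed sweep uses d_ais in 5..39 um.
#' @return An `ais_morphology`.
#' @export
build_synthetic_detailed <- function(seed = 1, hillock_angle_deg = -115.6,
                                     ais = ais_spec(5)) {
  if (!inherits(ais, "ais_spec")) ais <- ais_spec(ais)
  r_soma <- 8
  rng <- with_seed(seed, {
    draws <- runif(4000)  # pre-drawn stream; keeps the caller's RNG intact
    i <- 0
    function(n, lo, hi) {
      i <<- i + n
      lo + (hi - lo) * draws[(i - n + 1):i]
    }
  })

  secs <- list(new_section("soma", c(0, 0, 0), r_soma))
  n_primary <- 4L
  base_angles <- rng(n_primary, 0, 360)
  grow_branch <- function(start, angle_deg, len, r0, r1, parent_idx, z0) {
    np <- max(3, ceiling(len / 15) + 1)
    ang <- angle_deg * pi / 180
    pts <- matrix(0, np, 3); pts[1, ] <- start
    step <- len / (np - 1)
    for (i in 2:np) {
      ang <- ang + rng(1, -8, 8) * pi / 180  # gentle meander
      pts[i, ] <- pts[i - 1, ] + step * c(cos(ang), sin(ang), 0)
      pts[i, 3] <- z0 + rng(1, -1, 1)
    }
    radii <- seq(r0, r1, length.out = np)
    list(sec = new_section("dend", pts, radii, parent = parent_idx),
         end = pts[np, ], end_angle = ang * 180 / pi, end_r = r1)
  }
  for (k in seq_len(n_primary)) {
    a <- base_angles[k]
    start <- r_soma * c(cos(a * pi / 180), sin(a * pi / 180), 0)
    len <- rng(1, 120, 220)
    b <- grow_branch(start, a, len, rng(1, 1.2, 2), 0.6, 1L, 0)
    secs[[length(secs) + 1L]] <- b$sec
    parent_idx <- length(secs)
    if (k <= 2) {  # two primaries bifurcate -> >= 6 branch sections total
      for (s in c(-1, 1)) {
        bb <- grow_branch(b$end, b$end_angle + s * rng(1, 20, 40),
                          rng(1, 60, 140), 0.6, 0.3, parent_idx, b$end[3])
        secs[[length(secs) + 1L]] <- bb$sec
      }
    }
  }

  # hillock + axon along a straight ray at hillock_angle_deg
  theta <- hillock_angle_deg * pi / 180
  u <- c(cos(theta), sin(theta), 0)
  origin <- r_soma * u
  hillock_len <- 5
  d0 <- ais$d_ais; d1 <- d0 + ais$length; axon_len <- 500
  soma_idx <- 1L
  hillock <- new_section("hillock",
                         rbind(origin, origin + hillock_len * u),
                         c(1.5, 0.75), parent = soma_idx)
  secs[[length(secs) + 1L]] <- hillock
  h_idx <- length(secs)
  # path distance along the axon is measured from the soma surface; the
  # hillock occupies [0, 5] so the axon cylinder spans [5, 500]
  seg <- function(s0, s1, parent) {
    r <- straight_run(origin, u, s0, s1, 0.5)
    new_section(if (s0 >= d0 && s1 <= d1) "ais" else "axon",
                r$points, r$radii, parent = parent)
  }
  prev <- h_idx
  bounds <- sort(unique(c(hillock_len, d0, d1, axon_len)))
  bounds <- bounds[bounds >= hillock_len & bounds <= axon_len]
  for (i in seq_len(length(bounds) - 1)) {
    secs[[length(secs) + 1L]] <- seg(bounds[i], bounds[i + 1], prev)
    prev <- length(secs)
  }
  new_morphology(secs, axon_orientation_deg = hillock_angle_deg %% 360,
                 d_ais = d0, model = "detailed")
}

#' Total cable length per tag (um)
#' @param m An `ais_morphology`.
#' @return Named numeric vector of path lengths by section tag.
#' @export
section_lengths <- function(m) {
  tags <- vapply(m$sections, `[[`, "", "tag")
  len <- vapply(m$sections, function(s) {
    if (s$tag == "soma") return(0)
    sum(sqrt(rowSums(diff(s$points)^2)))
  }, numeric(1))
  tapply(len, tags, sum)
}
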