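#' Ion-channel density table
#'
#' Per-tag channel current densities (pS/um^2) and reversal potentials (mV).
#' Defaults: soma g_Na = 50, g_K = 100, g_Kv7 = 1; AIS g_Na = 7000,
#' g_K = 2000, g_Kv7 = 7; dendrite g_Na = 20, g_K = 0.3, g_Kv7 = 1. The AIS
#' is thus 140x more sodium-dense than the soma, which is what makes it the
#' spike initiation site. The hillock uses somatic densities; the distal
#' (non-AIS) axon carries moderate unmyelinated-axon densities.
#' E_Na = 55 mV, E_K = -98 mV.
#'
#' @param soma,ais,dend,hillock,axon Named numeric vectors with elements
#'   `g_na`, `g_k`, `g_kv7` in pS/um^2.
#' @param e_na,e_k Reversal potentials in mV.
#' @return An object of class `channel_distribution`.
#' @export
channel_distribution <- function(
    soma    = c(g_na = 50,   g_k = 100,  g_kv7 = 1),
    ais     = c(g_na = 7000, g_k = 2000, g_kv7 = 7),
    dend    = c(g_na = 20,   g_k = 0.3,  g_kv7 = 1),
    hillock = c(g_na = 50,   g_k = 100,  g_kv7 = 1),
    axon    = c(g_na = 300,  g_k = 100,  g_kv7 = 1),
    e_na = 55, e_k = -98) {
  tabs <- list(soma = soma, ais = ais, dend = dend, hillock = hillock,
               axon = axon)
  for (nm in names(tabs)) {
    g <- tabs[[nm]]
    if (!all(c("g_na", "g_k", "g_kv7") %in% names(g)))
      stop("density vector for ", nm, " must name g_na, g_k, g_kv7")
    if (any(g < 0)) stop("negative channel density for tag ", nm)
  }
  if (ais[["g_na"]] <= soma[["g_na"]] || ais[["g_k"]] <= soma[["g_k"]])
    stop("AIS Na and K densities must exceed somatic densities")
  structure(c(tabs, list(e_na = e_na, e_k = e_k)),
            class = "channel_distribution")
}

#' Passive membrane and cytoplasm parameters
#'
#' Standard cortical values: axial resistivity Ra = 150 Ohm cm, specific
#' capacitance cm = 1 uF/cm^2, leak conductance 1/30000 S/cm^2 (30 ms
#' membrane time constant), leak reversal -80 mV.
#'
#' @param ra_ohm_cm,cm_uF_cm2,g_leak_S_cm2,e_leak_mV Passive parameters.
#' @param celsius Temperature used to scale channel kinetics (Q10 = 3
#'   relative to the ~36 degC reference of the cortical rate functions).
#'   Default 34 degC, matching heated culture preparations.
#' @return A list of passive parameters.
#' @export
passive_params <- function(ra_ohm_cm = 150, cm_uF_cm2 = 1,
                           g_leak_S_cm2 = 1 / 30000, e_leak_mV = -80,
                           celsius = 34) {
  list(ra = ra_ohm_cm, cm = cm_uF_cm2, g_leak = g_leak_S_cm2,
       e_leak = e_leak_mV, celsius = celsius,
       phi = 3^((celsius - 36) / 10))
}

#' Attach channel densities to a morphology
#'
#' @param m An `ais_morphology` with an AIS section.
#' @param dist A [channel_distribution()].
#' @param passive A [passive_params()] list.
#' @return `m` with `$biophys` set.
#' @export
assign_biophysics <- function(m, dist = channel_distribution(),
                              passive = passive_params()) {
  tags <- vapply(m$sections, `[[`, "", "tag")
  if (!any(tags == "ais")) stop("morphology has no AIS section")
  if (!inherits(dist, "channel_distribution"))
    stop("dist must be a channel_distribution")
  m$biophys <- list(dist = dist, passive = passive)
  m
}

# ---- compartmentalization ---------------------------------------------------

# spatial discretization targets (um) per tag; AIS and proximal axon are
# kept at <= 2.5 um so 1-2 um AIS steps are resolvable
seg_target <- function(tag, s_mid = NULL) {
  switch(tag,
         soma = Inf, hillock = 2.5, ais = 2.5, dend = 25,
         axon = 2.5)  # refined below for distal axon
}

# Flatten a morphology into an ordered compartment table suitable for the
# tree solver: parent index always precedes the child.
morph_to_comps <- function(m) {
  if (is.null(m$biophys)) stop("assign_biophysics() first")
  dist <- m$biophys$dist
  rows <- list()
  last_comp_of_sec <- integer(length(m$sections))
  soma_path <- 0

  add_comp <- function(p0, p1, radius, tag, parent) {
    len <- sqrt(sum((p1 - p0)^2))
    rows[[length(rows) + 1L]] <<- data.frame(
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      radius = radius, length = len,
      area = 2 * pi * radius * len, tag = tag, parent = parent)
    length(rows)
  }

  # soma: spherical, single compartment
  s1 <- m$sections[[1]]
  soma_r <- s1$radii[1]
  rows[[1]] <- data.frame(x0 = s1$points[1, 1], y0 = s1$points[1, 2],
                          z0 = s1$points[1, 3], x1 = s1$points[1, 1],
                          y1 = s1$points[1, 2], z1 = s1$points[1, 3],
                          radius = soma_r, length = 2 * soma_r,
                          area = 4 * pi * soma_r^2, tag = "soma", parent = 0L)
  last_comp_of_sec[1] <- 1L

  # distance of a section start from the soma along the axon, to grade the
  # distal axon discretization
  for (si in seq_along(m$sections)[-1]) {
    s <- m$sections[[si]]
    pts <- s$points; radii <- s$radii
    seglen <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seglen))
    total <- cum[length(cum)]
    if (total <= 0) next
    dist_from_soma <- sqrt(sum((pts[1, ] - m$sections[[1]]$points[1, ])^2))
    target <- if (s$tag == "axon" && dist_from_soma > 100) 25 else
      if (s$tag == "axon" && total > 50) 10 else seg_target(s$tag)
    n_seg <- max(1L, ceiling(total / target))
    breaks <- seq(0, total, length.out = n_seg + 1)
    interp <- function(ss) {
      i <- findInterval(ss, cum, rightmost.closed = TRUE)
      i <- min(i, length(seglen))
      f <- if (seglen[i] > 0) (ss - cum[i]) / seglen[i] else 0
      list(p = pts[i, ] + f * (pts[i + 1, ] - pts[i, ]),
           r = radii[i] + f * (radii[i + 1] - radii[i]))
    }
    parent_comp <- last_comp_of_sec[s$parent]
    for (k in seq_len(n_seg)) {
      a <- interp(breaks[k]); b <- interp(breaks[k + 1])
      parent_comp <- add_comp(a$p, b$p, (a$r + b$r) / 2, s$tag, parent_comp)
    }
    last_comp_of_sec[si] <- parent_comp
  }

  comps <- do.call(rbind, rows)
  comps$tag <- as.character(comps$tag)

  # electrical parameters
  pp <- m$biophys$passive
  area_cm2 <- comps$area * 1e-8
  comps$cm_nF <- pp$cm * area_cm2 * 1e3          # uF -> nF
  # axial half-resistance of each cylinder (MOhm); soma treated as a point
  r_half <- ifelse(comps$tag == "soma", 0,
                   pp$ra * comps$length / (2 * pi * comps$radius^2) * 1e-2)
  comps$r_axial <- NA_real_
  for (i in seq_len(nrow(comps))[-1]) {
    p <- comps$parent[i]
    comps$r_axial[i] <- max(r_half[i] + r_half[p], 1e-6)
  }

  to_uS <- function(g_ps_um2) g_ps_um2 * comps$area * 1e-6
  g_of <- function(which) vapply(comps$tag, function(tg)
    dist[[tg]][[which]], numeric(1))
  comps$g_na   <- to_uS(g_of("g_na"))
  comps$g_k    <- to_uS(g_of("g_k"))
  comps$g_kv7  <- to_uS(g_of("g_kv7"))
  comps$g_leak <- pp$g_leak * area_cm2 * 1e6     # S -> uS
  rownames(comps) <- NULL
  attr(comps, "passive") <- pp
  attr(comps, "dist") <- dist
  comps
}
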