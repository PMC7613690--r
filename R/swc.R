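#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`).
#' Structure types are mapped to tags: 1 -> soma, 2 -> axon, everything
#' else -> dend. The tree is split into unbranched paths (sections) at
#' branch points. Two radius-repair steps mirror common reconstruction
#' pipelines: radii at or below 0.1 um are replaced by linear interpolation
#' from valid neighbors along the path, and each path's radii are smoothed
#' with a 15-sample centered moving average.
#'
#' @param path Path to an SWC file.
#' @param smooth Apply interpolation + moving-average smoothing (default
#'   `TRUE`). Disable for exact round-trips with [write_swc()].
#' @return An `ais_morphology` (without an AIS section; use the builders for
#'   AIS placement, or tag sections downstream).
#' @export
load_swc <- function(path, smooth = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("SWC parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 columns, got %d",
                 rows[bad[1]], lengths(fields)[bad[1]]))
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7, byrow = TRUE)
  if (anyNA(tab)) {
    badrow <- which(apply(tab, 1, anyNA))[1]
    stop(sprintf("SWC parse error at line %d: non-numeric field", rows[badrow]))
  }
  colnames(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  id <- as.integer(tab[, "id"]); parent <- as.integer(tab[, "parent"])
  idx <- match(parent, id)            # NA for roots
  tag_of <- function(tp) if (tp == 1) "soma" else if (tp == 2) "axon" else "dend"

  children <- split(seq_along(id), factor(idx, levels = seq_along(id)))
  n_children <- lengths(children)
  soma_rows <- which(tab[, "type"] == 1)
  if (length(soma_rows) == 0) stop("SWC parse error: no soma (type 1) point")
  soma_row <- soma_rows[1]

  # walk unbranched paths from each branch/root child
  secs <- list(new_section("soma", tab[soma_row, c("x", "y", "z")],
                           max(tab[soma_row, "radius"], 0.5)))
  sec_of_point <- integer(length(id)); sec_of_point[soma_row] <- 1L
  starts <- which((is.na(idx) | idx %in% soma_rows | n_children[idx] > 1) &
                    tab[, "type"] != 1)
  for (s in starts) {
    pts_idx <- s
    cur <- s
    repeat {
      ch <- children[[cur]]
      ch <- ch[tab[ch, "type"] != 1]
      if (length(ch) != 1) break
      cur <- ch
      pts_idx <- c(pts_idx, cur)
    }
    p_idx <- idx[s]
    # anchor the section at its parent point, except when the parent is the
    # soma sphere (the section then starts at its own surface anchor)
    prepend <- if (!is.na(p_idx) && tab[p_idx, "type"] != 1) p_idx else NULL
    rows_sec <- c(prepend, pts_idx)
    radii <- tab[rows_sec, "radius"]
    if (smooth) {
      low <- radii <= 0.1
      if (any(low) && any(!low)) {
        ok <- which(!low)
        radii[low] <- stats::approx(ok, radii[ok], xout = which(low),
                                    rule = 2)$y
      }
      radii <- moving_average(radii, 15)
    }
    radii <- pmax(radii, 0.05)
    parent_sec <- if (!is.na(p_idx)) sec_of_point[p_idx] else 1L
    secs[[length(secs) + 1L]] <- new_section(tag_of(tab[s, "type"]),
                                             tab[rows_sec, c("x", "y", "z")],
                                             radii, parent = parent_sec)
    sec_of_point[pts_idx] <- length(secs)
  }
  new_morphology(secs, soma_center = tab[soma_row, c("x", "y", "z")],
                 model = "swc")
}

#' Write a morphology to SWC
#'
#' Inverse of [load_swc()] for morphologies whose sections form a tree
#' anchored at the soma. Section tags map to SWC types (soma -> 1,
#' axon/ais/hillock -> 2, dend -> 3).
#'
#' @param m An `ais_morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  type_of <- function(tag) switch(tag, soma = 1L, dend = 3L, 2L)
  rows <- list(); counter <- 0L
  last_id_of_sec <- integer(length(m$sections))
  for (si in seq_along(m$sections)) {
    s <- m$sections[[si]]
    pts <- s$points; radii <- s$radii
    parent_id <- if (s$tag == "soma") -1L else last_id_of_sec[s$parent]
    parent_is_soma <- s$tag != "soma" &&
      m$sections[[s$parent]]$tag == "soma"
    # when the parent is another cable section the first point repeats the
    # parent's last point and is not re-emitted
    start <- if (s$tag == "soma" || parent_is_soma) 1L else 2L
    if (s$tag == "soma") {
      counter <- counter + 1L
      rows[[length(rows) + 1L]] <- c(counter, 1, pts[1, ], radii[1], -1)
      last_id_of_sec[si] <- counter
      next
    }
    prev <- parent_id
    for (i in start:nrow(pts)) {
      counter <- counter + 1L
      rows[[length(rows) + 1L]] <- c(counter, type_of(s$tag), pts[i, ],
                                     radii[i], prev)
      prev <- counter
    }
    last_id_of_sec[si] <- counter
  }
  tab <- do.call(rbind, rows)
  writeLines(c("# SWC written by aistrack",
               apply(tab, 1, function(r)
                 sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                         r[1], r[2], r[3], r[4], r[5], r[6], r[7]))),
             path)
  invisible(path)
}
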