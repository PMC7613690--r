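#' Build a planar HD-MEA probe model
#'
#' Electrodes form a regular lattice in the z = 0 plane, centered on the
#' origin so that for even grid sizes the origin is the midpoint of the four
#' central electrodes. The default matches a CMOS HD-MEA block: a 30 x 30
#' grid with 17.5 um pitch and 9.3 x 5.45 um rectangular electrodes. A
#' central 12 x 12 block (ties broken toward lower indices) is kept as the
#' in-depth analysis region.
#'
#' @param rows,cols Grid dimensions (each >= 12).
#' @param pitch Center-to-center electrode spacing, um.
#' @param electrode_w,electrode_h Electrode dimensions, um (metadata only;
#'   electrodes are treated as points at their centers by the forward model).
#' @return An object of class `mea_probe` with `centers` (data.frame of
#'   id, x, y, z), `analysis_block` (electrode ids of the central 12 x 12)
#'   and the geometry fields.
#' @examples
#' p <- build_probe()
#' nrow(p$centers)            # 900
#' length(p$analysis_block)   # 144
#' @export
build_probe <- function(rows = 30, cols = 30, pitch = 17.5,
                        electrode_w = 9.3, electrode_h = 5.45) {
  if (rows < 12 || cols < 12) stop("probe grid must be at least 12 x 12")
  if (pitch <= 0) stop("pitch must be positive")
  cx <- (seq_len(cols) - (cols + 1) / 2) * pitch
  cy <- (seq_len(rows) - (rows + 1) / 2) * pitch
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  centers <- data.frame(id = seq_len(rows * cols),
                        x = cx[grid$col], y = cy[grid$row], z = 0)
  r0 <- floor((rows - 12) / 2); c0 <- floor((cols - 12) / 2)
  block <- centers$id[grid$row > r0 & grid$row <= r0 + 12 &
                        grid$col > c0 & grid$col <= c0 + 12]
  structure(list(n_rows = rows, n_cols = cols, pitch = pitch,
                 electrode_w = electrode_w, electrode_h = electrode_h,
                 centers = centers, analysis_block = block),
            class = "mea_probe")
}

#' @export
print.mea_probe <- function(x, ...) {
  cat(sprintf("<mea_probe> %d x %d grid, pitch %.2f um, %d electrodes (%d in analysis block)\n",
              x$n_rows, x$n_cols, x$pitch, nrow(x$centers),
              length(x$analysis_block)))
  invisible(x)
}

#' Nearest electrode to a point
#'
#' @param probe An `mea_probe`.
#' @param p A 3D point (um). A 2D point is taken at z = 0.
#' @return The electrode id minimizing the Euclidean distance; ties are
#'   broken toward the lowest id.
#' @export
nearest_electrode <- function(probe, p) {
  if (length(p) == 2) p <- c(p, 0)
  d2 <- (probe$centers$x - p[1])^2 + (probe$centers$y - p[2])^2 +
    (probe$centers$z - p[3])^2
  probe$centers$id[which.min(d2)]  # which.min returns the first minimum
}

#' Export electrode positions as CSV
#' @param probe An `mea_probe`.
#' @param path Output CSV path (columns id, x, y, z).
#' @return `path`, invisibly.
#' @export
export_probe_csv <- function(probe, path) {
  write.csv(probe$centers, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a probe specification (YAML)
#' @param probe An `mea_probe`.
#' @param path YAML file path.
#' @return `path` invisibly for write; an `mea_probe` for read.
#' @export
write_probe_yaml <- function(probe, path) {
  yaml::write_yaml(list(rows = probe$n_rows, cols = probe$n_cols,
                        pitch = probe$pitch,
                        electrode_w = probe$electrode_w,
                        electrode_h = probe$electrode_h), path)
  invisible(path)
}

#' @rdname write_probe_yaml
#' @export
read_probe_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build_probe(y$rows, y$cols, y$pitch, y$electrode_w, y$electrode_h)
}
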