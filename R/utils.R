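# internal helpers

# evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so seeded builders do not perturb outer streams
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# centered moving average with window `k` (odd); edges use the part of the
# window that lies inside the vector
moving_average <- function(x, k = 15) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

deg2rad <- function(d) d * pi / 180

rotate_z <- function(pts, theta_deg, center = c(0, 0, 0)) {
  th <- deg2rad(theta_deg)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}
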