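#' Pipeline configuration
#'
#' Bundles the simulation grid, featurization, ML and kernel settings for
#' an end-to-end run. Every stochastic stage consumes an explicit seed
#' derived from `seed`.
#'
#' @param profile,grid Passed to [sim_config()].
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @param sham_ratio Shams per valid vector.
#' @param kernel_L Kernel length.
#' @param feature_set Features for the delta vectors.
#' @param ... Further [sim_config()] overrides.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(profile = "bas", grid = "reduced", seed = 1L,
                            out_dir = tempfile("aistrack-run-"),
                            sham_ratio = 1L, kernel_L = 25L,
                            feature_set = c("amp", "latency", "half_width",
                                            "p2p", "slope_fall",
                                            "slope_rise"), ...) {
  structure(list(sim = sim_config(profile, grid, seed = seed, ...),
                 seed = seed, out_dir = out_dir, sham_ratio = sham_ratio,
                 kernel_L = kernel_L, feature_set = feature_set),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' simulate -> featurize -> NCA + detector + magnitude regressor ->
#' kernel library, writing every artifact (RDS data, JSON metrics, config
#' snapshot) under `cfg$out_dir` and returning a manifest with md5 hashes.
#' Any stage failure aborts with the stage name attached.
#'
#' @param cfg A [pipeline_config()].
#' @param probe An [build_probe()] result.
#' @param family Optional pre-computed `ais_family` matching `cfg` (skips
#'   the simulate stage).
#' @return The run manifest (named list of artifacts with hashes),
#'   invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(cfg, probe = build_probe(), family = NULL) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  save_rds <- function(x, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".rds"))
    saveRDS(x, p); p
  }
  save_json <- function(x, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s [partial manifest: %s]",
                   name, conditionMessage(e),
                   paste(names(artifacts), collapse = ", ")), call. = FALSE)
    })
  }

  artifacts$config <- save_json(list(profile = cfg$sim$profile,
                                     grid = cfg$sim$grid, seed = cfg$seed,
                                     sham_ratio = cfg$sham_ratio,
                                     kernel_L = cfg$kernel_L,
                                     n_scheduled = nrow(enumerate_grid(cfg$sim))),
                                "config")

  fam <- if (is.null(family)) stage("simulate", run_family(cfg$sim, probe))
         else family
  artifacts$sims <- save_rds(fam, "family")

  ds <- stage("featurize",
              build_delta_dataset(fam, cfg$feature_set,
                                  sham_ratio = cfg$sham_ratio,
                                  seed = cfg$seed + 1L))
  artifacts$dataset <- save_rds(ds, "dataset")
  utils::write.csv(cbind(as.data.frame(ds$X), valid = ds$valid,
                         magnitude = ds$magnitude),
                   file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)
  artifacts$features_csv <- file.path(cfg$out_dir, "features.csv")

  nca <- stage("nca", nca_feature_weights(ds$X, ds$valid,
                                          nca_config(seed = cfg$seed + 2L)))
  det <- stage("detect", train_detector(ds$X[, nca$selected, drop = FALSE],
                                        ds$valid,
                                        split_seed = cfg$seed + 3L))
  amp_cols <- grep("^amp_", colnames(ds$X))
  reg <- stage("magnitude",
               train_magnitude_regressor(ds$X[ds$valid, amp_cols,
                                              drop = FALSE],
                                         ds$magnitude[ds$valid],
                                         split_seed = cfg$seed + 4L))
  artifacts$metrics <- save_json(
    list(nca_selected = sum(nca$selected),
         detector = list(tpr = det$tpr, fpr = det$fpr,
                         accuracy = det$accuracy),
         regressor = list(r2 = reg$r2, rmse = reg$rmse)), "metrics")
  artifacts$models <- save_rds(list(nca = nca, detector = det,
                                    regressor = reg), "models")

  lib <- stage("kernel", build_kernel_library(fam, L = cfg$kernel_L))
  artifacts$kernel_library <- save_rds(lib, "kernel_library")

  manifest <- lapply(artifacts, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  save_json(manifest, "manifest")
  invisible(manifest)
}

#' Deterministic test fixtures
#'
#' Small synthetic inputs for unit tests that exercise the featurization
#' and kernel machinery without running the simulator:
#' * `waveform_pair`: two 96-sample traces where the second is the first
#'   convolved with a stored known kernel (returned as `h`);
#' * `footprint`: a 900-electrode x 96-sample array with a negative
#'   biphasic sink moving along a synthetic axon path;
#' * `dataset`: balanced valid/sham delta vectors with one planted
#'   separating feature (column 1).
#'
#' @param kind One of `"waveform_pair"`, `"footprint"`, `"dataset"`.
#' @param seed RNG seed.
#' @return A list; contents depend on `kind`.
#' @export
make_fixture <- function(kind = c("waveform_pair", "footprint", "dataset"),
                         seed = 0) {
  kind <- match.arg(kind)
  fs <- 32000
  spike <- function(n, t0, amp, width_ms, fs) {
    t <- (seq_len(n) - t0) / (fs / 1000)
    -amp * exp(-t^2 / (2 * width_ms^2)) +
      0.35 * amp * exp(-(t - 2.2 * width_ms)^2 / (2 * (1.8 * width_ms)^2))
  }
  with_seed(seed, switch(kind,
    waveform_pair = {
      x <- spike(96, 33, 120, 0.18, fs)
      h <- c(0.15, 0.45, 0.8, 0.35, -0.25, -0.1, 0.05, rep(0, 5))
      y <- predict_waveform(x, h)
      list(x = x, y = y, h = h, fs = fs)
    },
    footprint = {
      probe <- build_probe()
      sink_xy <- c(30, 5)  # along a synthetic axon path in +x
      d <- sqrt((probe$centers$x - sink_xy[1])^2 +
                  (probe$centers$y - sink_xy[2])^2 + 100)
      amp <- 4000 / d
      delay <- pmin(round(d / 40), 20)
      W <- t(vapply(seq_len(nrow(probe$centers)), function(e)
        spike(96, 33 + delay[e], amp[e], 0.2, fs), numeric(96)))
      list(waveforms = W + matrix(rnorm(length(W), sd = 0.25), nrow(W)),
           electrode_ids = probe$centers$id, fs = fs, probe = probe)
    },
    dataset = {
      n <- 120; p <- 12
      X <- matrix(rnorm(n * p), n, p)
      valid <- rep(c(TRUE, FALSE), length.out = n)
      X[, 1] <- ifelse(valid, 3, -3) + rnorm(n, sd = 0.3)
      mag <- ifelse(valid, abs(X[, 1]) * 5, NA)
      list(X = X, valid = valid, magnitude = mag)
    }))
}
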