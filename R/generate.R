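#' Configuration for the synthetic chemosensor data generators
#'
#' Bundles the free parameters of the two synthetic datasets. Defaults are
#' chosen to produce a nontrivial but tractable 8-analyte classification
#' problem: analyte-characteristic mean concentrations log-spaced over one
#' order of magnitude, per-sensor Gaussian jitter at a few percent of each
#' sensor's noiseless dynamic range, and sigmoid transduction parameters that
#' saturate most sensors for the high-concentration analytes.
#'
#' @param n_per_class Samples generated per analyte class (default 16, giving
#'   the 128-sample pool used by the eight-fold evaluation protocol).
#' @param concentration_means Positive means of the per-class exponential
#'   concentration distributions; default `10^seq(0, 1, length.out = 8)`.
#' @param noise_frac Per-sensor Gaussian noise s.d. expressed as a fraction
#'   of that sensor's noiseless dynamic range (default 0.03). Used when
#'   `noise_scales` is `NULL`.
#' @param noise_scales Optional explicit per-sensor noise s.d. vector
#'   (absolute units); overrides `noise_frac`.
#' @param sigmoid_scale,sigmoid_shift Per-sensor slope `s` and midpoint `t` of
#'   the saturating transduction sigmoid `1 / (1 + exp(-s * (r - t)))`.
#'   Scalars are recycled across sensors.
#' @param seed Integer seed; every draw the generators make is derived from it.
#' @return A list of class `hq_config`.
#' @export
generation_config <- function(n_per_class = 16L,
                              concentration_means = 10^seq(0, 1, length.out = 8),
                              noise_frac = 0.03,
                              noise_scales = NULL,
                              sigmoid_scale = 10,
                              sigmoid_shift = 0.15,
                              seed = 42L) {
  stopifnot(n_per_class >= 1, all(concentration_means > 0),
            noise_frac >= 0, all(sigmoid_scale > 0))
  if (!is.null(noise_scales)) stopifnot(all(noise_scales >= 0))
  structure(
    list(n_per_class = as.integer(n_per_class),
         concentration_means = concentration_means,
         noise_frac = noise_frac,
         noise_scales = noise_scales,
         sigmoid_scale = sigmoid_scale,
         sigmoid_shift = sigmoid_shift,
         seed = as.integer(seed)),
    class = "hq_config"
  )
}

sensor_cols <- function(n) paste0("sensor_", seq_len(n))

# assemble the sample tibble shared by both generators
new_sample_set <- function(responses, labels, tag, config, affinity) {
  n_sensors <- ncol(responses)
  out <- tibble::as_tibble(responses, .name_repair = "minimal")
  names(out) <- sensor_cols(n_sensors)
  out$label <- as.integer(labels)
  class(out) <- c("hq_samples", class(out))
  attr(out, "dataset_tag") <- tag
  attr(out, "config") <- config
  attr(out, "affinity") <- affinity
  out
}

#' Generate the concentration-variability dataset
#'
#' Draws, for each analyte class `k`, concentrations from an exponential
#' distribution with class-characteristic mean, multiplies them into column
#' `k` of the affinity matrix, and adds per-sensor zero-mean Gaussian jitter.
#' Responses that fall below zero after jitter are clipped at 0 (a sensor
#' cannot emit a negative reading). The class signal therefore lives in the
#' *pattern* of sensor responses, while overall magnitude varies by orders of
#' magnitude within and across classes.
#'
#' @param G Affinity matrix (sensors x analytes), typically
#'   [tune_sparsity()] applied to [build_hierarchical_affinity()].
#' @param config A [generation_config()].
#' @return A tibble of class `hq_samples` with columns `sensor_1` ...
#'   `sensor_n` and `label` (integer class in `1..n_analytes`), rows ordered
#'   by class. Generation metadata is kept in attributes `dataset_tag`,
#'   `config` and `affinity`.
#' @examples
#' G <- tune_sparsity(build_hierarchical_affinity())
#' smp <- generate_concentration(G, generation_config(seed = 1))
#' dplyr::count(smp, label)
#' @export
generate_concentration <- function(G, config = generation_config()) {
  stopifnot(is.matrix(G), inherits(config, "hq_config"))
  n_sensors <- nrow(G)
  n_classes <- ncol(G)
  if (length(config$concentration_means) != n_classes) {
    stop("`concentration_means` must have one entry per analyte class.",
         call. = FALSE)
  }
  set.seed(config$seed)
  npc <- config$n_per_class
  labels <- rep(seq_len(n_classes), each = npc)
  conc <- stats::rexp(length(labels),
                      rate = 1 / config$concentration_means[labels])
  clean <- t(G[, labels, drop = FALSE]) * conc  # n x sensors
  noise_sd <- config$noise_scales
  if (is.null(noise_sd)) {
    # dynamic range of the noiseless responses, per sensor
    rng <- apply(clean, 2, function(x) diff(range(x)))
    noise_sd <- config$noise_frac * rng
  }
  noise <- matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean))
  noise <- sweep(noise, 2, noise_sd, "*")
  responses <- pmax(clean + noise, 0)
  new_sample_set(responses, labels, "concentration", config, G)
}

#' Generate the saturation dataset from a concentration dataset
#'
#' Applies a per-sensor sigmoid transduction nonlinearity
#' `1 / (1 + exp(-s * (r - t)))` to every response of an existing
#' concentration dataset, emulating sensors whose outputs saturate at high
#' analyte concentrations. Outputs lie in (0, 1); the map is monotone per
#' sensor, so within-sensor response order is preserved while absolute
#' differences among strongly driven sensors are compressed toward 1.
#'
#' @param concentration_set An `hq_samples` tibble from
#'   [generate_concentration()].
#' @param config Optional [generation_config()] supplying `sigmoid_scale` and
#'   `sigmoid_shift`; defaults to the configuration stored in
#'   `concentration_set`.
#' @return A tibble of class `hq_samples` with `dataset_tag = "saturation"`.
#' @export
generate_saturation <- function(concentration_set, config = NULL) {
  stopifnot(inherits(concentration_set, "hq_samples"))
  if (is.null(config)) config <- attr(concentration_set, "config")
  resp <- sample_matrix(concentration_set)
  n_sensors <- ncol(resp)
  s <- rep_len(config$sigmoid_scale, n_sensors)
  t <- rep_len(config$sigmoid_shift, n_sensors)
  sat <- 1 / (1 + exp(-sweep(sweep(resp, 2, t, "-"), 2, s, "*")))
  new_sample_set(sat, concentration_set$label, "saturation", config,
                 attr(concentration_set, "affinity"))
}

#' Extract the response matrix from a sample set
#'
#' @param samples An `hq_samples` tibble (or any data frame with `sensor_*`
#'   columns).
#' @return A numeric matrix, rows = samples, columns = sensors.
#' @export
sample_matrix <- function(samples) {
  cols <- grep("^sensor_", names(samples), value = TRUE)
  as.matrix(samples[cols])
}

#' Write a sample set to CSV with a JSON metadata sidecar
#'
#' @param samples An `hq_samples` tibble.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  meta <- list(
    dataset_tag = attr(samples, "dataset_tag"),
    config = unclass(attr(samples, "config")),
    affinity = unclass(attr(samples, "affinity"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.hq_samples <- function(x, ...) {
  cat("<hq_samples> ", attr(x, "dataset_tag"), " dataset: ",
      nrow(x), " samples x ", ncol(sample_matrix(x)), " sensors, ",
      length(unique(x$label)), " analyte classes\n", sep = "")
  NextMethod()
}
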