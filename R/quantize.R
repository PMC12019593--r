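#' Spike phase of a mitral cell under a constant drive
#'
#' Simulates one gamma cycle of a single MC receiving `drive` plus the
#' sinusoidal background and returns the phase of its spike (0 if silent).
#' Used by the calibration routine and by the weight/threshold duality
#' checks.
#'
#' @param drive Constant input current (the ET activation times the synaptic
#'   weight).
#' @param lif MC [lif_params()].
#' @param osc [oscillator_config()].
#' @return Integer phase in `{0} U [1, phase_bins]`.
#' @export
mc_spike_phase <- function(drive, lif = lif_params(), osc = oscillator_config()) {
  v <- lif$E
  for (s in seq_len(osc$period) - 1L) {
    v <- rk4_v(v, lif, drive + gamma_drive(s, osc), 1)
    if (v >= lif$v_th) return(s + 1L)
  }
  0L
}

#' Calibrate the drive constant of the quantization map
#'
#' Finds, by bisection, the smallest constant input current `c` for which a
#' mitral cell (receiving `c` plus the gamma sinusoid) emits a spike within
#' one 50-step cycle. The quantization weight attached to an intended
#' detection threshold `x` is then `c / x`: an ET activation exactly at `x`
#' delivers drive `c` and fires the cell at the latest attainable phase,
#' while larger activations fire it earlier. The value depends on the LIF and
#' oscillator parameterization and is therefore computed, not assumed.
#'
#' @param lif MC [lif_params()].
#' @param osc [oscillator_config()].
#' @param tol Bisection tolerance on the current (default 1e-4).
#' @param cap Safety cap on the search (default 100); if no spiking current
#'   is found below it, a configuration error is raised.
#' @return The calibrated constant (a single positive number).
#' @export
calibrate_drive_constant <- function(lif = lif_params(),
                                     osc = oscillator_config(),
                                     tol = 1e-4, cap = 100) {
  spikes <- function(drive) mc_spike_phase(drive, lif, osc) > 0L
  lo <- 0
  hi <- cap
  if (spikes(lo)) stop("cell spikes with zero drive; check LIF parameters.",
                       call. = FALSE)
  if (!spikes(hi)) stop("no spiking current found below the safety cap ",
                        cap, "; check LIF/oscillator parameters.",
                        call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Equidistant detection-threshold grid
#'
#' `n` equidistant values spanning `range` inclusive. Mapping thresholds
#' through `w = c / x` produces the 1/x-distributed weight sets used across
#' conditions. The degenerate `n = 1` grid maps to the top of the range (the
#' most conservative single threshold).
#'
#' @param range Two increasing positive numbers, default `c(0.01, 1)` (the
#'   network's detection limit up to the normalization ceiling).
#' @param n Number of thresholds.
#' @return Numeric vector of length `n`.
#' @examples
#' make_threshold_grid(c(0.01, 1), 10)
#' @export
make_threshold_grid <- function(range = c(0.01, 1), n) {
  stopifnot(length(range) == 2, range[1] > 0, range[1] < range[2])
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  if (n == 1) return(range[2])
  seq(range[1], range[2], length.out = n)
}

#' Exact Jenks natural-breaks partition of a numeric vector
#'
#' One-dimensional clustering minimizing the total within-class sum of
#' squared deviations, solved exactly by Fisher's dynamic program (not the
#' iterative heuristic). Used to adapt quantization-threshold density to the
#' empirical distribution of calibration observations.
#'
#' @param values Numeric vector (need not be sorted).
#' @param k Number of classes; if it exceeds the number of distinct values it
#'   is reduced with a warning.
#' @return Numeric vector of `k + 1` boundaries partitioning
#'   `[min(values), max(values)]`; interior boundaries are midpoints between
#'   adjacent class edges. Attributes: `sizes` (class sizes over the sorted
#'   values), `assignment` (class index per input value), `ss` (attained
#'   total within-class sum of squares).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # break between 3 and 10
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(is.numeric(values), length(values) >= 1, k >= 1)
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  n_distinct <- length(unique(x))
  if (k > n_distinct) {
    warning("k = ", k, " exceeds the number of distinct values (",
            n_distinct, "); reduced.", call. = FALSE)
    k <- n_distinct
  }
  # prefix sums for O(1) within-class SS of x[i..j]
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ss <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  # D[j, m]: minimal total SS partitioning x[1..j] into m classes
  D <- matrix(Inf, n, k)
  B <- matrix(1L, n, k)  # start index of the last class
  for (j in seq_len(n)) D[j, 1] <- ss(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          cand <- D[i - 1, m - 1] + ss(i, j)
          if (cand < D[j, m]) {
            D[j, m] <- cand
            B[j, m] <- i
          }
        }
      }
    }
  }
  # backtrack class start indices
  starts <- integer(k)
  j <- n
  for (m in k:1) {
    starts[m] <- B[j, m]
    j <- starts[m] - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  boundaries <- numeric(k + 1)
  boundaries[1] <- x[1]
  boundaries[k + 1] <- x[n]
  if (k > 1) {
    for (m in seq_len(k - 1)) {
      boundaries[m + 1] <- (x[ends[m]] + x[starts[m + 1]]) / 2
    }
  }
  assignment_sorted <- rep(seq_len(k), times = ends - starts + 1L)
  assignment <- integer(n)
  assignment[ord] <- assignment_sorted
  structure(boundaries,
            sizes = ends - starts + 1L,
            assignment = assignment,
            ss = D[n, k])
}

#' Calibration observations for data-aware quantization
#'
#' @param et_matrix Matrix of ET activations (rows = training-fold samples,
#'   columns = sensors) recorded with synaptic learning off.
#' @param n_segments Number of Jenks segments for the adaptive condition
#'   (equal to the duplication factor).
#' @return A list of class `hq_calibration`.
#' @export
calibration_set <- function(et_matrix, n_segments = 1L) {
  stopifnot(is.matrix(et_matrix), all(is.finite(et_matrix)), n_segments >= 1)
  structure(list(observations = et_matrix,
                 n_segments = as.integer(n_segments)),
            class = "hq_calibration")
}

# strictly increasing thresholds bounded below by the detection limit
enforce_thresholds <- function(th, floor_at) {
  th[1] <- max(th[1], floor_at)
  if (length(th) > 1) {
    for (i in 2:length(th)) th[i] <- max(th[i], th[i - 1] * (1 + 1e-9))
  }
  th
}

#' Build an ET-to-MC quantization scheme
#'
#' Constructs the per-column detection thresholds and the corresponding
#' 1/x-distributed synaptic weights (`w = c / threshold`) for one of the four
#' experimental conditions:
#' \describe{
#'   \item{homogeneous}{all `duplication x n_sensors` weights identical; the
#'     shared threshold is entry `gain_index` of a 10-point equidistant grid
#'     on `input_range`.}
#'   \item{uniform}{every column carries `duplication` equidistant thresholds
#'     spanning `input_range` — a flat prior on each sensor's response.}
#'   \item{scaled}{per column, equidistant thresholds spanning the min-max
#'     range of that sensor's calibration observations.}
#'   \item{adaptive}{per column, thresholds piecewise-interpolated across the
#'     Jenks natural-breaks segments of that sensor's calibration
#'     observations, an equal number per segment, so threshold density tracks
#'     observation density.}
#' }
#'
#' @param condition One of `"homogeneous"`, `"uniform"`, `"scaled"`,
#'   `"adaptive"`.
#' @param duplication MC duplication factor (MCs per column).
#' @param n_sensors Number of sensor columns (default 8).
#' @param gain_index For the homogeneous condition, which of the 10 gain
#'   levels to apply (1 = lowest threshold = highest weight).
#' @param calib An [calibration_set()]; required for scaled/adaptive.
#' @param lif,osc MC LIF and oscillator parameters used to calibrate the
#'   drive constant.
#' @param input_range Normalized input range covered by the data-blind
#'   conditions, default `c(0.01, 1)`; its lower end is also the detection
#'   floor below which calibrated thresholds are never placed.
#' @param drive_constant Optionally, a precomputed [calibrate_drive_constant()]
#'   value (avoids recomputation across many schemes).
#' @return A list of class `hq_scheme` with elements `condition`,
#'   `duplication`, `thresholds` and `weights` (`duplication x n_sensors`
#'   matrices, one column per sensor column), `input_range`, and the
#'   calibration constant `c`.
#' @export
build_scheme <- function(condition = c("homogeneous", "uniform", "scaled", "adaptive"),
                         duplication, n_sensors = 8L, gain_index = NULL,
                         calib = NULL, lif = lif_params(),
                         osc = oscillator_config(),
                         input_range = c(0.01, 1),
                         drive_constant = NULL) {
  condition <- match.arg(condition)
  stopifnot(duplication >= 1)
  duplication <- as.integer(duplication)
  if (is.null(drive_constant)) {
    drive_constant <- calibrate_drive_constant(lif, osc)
  }
  floor_at <- input_range[1]
  thresholds <- matrix(NA_real_, duplication, n_sensors)
  if (condition == "homogeneous") {
    if (is.null(gain_index) || gain_index < 1 || gain_index > 10) {
      stop("homogeneous condition requires `gain_index` in 1..10.",
           call. = FALSE)
    }
    grid10 <- make_threshold_grid(input_range, 10L)
    thresholds[] <- grid10[gain_index]
  } else if (condition == "uniform") {
    thresholds[] <- make_threshold_grid(input_range, duplication)
  } else {
    if (is.null(calib)) {
      stop("the ", condition, " condition requires a calibration set.",
           call. = FALSE)
    }
    obs <- calib$observations
    if (ncol(obs) != n_sensors) {
      stop("calibration observations must have one column per sensor.",
           call. = FALSE)
    }
    for (j in seq_len(n_sensors)) {
      xj <- obs[, j]
      lo <- max(min(xj), floor_at)
      hi <- max(xj)
      if (hi <= lo) { lo <- hi / 2; }  # degenerate sensor range guard
      if (condition == "scaled") {
        th <- make_threshold_grid(c(lo, hi), duplication)
      } else {
        k <- min(calib$n_segments, length(unique(xj)))
        br <- suppressWarnings(jenks_breaks(xj, k))
        k <- length(br) - 1L
        br <- enforce_thresholds(as.numeric(br), floor_at)
        th <- if (duplication == 1) {
          br[k + 1]
        } else {
          stats::approx(0:k, br, xout = seq(0, k, length.out = duplication))$y
        }
      }
      thresholds[, j] <- enforce_thresholds(th, floor_at)
    }
  }
  weights <- drive_constant / thresholds
  structure(list(condition = condition,
                 duplication = duplication,
                 n_sensors = as.integer(n_sensors),
                 gain_index = gain_index,
                 thresholds = thresholds,
                 weights = weights,
                 input_range = input_range,
                 c = drive_constant),
            class = "hq_scheme")
}

#' @export
print.hq_scheme <- function(x, ...) {
  cat("<hq_scheme> ", x$condition, " condition, duplication ", x$duplication,
      " (", x$duplication * x$n_sensors, " MCs), c = ", signif(x$c, 5),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a quantization scheme to JSON
#'
#' @param scheme An `hq_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(
    list(condition = scheme$condition, duplication = scheme$duplication,
         n_sensors = scheme$n_sensors, gain_index = scheme$gain_index,
         thresholds = scheme$thresholds, weights = scheme$weights,
         input_range = scheme$input_range, c = scheme$c),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tidy a quantization scheme into a threshold/weight table
#'
#' @param x An `hq_scheme`.
#' @param ... Unused.
#' @return A tibble with columns `sensor`, `mc` (within-column index),
#'   `threshold`, `weight`.
#' @exportS3Method generics::tidy
tidy.hq_scheme <- function(x, ...) {
  tibble::tibble(
    sensor = rep(seq_len(x$n_sensors), each = x$duplication),
    mc = rep(seq_len(x$duplication), times = x$n_sensors),
    threshold = as.vector(x$thresholds),
    weight = as.vector(x$weights)
  )
}
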