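#' Leaky integrate-and-fire parameters
#'
#' Membrane dynamics follow `tau_m * dv/dt = I/g_L - (v - E)`, with the
#' potential reset to `E` upon crossing `v_th`. Defaults are the mitral-cell
#' parameterization; granule cells use the same constants except a higher
#' threshold (`v_th = -50`), i.e. a 10 mV drive-to-threshold rather than 5.
#'
#' @param tau_m Membrane time constant, ms.
#' @param g_L Leak conductance.
#' @param E Resting potential, mV (also the post-spike reset value).
#' @param v_th Spike threshold, mV; must exceed `E`.
#' @return A list of class `hq_lif`.
#' @export
lif_params <- function(tau_m = 4, g_L = 1, E = -60, v_th = -55) {
  stopifnot(tau_m > 0, g_L > 0, v_th > E)
  structure(list(tau_m = tau_m, g_L = g_L, E = E, v_th = v_th),
            class = "hq_lif")
}

#' Granule-cell LIF parameters
#' @rdname lif_params
#' @export
gc_lif_params <- function() lif_params(v_th = -50)

#' Gamma oscillator configuration
#'
#' The background inhibitory rhythm applied to mitral cells: one period is 50
#' simulation steps of 1 ms, the additive drive spans `[-40, 0]`, and the
#' period is divided into 50 discrete spike phases. Inhibition is weakest
#' (drive 0) at `peak_step` and strongest (-40) half a period later.
#' `peak_step` defaults to 20 so that even the weakest detectable input has
#' spiked by roughly phase 25; all MC spikes then land in the first half of
#' the cycle and the half-cycle (25 ms) MC-to-GC delay guarantees granule
#' cells fire only while mitral cells are quiescent, with no synaptic events
#' straddling a cycle boundary.
#'
#' @param period Cycle length in 1-ms steps (default 50).
#' @param amplitude_range Two numbers, the sinusoid's minimum and maximum
#'   additive current (default `c(-40, 0)`).
#' @param phase_bins Number of discrete spike phases per cycle; must equal
#'   `period` at the 1 ms resolution.
#' @param peak_step Step (0-based, within the cycle) at which the drive
#'   reaches its maximum.
#' @return A list of class `hq_osc`.
#' @export
oscillator_config <- function(period = 50L, amplitude_range = c(-40, 0),
                              phase_bins = 50L, peak_step = 20L) {
  stopifnot(period >= 2, phase_bins == period,
            amplitude_range[1] <= amplitude_range[2], amplitude_range[2] <= 0,
            peak_step >= 0, peak_step < period)
  structure(list(period = as.integer(period),
                 amplitude_range = amplitude_range,
                 phase_bins = as.integer(phase_bins),
                 peak_step = as.integer(peak_step)),
            class = "hq_osc")
}

#' Sinusoidal gamma drive at a given simulation step
#'
#' Implemented as
#' `lo + (hi - lo)/2 * (1 + cos(2*pi*(step - peak_step)/period))`: the drive
#' equals the range maximum at `peak_step` and the range minimum half a
#' period away.
#'
#' @param step Simulation step (0-based; vectorized).
#' @param cfg An [oscillator_config()].
#' @return Additive current value(s).
#' @export
gamma_drive <- function(step, cfg = oscillator_config()) {
  stopifnot(all(step >= 0))
  lo <- cfg$amplitude_range[1]
  hi <- cfg$amplitude_range[2]
  lo + (hi - lo) / 2 *
    (1 + cos(2 * pi * (step - cfg$peak_step) / cfg$period))
}

#' Fresh neuron state
#'
#' @param params An [lif_params()].
#' @return List with `v` (membrane potential, initialized to `E`),
#'   `refractory` (has the unit fired this cycle) and `last_spike_step`.
#' @export
neuron_state <- function(params = lif_params()) {
  list(v = params$E, refractory = FALSE, last_spike_step = NA_integer_)
}

# one RK4 step of the linear LIF ODE with input current held constant
rk4_v <- function(v, params, I, dt) {
  f <- function(v) (I / params$g_L - (v - params$E)) / params$tau_m
  k1 <- f(v)
  k2 <- f(v + dt / 2 * k1)
  k3 <- f(v + dt / 2 * k2)
  k4 <- f(v + dt * k3)
  v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance a LIF neuron one RK4 step
#'
#' Integrates `tau_m dv/dt = I/g_L - (v - E)` for one step of `dt` ms using
#' the classical fourth-order Runge-Kutta scheme, with the input current held
#' constant over the step. Threshold crossing is checked after the full step;
#' on a spike the potential is reset to `E` and the unit becomes refractory
#' until the next cycle reset.
#'
#' @param state A [neuron_state()].
#' @param params An [lif_params()].
#' @param I Input current (finite scalar).
#' @param dt Step size in ms (default 1).
#' @param step Current simulation step index, recorded on spike.
#' @return Updated state, with `spiked = TRUE/FALSE` appended.
#' @export
lif_step_rk4 <- function(state, params, I, dt = 1, step = 0L) {
  if (!is.finite(I)) stop("input current must be finite.", call. = FALSE)
  v <- rk4_v(state$v, params, I, dt)
  spiked <- FALSE
  if (!state$refractory && v >= params$v_th) {
    spiked <- TRUE
    state$last_spike_step <- as.integer(step)
    state$refractory <- TRUE
    v <- params$E
  }
  state$v <- v
  state$spiked <- spiked
  state
}

#' Reset a collection of neuron states at a cycle boundary
#'
#' Every 50 steps all spiking-unit voltages and refractory flags are reset,
#' enforcing the one-spike-per-cycle discipline of the phase code.
#'
#' @param states List of [neuron_state()] objects.
#' @param params An [lif_params()] providing the resting potential.
#' @return The reset states (spike logs cleared).
#' @export
reset_cycle <- function(states, params = lif_params()) {
  lapply(states, function(s) {
    s$v <- params$E
    s$refractory <- FALSE
    s$last_spike_step <- NA_integer_
    s$spiked <- FALSE
    s
  })
}

#' Convert a spike step to a within-cycle phase
#'
#' Phases range over `1..phase_bins` (1 = first step of the cycle, i.e. the
#' earliest and therefore strongest response); silent units are coded 0.
#'
#' @param spike_step Global step at which the unit spiked, or `NA` if silent.
#' @param cycle_start Global step at which the cycle began.
#' @param cfg An [oscillator_config()].
#' @return Integer phase in `{0} U [1, phase_bins]`.
#' @export
extract_phase <- function(spike_step, cycle_start, cfg = oscillator_config()) {
  if (is.na(spike_step)) return(0L)
  off <- spike_step - cycle_start
  if (off < 0 || off >= cfg$period) {
    stop("spike step ", spike_step, " outside cycle starting at ",
         cycle_start, ".", call. = FALSE)
  }
  as.integer(off + 1L)
}
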