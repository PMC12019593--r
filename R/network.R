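#' Spike-timing-dependent plasticity parameters
#'
#' The asymmetric Hebbian rule applied to MC-to-GC synapses once per gamma
#' cycle: with pre-synaptic (arrival) time `t_i` and post-synaptic time
#' `t_j`, potentiation `dw = a_plus * exp((t_i - t_j)/tau_plus)` when the pre
#' spike arrives first, depression `dw = -a_minus * exp((t_j - t_i)/tau_minus)`
#' otherwise; weights are clamped to `clamp` after every update. Exact
#' coincidence is treated as causal (potentiation), since the synaptic delay
#' means the arrival did drive the response.
#'
#' @param a_plus,a_minus Potentiation/depression amplitudes (defaults 0.3125
#'   and 1.25).
#' @param tau_plus,tau_minus Exponential time constants, ms (default 4).
#' @param clamp Two numbers, the permissible weight range (default
#'   `c(0, 30)`).
#' @param alpha_in_exponent If `TRUE`, use the amplitudes as the exponential
#'   time constants as well (an alternative literal reading of the rule;
#'   default `FALSE`).
#' @return A list of class `hq_stdp`.
#' @export
stdp_params <- function(a_plus = 0.3125, a_minus = 1.25,
                        tau_plus = 4, tau_minus = 4,
                        clamp = c(0, 30), alpha_in_exponent = FALSE) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0,
            clamp[1] < clamp[2])
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 w_min = clamp[1], w_max = clamp[2],
                 alpha_in_exponent = alpha_in_exponent),
            class = "hq_stdp")
}

#' Single STDP weight update
#'
#' @param w Current weight.
#' @param t_pre Pre-synaptic spike arrival time, ms (within-cycle).
#' @param t_post Post-synaptic spike time, ms.
#' @param p An [stdp_params()].
#' @return Updated, clamped weight. If either time is `NA` (no spike) the
#'   weight is returned unchanged.
#' @examples
#' stdp_update(25, 10, 14)  # pre 4 ms before post: +0.3125 * exp(-1)
#' stdp_update(25, 14, 10)  # post 4 ms before pre: -1.25 * exp(-1)
#' @export
stdp_update <- function(w, t_pre, t_post, p = stdp_params()) {
  if (is.na(t_pre) || is.na(t_post)) return(w)
  dt <- t_post - t_pre
  exp_plus <- if (p$alpha_in_exponent) p$a_plus else p$tau_plus
  exp_minus <- if (p$alpha_in_exponent) p$a_minus else p$tau_minus
  dw <- if (dt >= 0) p$a_plus * exp(-dt / exp_plus)
        else -p$a_minus * exp(dt / exp_minus)
  min(max(w + dw, p$w_min), p$w_max)
}

#' Random MC-to-GC connectivity mask
#'
#' Edges are independent Bernoulli draws with probability `1/duplication`
#' (the inverse of the MC:ET ratio), keeping the expected number of MC
#' inputs per GC constant as columns are duplicated.
#'
#' @param n_mc,n_gc Layer sizes.
#' @param duplication MC duplication factor.
#' @param seed Integer seed (draws are reproducible).
#' @return An `n_mc x n_gc` integer 0/1 matrix.
#' @export
build_connectivity <- function(n_mc, n_gc, duplication, seed) {
  stopifnot(duplication >= 1)
  set.seed(seed)
  matrix(as.integer(stats::runif(n_mc * n_gc) < 1 / duplication), n_mc, n_gc)
}

#' Construct an EPL network for a quantization scheme
#'
#' Builds the spiking stage: `duplication` mitral cells per sensor column
#' (drive = column weight times the column's ET activation, plus the gamma
#' sinusoid), and four times as many granule cells receiving random MC
#' projections with connection probability `1/duplication`. MC-to-GC weights
#' are initialized to 25 and are the only plastic synapses; ET-to-MC weights
#' come frozen from the scheme. GCs receive no sinusoid; MC spikes reach
#' them after a half-cycle (25 ms) delay as additive current transients
#' that decay with time constant `tau_syn`, so GCs can only fire while MCs
#' are quiescent and need near-coincident input from multiple MCs to cross
#' their 10 mV drive-to-threshold.
#'
#' @param scheme An [build_scheme()] result.
#' @param seed Integer seed for the connectivity draw.
#' @param mc_params,gc_params LIF parameterizations.
#' @param stdp An [stdp_params()].
#' @param delay Synaptic delay in steps (default 25, half the gamma period).
#' @param tau_syn Decay time constant (ms) of the GC synaptic current
#'   transient (default 2): sets the width of the coincidence-detection
#'   window to a few milliseconds while keeping any single spike, even at
#'   the weight clamp maximum, unable to fire a GC.
#' @param init_w Initial MC-to-GC weight (default 25).
#' @param osc An [oscillator_config()].
#' @param use_delay_in_stdp Use synaptic arrival times (spike + delay) as the
#'   pre-synaptic times in the STDP rule (default `TRUE`).
#' @return A list of class `hq_network`.
#' @export
epl_network <- function(scheme, seed, mc_params = lif_params(),
                        gc_params = gc_lif_params(), stdp = stdp_params(),
                        delay = 25L, tau_syn = 2, init_w = 25,
                        osc = oscillator_config(),
                        use_delay_in_stdp = TRUE) {
  stopifnot(inherits(scheme, "hq_scheme"))
  n_mc <- scheme$duplication * scheme$n_sensors
  n_gc <- 4L * n_mc
  conn <- build_connectivity(n_mc, n_gc, scheme$duplication, seed)
  w <- matrix(0, n_mc, n_gc)
  w[conn == 1L] <- init_w
  structure(list(scheme = scheme, n_mc = n_mc, n_gc = n_gc,
                 connectivity = conn, w = w,
                 mc_params = mc_params, gc_params = gc_params,
                 stdp = stdp, delay = as.integer(delay),
                 tau_syn = tau_syn, osc = osc,
                 use_delay_in_stdp = use_delay_in_stdp, seed = seed),
            class = "hq_network")
}

# constant per-MC drive for an ET activation vector (column-major MC order:
# MCs of sensor column j occupy rows (j-1)*duplication + 1..duplication)
mc_drive_for <- function(net, et) {
  as.vector(sweep(net$scheme$weights, 2, et, "*"))
}

# pure-R reference engine, mirrors src/sim.cpp step for step
present_sample_r <- function(net, et, n_cycles, learning) {
  period <- net$osc$period
  total <- n_cycles * period
  gamma <- gamma_drive(seq_len(period) - 1L, net$osc)
  drive <- mc_drive_for(net, et)
  mcp <- net$mc_params; gcp <- net$gc_params; p <- net$stdp
  n_mc <- net$n_mc; n_gc <- net$n_gc
  W <- net$w
  mc_ph <- matrix(0L, n_cycles, n_mc)
  gc_ph <- matrix(0L, n_cycles, n_gc)
  gc_in <- matrix(0, total + net$delay + 1L, n_gc)
  syn_decay <- exp(-1 / net$tau_syn)
  syn_i <- rep(0, n_gc)
  vm <- rep(mcp$E, n_mc); vg <- rep(gcp$E, n_gc)
  rm_ <- rep(FALSE, n_mc); rg <- rep(FALSE, n_gc)
  for (t in seq_len(total) - 1L) {
    cyc <- t %/% period + 1L
    s <- t %% period
    if (s == 0L) {
      vm[] <- mcp$E; vg[] <- gcp$E; rm_[] <- FALSE; rg[] <- FALSE
      syn_i[] <- 0
    }
    for (i in seq_len(n_mc)) {
      vm[i] <- rk4_v(vm[i], mcp, drive[i] + gamma[s + 1L], 1)
      if (!rm_[i] && vm[i] >= mcp$v_th) {
        rm_[i] <- TRUE
        mc_ph[cyc, i] <- s + 1L
        vm[i] <- mcp$E
        ta <- t + net$delay
        if (ta < total) {
          sel <- net$connectivity[i, ] == 1L
          gc_in[ta + 1L, sel] <- gc_in[ta + 1L, sel] + W[i, sel]
        }
      }
    }
    syn_i <- syn_i * syn_decay + gc_in[t + 1L, ]
    for (j in seq_len(n_gc)) {
      vg[j] <- rk4_v(vg[j], gcp, syn_i[j], 1)
      if (!rg[j] && vg[j] >= gcp$v_th) {
        rg[j] <- TRUE
        gc_ph[cyc, j] <- s + 1L
        vg[j] <- gcp$E
      }
    }
    if (learning && s == period - 1L) {
      for (i in seq_len(n_mc)) {
        if (mc_ph[cyc, i] == 0L) next
        t_pre <- mc_ph[cyc, i] + if (net$use_delay_in_stdp) net$delay else 0L
        for (j in seq_len(n_gc)) {
          if (net$connectivity[i, j] == 1L && gc_ph[cyc, j] > 0L) {
            W[i, j] <- stdp_update(W[i, j], t_pre, gc_ph[cyc, j], p)
          }
        }
      }
    }
  }
  list(mc_phases = mc_ph, gc_phases = gc_ph, w = W)
}

#' Present one sample to the network
#'
#' Exposes the network to a fixed ET activation vector for `n_cycles` gamma
#' cycles (50 steps each). Mitral cells receive the constant current
#' `weight * ET` plus the sinusoid; their spikes are forwarded to connected
#' granule cells as delayed single-step pulses; all voltages and refractory
#' flags reset at every cycle boundary, enforcing one spike per unit per
#' cycle. With `learning = TRUE` the STDP rule is applied at the end of
#' every cycle.
#'
#' @param net An [epl_network()].
#' @param et ET activation vector (length `n_sensors`), e.g. from
#'   [normalize_l1()].
#' @param n_cycles Exposure length in cycles (default 5).
#' @param learning Apply STDP updates (default `FALSE`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical results).
#' @return A list with `network` (weights possibly updated), `mc_phases` and
#'   `gc_phases` (`n_cycles x n_units` integer matrices, 0 = silent), and
#'   `et` (the input vector).
#' @export
present_sample <- function(net, et, n_cycles = 5L, learning = FALSE,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(net, "hq_network"))
  if (length(et) != net$scheme$n_sensors) {
    stop("`et` length must match the number of sensor columns.",
         call. = FALSE)
  }
  if (any(!is.finite(et))) stop("`et` must be finite.", call. = FALSE)
  if (engine == "cpp") {
    gamma <- gamma_drive(seq_len(net$osc$period) - 1L, net$osc)
    res <- present_sample_cpp(mc_drive_for(net, et), net$connectivity, net$w,
                              as.integer(n_cycles), learning,
                              unclass(net$mc_params), unclass(net$gc_params),
                              gamma, net$delay, net$tau_syn,
                              unclass(net$stdp), net$use_delay_in_stdp)
  } else {
    res <- present_sample_r(net, et, n_cycles, learning)
  }
  net$w <- res$w
  list(network = net, mc_phases = res$mc_phases, gc_phases = res$gc_phases,
       et = et)
}

#' Rinse cycle
#'
#' One 50-step cycle with an all-zeros input. No unit can spike (MC drive
#' stays below threshold and no pulses are pending, as delayed synaptic
#' events do not persist across sample boundaries), and all states are reset,
#' so subsequent presentations are independent of earlier ones.
#'
#' @param net An [epl_network()].
#' @param engine Simulation engine, as in [present_sample()].
#' @return The network, unchanged except for the state reset.
#' @export
rinse <- function(net, engine = c("cpp", "r")) {
  res <- present_sample(net, rep(0, net$scheme$n_sensors), n_cycles = 1L,
                        learning = FALSE, engine = match.arg(engine))
  res$network
}

#' Two-shot training of the granule-cell layer
#'
#' Sequentially presents each of the 16 training samples (two per analyte
#' class) for five learning cycles, with a rinse cycle between samples.
#' Only MC-to-GC weights change; the quantization scheme stays frozen.
#'
#' @param net An [epl_network()].
#' @param training_samples An `hq_samples` tibble (or data frame with
#'   `sensor_*` and `label` columns) holding exactly two samples per class.
#' @param n_cycles Cycles per presentation (default 5).
#' @param engine Simulation engine.
#' @return The trained network.
#' @export
train_two_shot <- function(net, training_samples, n_cycles = 5L,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  counts <- table(training_samples$label)
  if (length(unique(counts)) != 1 || counts[[1]] != 2) {
    stop("two-shot training needs exactly 2 samples per class.",
         call. = FALSE)
  }
  resp <- sample_matrix(training_samples)
  for (i in seq_len(nrow(resp))) {
    et <- normalize_l1(osn_relay(resp[i, ]))
    out <- present_sample(net, et, n_cycles = n_cycles, learning = TRUE,
                          engine = engine)
    net <- rinse(out$network, engine = engine)
  }
  net
}

#' @export
print.hq_network <- function(x, ...) {
  cat("<hq_network> ", x$n_mc, " MCs (", x$scheme$n_sensors, " columns x ",
      x$scheme$duplication, "), ", x$n_gc, " GCs, ",
      sum(x$connectivity), " MC->GC edges, ", x$scheme$condition,
      " quantization\n", sep = "")
  invisible(x)
}

#' Summarize a network in one row
#'
#' @param x An `hq_network`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, edge count, weight summary.
#' @exportS3Method generics::glance
glance.hq_network <- function(x, ...) {
  ww <- x$w[x$connectivity == 1L]
  tibble::tibble(
    condition = x$scheme$condition,
    duplication = x$scheme$duplication,
    n_mc = x$n_mc, n_gc = x$n_gc,
    n_edges = sum(x$connectivity),
    mean_weight = mean(ww), min_weight = min(ww), max_weight = max(ww)
  )
}

#' Tidy the plastic synapses of a network
#'
#' @param x An `hq_network`.
#' @param ... Unused.
#' @return A tibble with one row per MC-to-GC edge: `mc`, `gc`, `weight`.
#' @exportS3Method generics::tidy
tidy.hq_network <- function(x, ...) {
  idx <- which(x$connectivity == 1L, arr.ind = TRUE)
  tibble::tibble(mc = idx[, 1], gc = idx[, 2],
                 weight = x$w[idx])
}
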