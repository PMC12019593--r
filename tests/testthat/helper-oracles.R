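# Independent oracles used across the suite.

# closed-form solution of tau * dv/dt = I/gL - (v - E) from v(0) = v0,
# input held constant
lif_closed_form <- function(t, v0, I, params) {
  asym <- params$E + I / params$g_L
  asym + (v0 - asym) * exp(-t / params$tau_m)
}

# Hoyer sparsity straight from its definition (kept separate from the
# package implementation on purpose)
hoyer_direct <- function(v) {
  n <- length(v)
  (sqrt(n) - sum(v) / sqrt(sum(v^2))) / (sqrt(n) - 1)
}

# exhaustive search over all ordered partitions of sorted values into k
# contiguous nonempty classes, minimizing total within-class SS
jenks_brute_force <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wss <- function(v) sum((v - mean(v))^2)
  if (k == 1) {
    return(list(ss = wss(x), sizes = n))
  }
  cuts <- utils::combn(n - 1, k - 1)
  best_ss <- Inf
  best_sizes <- NULL
  for (ci in seq_len(ncol(cuts))) {
    edges <- c(0, cuts[, ci], n)
    ss <- 0
    for (m in seq_len(k)) {
      ss <- ss + wss(x[(edges[m] + 1):edges[m + 1]])
    }
    if (ss < best_ss) {
      best_ss <- ss
      best_sizes <- diff(edges)
    }
  }
  list(ss = best_ss, sizes = best_sizes)
}

# shared small fixtures (built once per test run)
tuned_affinity <- local({
  G <- NULL
  function() {
    if (is.null(G)) G <<- tune_sparsity(build_hierarchical_affinity())
    G
  }
})

small_pool <- local({
  cache <- list()
  function(tag = "concentration", seed = 11L) {
    key <- paste(tag, seed)
    if (is.null(cache[[key]])) {
      conc <- generate_concentration(tuned_affinity(),
                                     generation_config(seed = seed))
      cache[[key]] <<- if (tag == "concentration") conc
                       else generate_saturation(conc)
    }
    cache[[key]]
  }
})

drive_const <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- calibrate_drive_constant()
    val
  }
})
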