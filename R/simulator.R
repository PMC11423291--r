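#' Single-neuron model parameters
#'
#' Parameters of the quadratic integrate-and-fire neuron with adaptation,
#' miniature synaptic currents (minis) and white membrane noise. Voltages
#' in mV, times in ms. `C` is the normalized membrane constant; `v_r` and
#' `v_t` the resting and threshold potentials; `v_p` the firing cutoff and
#' `v_c` the reset; `b`, `d`, `tau_a` control the slow adaptation current;
#' minis arrive as a Poisson process of rate `lambda_mini` per ms, each
#' adding `g_m` to a shared exponentially decaying (tau `tau_m`) current;
#' the white-noise term has amplitude `g_s`. The firing cutoff and reset of
#' standard cells follow the usual convention for this neuron class
#' (`v_p = +30`, `v_c = -50`); bursty cells override `v_c` and `d`.
#'
#' @param C,k,v_r,v_t,v_p,v_c,b,d,tau_a,g_s,lambda_mini,g_m,tau_m model
#'   constants, see Description.
#' @return A named list of class `neuron_params`.
#' @export
neuron_params <- function(C = 100, k = 0.7, v_r = -60, v_t = -40, v_p = 30,
                          v_c = -50, b = -2, d = 100, tau_a = 33, g_s = 30,
                          lambda_mini = 0.1, g_m = 30, tau_m = 10) {
  stopifnot(v_r < v_t, tau_a > 0, lambda_mini >= 0, tau_m > 0, C > 0)
  structure(as.list(environment()), class = "neuron_params")
}

#' Synaptic parameters
#'
#' Exponential synaptic currents with short-term depression. The excitatory
#' strength `g_exc` is the model's control parameter (about 40 mV at full
#' scale; re-tuned when the plating area is scaled down); the inhibitory
#' strength is fixed at -50 mV. `tau_exc` / `tau_inh` are the current decay
#' constants (ms); depression recovers with `tau_D_*` (ms) and each
#' presynaptic spike multiplies the depression variable by `beta_*`.
#'
#' @param g_exc,g_inh,tau_exc,tau_inh,tau_D_exc,tau_D_inh,beta_exc,beta_inh
#'   see Description.
#' @return A named list of class `synapse_params`.
#' @export
synapse_params <- function(g_exc = 40, g_inh = -50, tau_exc = 10,
                           tau_inh = 20, tau_D_exc = 2000, tau_D_inh = 200,
                           beta_exc = 0.8, beta_inh = 0.95) {
  stopifnot(tau_exc > 0, tau_inh > 0, tau_D_exc > 0, tau_D_inh > 0,
            beta_exc > 0, beta_exc < 1, beta_inh > 0, beta_inh < 1)
  structure(as.list(environment()), class = "synapse_params")
}

.derive_seed <- function(seed) {
  if (is.null(seed)) sample.int(2147483646L, 1) else as.integer(seed)
}

#' Build a spatially embedded culture network
#'
#' Neurons are placed uniformly at random on a square plating region at the
#' given density. Each neuron grows an axon as a biased random walk: total
#' length Rayleigh-distributed (scale `axon_scale_um`), grown in
#' `seg_len_um` segments whose headings follow a Gaussian around the
#' previous heading (sd `angle_sd_deg` degrees), with a uniformly random
#' initial heading. Each neuron's dendritic tree is an effective disk with
#' Gaussian radius (mean `dend_mean_um`, sd `dend_sd_um`). A directed
#' synapse pre -> post is created with probability `p_conn` when the
#' presynaptic axon crosses the postsynaptic dendritic disk (at most one
#' connection per ordered pair). 20% of neurons are inhibitory.
#'
#' With `periodic = TRUE` the plating square has periodic boundaries, which
#' emulates the bulk of a much larger culture when using a scaled-down
#' region; the default is open boundaries.
#'
#' @param side_length_mm side of the square plating region (mm).
#' @param density_per_mm2 neuron density (default 800 / mm^2).
#' @param frac_inhibitory fraction of inhibitory neurons.
#' @param axon_scale_um Rayleigh scale of the axon total length
#'   (micrometres; mean length is `axon_scale_um * sqrt(pi/2)`).
#' @param seg_len_um axon growth segment (micrometres).
#' @param angle_sd_deg heading change sd per segment (degrees).
#' @param dend_mean_um,dend_sd_um dendritic disk radius distribution
#'   (micrometres; radii are truncated below at 10).
#' @param p_conn connection probability at an axon--dendrite crossing.
#' @param periodic logical, periodic boundary conditions.
#' @param keep_geometry keep axon polylines (debug / verification).
#' @param seed integer seed; drawn from the R RNG when `NULL`.
#' @return A `culture_network`: list with `positions` (um), `ei`, `edges`
#'   (data.frame `from`, `to`), `n`, `side_um`, `periodic`, `axons`
#'   (optional), `dend_radius`, `axon_length`, `seed`.
#' @export
culture_network <- function(side_length_mm = 2.5, density_per_mm2 = 800,
                            frac_inhibitory = 0.2, axon_scale_um = 900,
                            seg_len_um = 10, angle_sd_deg = 15,
                            dend_mean_um = 150, dend_sd_um = 40,
                            p_conn = 0.13, periodic = FALSE,
                            keep_geometry = FALSE, seed = NULL) {
  stopifnot(side_length_mm > 0, density_per_mm2 > 0)
  seed <- .derive_seed(seed)
  set.seed(seed)
  side <- side_length_mm * 1000
  n <- round(density_per_mm2 * side_length_mm^2)
  if (n < 2) stop("network needs at least 2 neurons")
  pos <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
  dend_r <- pmax(stats::rnorm(n, dend_mean_um, dend_sd_um), 10)
  axon_len <- axon_scale_um * sqrt(-2 * log(stats::runif(n)))
  ei <- rep("E", n)
  ei[sample.int(n, round(frac_inhibitory * n))] <- "I"
  net <- cpp_build_network(pos[, 1], pos[, 2], dend_r, axon_len,
                           seg_len_um, angle_sd_deg * pi / 180, p_conn,
                           side, side, periodic, keep_geometry,
                           seed + 1)
  structure(list(
    positions = pos, ei = ei,
    edges = data.frame(from = net$from, to = net$to),
    n = n, side_um = side, periodic = periodic,
    axons = if (keep_geometry) net$axons,
    dend_radius = dend_r, axon_length = axon_len, seed = seed),
    class = "culture_network")
}

#' @export
print.culture_network <- function(x, ...) {
  cat(sprintf(
    "Culture network: %d neurons on %.2g x %.2g mm (%s boundaries)\n",
    x$n, x$side_um / 1000, x$side_um / 1000,
    if (x$periodic) "periodic" else "open"))
  cat(sprintf("  %d synapses (mean out-degree %.1f), %d%% inhibitory\n",
              nrow(x$edges), nrow(x$edges) / x$n,
              round(100 * mean(x$ei == "I"))))
  invisible(x)
}

#' Per-neuron parameter table for a model variant
#'
#' Expands scalar neuron/synapse parameters into per-neuron vectors for the
#' integrator, applying a population variant. `"homogeneous"`: all
#' excitatory cells standard. `"heterogeneous"`: the excitatory population
#' is split into standard cells and one eighth bursty cells (`v_c = -40`,
#' `d = 50`), i.e. 70% standard / 10% bursty / 20% inhibitory overall, and
#' every excitatory cell's resting potential becomes -62 mV plus a
#' Rayleigh(sd 2 mV) offset. With `inhibition_blocked = TRUE` the output
#' strength of inhibitory cells is set to 0 (the in-silico analogue of
#' saturating picrotoxin).
#'
#' @param network a `culture_network`.
#' @param variant `"homogeneous"` or `"heterogeneous"`.
#' @param inhibition_blocked logical.
#' @param params a [neuron_params()].
#' @param syn a [synapse_params()].
#' @param seed integer seed for the heterogeneous offsets.
#' @return A data.frame with one row per neuron: `v_r`, `v_c`, `d`,
#'   `g_out`, `is_inh`, `beta_syn`, `tau_D`, `bursty`.
#' @export
apply_variant <- function(network, variant = c("homogeneous",
                                               "heterogeneous"),
                          inhibition_blocked = FALSE,
                          params = neuron_params(), syn = synapse_params(),
                          seed = NULL) {
  stopifnot(inherits(network, "culture_network"))
  variant <- match.arg(variant)
  n <- network$n
  inh <- network$ei == "I"
  out <- data.frame(
    v_r = rep(params$v_r, n), v_c = rep(params$v_c, n),
    d = rep(params$d, n),
    g_out = ifelse(inh, if (inhibition_blocked) 0 else syn$g_inh,
                   syn$g_exc),
    is_inh = inh,
    beta_syn = ifelse(inh, syn$beta_inh, syn$beta_exc),
    tau_D = ifelse(inh, syn$tau_D_inh, syn$tau_D_exc),
    bursty = FALSE)
  if (variant == "heterogeneous") {
    seed <- .derive_seed(seed)
    set.seed(seed)
    exc <- which(!inh)
    n_bursty <- round(n * 0.1)
    if (n_bursty > length(exc))
      stop("population fractions incompatible with E/I split")
    bursty <- sample(exc, n_bursty)
    out$bursty[bursty] <- TRUE
    out$v_c[bursty] <- -40
    out$d[bursty] <- 50
    # Rayleigh offsets with sd 2 mV on a -62 mV base for all excitatory cells
    scale <- 2 / sqrt(2 - pi / 2)
    out$v_r[exc] <- -62 + scale * sqrt(-2 * log(stats::runif(length(exc))))
  }
  out
}

#' Simulate a culture recording
#'
#' Integrates the quadratic integrate-and-fire network with adaptation,
#' short-term synaptic depression, Poisson minis and white membrane noise
#' with a first-order Euler scheme (step `dt_ms`). Every presynaptic spike
#' delivers an exponentially decaying current of amplitude
#' `g * D(t_spike)` to all its targets, where `D` is the presynaptic
#' depression variable (recovery time `tau_D`, multiplicative drop `beta`
#' per spike). Returns the spike raster of the whole population (spike
#' times in seconds, positions and E/I labels attached).
#'
#' @param network a [culture_network()].
#' @param duration_s simulated time in seconds.
#' @param dt_ms integration step (ms, default 0.1).
#' @param variant,inhibition_blocked population variant, see
#'   [apply_variant()].
#' @param params a [neuron_params()].
#' @param syn a [synapse_params()].
#' @param seed integer seed; drawn from the R RNG when `NULL`.
#' @param v_guard integration guard bound (mV).
#' @param I_ext constant external current (mV), 0 in the standard model;
#'   useful for controlled single-neuron experiments.
#' @param record_neuron optional neuron id whose state trajectory
#'   (`v`, `u`, `D` after every step) is attached as attribute `"state"`.
#' @return A [spike_raster()] with `frame_interval = dt_ms / 1000`.
#' @export
simulate_culture <- function(network, duration_s, dt_ms = 0.1,
                             variant = "homogeneous",
                             inhibition_blocked = FALSE,
                             params = neuron_params(),
                             syn = synapse_params(), seed = NULL,
                             v_guard = 1000, I_ext = 0,
                             record_neuron = NULL) {
  stopifnot(inherits(network, "culture_network"), duration_s > 0)
  seed <- .derive_seed(seed)
  pp <- apply_variant(network, variant, inhibition_blocked, params, syn,
                      seed = seed + 2)
  # CSR adjacency
  ord <- order(network$edges$from)
  tgt <- network$edges$to[ord]
  ptr <- c(0L, cumsum(tabulate(network$edges$from[ord], nbins = network$n)))
  sim <- cpp_simulate_culture(
    network$n, as.integer(ptr), as.integer(tgt),
    pp$v_r, pp$v_c, pp$d, pp$g_out, pp$is_inh, pp$beta_syn, pp$tau_D,
    params$C, params$k, params$v_t, params$v_p, params$b, params$tau_a,
    params$g_s, params$lambda_mini, params$g_m, params$tau_m,
    syn$tau_exc, syn$tau_inh,
    duration_s * 1000, dt_ms, seed, v_guard, I_ext,
    if (is.null(record_neuron)) 0L else as.integer(record_neuron))
  out <- spike_raster(sim$neuron, sim$time_ms / 1000,
                      n_neurons = network$n, duration = duration_s,
                      frame_interval = dt_ms / 1000,
                      positions = network$positions, ei = network$ei)
  if (!is.null(record_neuron)) attr(out, "state") <- sim$state
  out
}

#' Galton--Watson avalanches (mean-field branching process)
#'
#' Generates avalanches of a branching process with Poisson offspring of
#' mean `m`, started from a single active unit. The avalanche size `S` is
#' the total number of activations and the duration `T` the number of
#' generations (the initial unit counts as generation 1). At the critical
#' point `m = 1` the avalanche statistics follow the mean-field laws
#' `P(S) ~ S^-1.5`, `P(T) ~ T^-2`, `<T>(S) ~ S^0.5`. Generations are capped
#' at `max_generations`; capped avalanches are flagged.
#'
#' Sizes and durations are simulated exactly via the generation totals
#' (the sum of independent Poisson offspring of a generation of `z` units
#' is Poisson with mean `m * z`).
#'
#' @param n_avalanches number of avalanches.
#' @param m mean branching ratio (>= 0).
#' @param max_generations generation cap.
#' @param seed integer seed; uses the R RNG stream when `NULL`.
#' @return An `avalanche_set` whose `avalanches` data.frame has columns
#'   `S`, `T`, `capped`; `bin_width` is 1 generation.
#' @export
branching_process <- function(n_avalanches, m = 1, max_generations = 1e4,
                              seed = NULL) {
  stopifnot(n_avalanches >= 1, m >= 0)
  if (!is.null(seed)) set.seed(seed)
  S <- rep(1, n_avalanches)
  T <- rep(1L, n_avalanches)
  z <- rep(1, n_avalanches)      # active units per avalanche
  active <- seq_len(n_avalanches)
  gen <- 1L
  while (length(active) && gen < max_generations) {
    z_new <- stats::rpois(length(active), m * z[active])
    alive <- z_new > 0
    S[active] <- S[active] + z_new
    T[active[alive]] <- gen + 1L
    z[active] <- z_new
    active <- active[alive]
    gen <- gen + 1L
  }
  capped <- logical(n_avalanches)
  capped[active] <- TRUE
  structure(list(
    avalanches = data.frame(S = S, T = as.integer(T), capped = capped),
    bin_width = 1, state = "branching", patch_id = NA_integer_,
    n_spikes = sum(S)),
    class = "avalanche_set")
}
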