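# Shared in-code fixtures for the test suite.

# Homogeneous Poisson raster: n neurons firing at `rate` Hz for `duration` s.
poisson_raster <- function(n_neurons, rate, duration, seed = 1,
                           frame_interval = 0.005) {
  set.seed(seed)
  counts <- stats::rpois(n_neurons, rate * duration)
  neuron <- rep(seq_len(n_neurons), counts)
  time <- stats::runif(sum(counts), 0, duration)
  # deduplicate identical (neuron, time) pairs, astronomically unlikely
  spike_raster(neuron, time, n_neurons = n_neurons, duration = duration,
               frame_interval = frame_interval)
}

# Bistable raster: alternating high-rate and low-rate epochs, used to
# exercise state detection without running the network model.
bistable_raster <- function(n_neurons = 200, up_rate = 20, down_rate = 0.02,
                            t_up = 1, t_down = 4, n_cycles = 10, seed = 1,
                            frame_interval = 0.005) {
  set.seed(seed)
  neuron <- integer(0); time <- numeric(0)
  t0 <- 0
  for (cyc in seq_len(n_cycles)) {
    # down epoch then up epoch
    for (ep in list(c(down_rate, t_down), c(up_rate, t_up))) {
      lam <- ep[1] * ep[2] * n_neurons
      k <- stats::rpois(1, lam)
      neuron <- c(neuron, sample.int(n_neurons, k, replace = TRUE))
      time <- c(time, stats::runif(k, t0, t0 + ep[2]))
      t0 <- t0 + ep[2]
    }
  }
  o <- order(neuron, time)
  spike_raster(neuron[o], time[o], n_neurons = n_neurons, duration = t0,
               frame_interval = frame_interval)
}

# Tiny deterministic raster from explicit (neuron, time) pairs.
raster_of <- function(neuron, time, ...) {
  spike_raster(neuron, time, ...)
}
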