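# Minimal single-neuron "network" used to exercise the integrator alone.
lone_neuron <- function() {
  structure(list(positions = matrix(0, 1, 2), ei = "E",
                 edges = data.frame(from = integer(0), to = integer(0)),
                 n = 1L, side_um = 100, periodic = FALSE, seed = 1L),
            class = "culture_network")
}

two_neurons <- function(ei = c("E", "E")) {
  structure(list(positions = matrix(c(0, 50, 0, 0), 2, 2), ei = ei,
                 edges = data.frame(from = 1L, to = 2L),
                 n = 2L, side_um = 100, periodic = FALSE, seed = 1L),
            class = "culture_network")
}

test_that("network growth respects geometry", {
  # neurons ~14 mm apart with ~120 um axons: no connections possible
  n <- 20
  res <- avalanchr:::cpp_build_network(
    1e4 * seq_len(n), 1e4 * seq_len(n), rep(150, n), rep(120, n),
    10, 15 * pi / 180, 1.0, 2e5, 2e5, FALSE, FALSE, 5)
  expect_length(res$from, 0L)

  # connection probability 0 gives an empty adjacency
  net0 <- culture_network(side_length_mm = 0.4, p_conn = 0, seed = 2)
  expect_equal(nrow(net0$edges), 0L)

  # determinism under seed
  n1 <- culture_network(side_length_mm = 0.4, seed = 11)
  n2 <- culture_network(side_length_mm = 0.4, seed = 11)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$positions, n2$positions)

  # ~20% inhibitory
  expect_equal(mean(n1$ei == "I"), 0.2, tolerance = 0.02)
  # no self-connections
  expect_true(all(n1$edges$from != n1$edges$to))
})

test_that("realized out-degree matches a brute-force geometric oracle", {
  # every connection's axon polyline must intersect the target's dendritic
  # disk; the expected edge count is p_conn * (number of crossing pairs)
  net <- culture_network(side_length_mm = 0.5, keep_geometry = TRUE,
                         seed = 13)
  crossings <- 0L
  for (i in seq_len(net$n)) {
    ax <- net$axons[[i]]
    p0 <- ax[-nrow(ax), , drop = FALSE]
    p1 <- ax[-1, , drop = FALSE]
    ux <- p1[, 1] - p0[, 1]; uy <- p1[, 2] - p0[, 2]
    len2 <- ux^2 + uy^2
    for (j in seq_len(net$n)) {
      if (i == j) next
      cx <- net$positions[j, 1] - p0[, 1]
      cy <- net$positions[j, 2] - p0[, 2]
      tt <- pmin(pmax((cx * ux + cy * uy) / pmax(len2, 1e-12), 0), 1)
      d2 <- (cx - tt * ux)^2 + (cy - tt * uy)^2
      if (any(d2 <= net$dend_radius[j]^2)) crossings <- crossings + 1L
    }
  }
  expected <- 0.13 * crossings
  sd_bin <- sqrt(crossings * 0.13 * 0.87)
  expect_lt(abs(nrow(net$edges) - expected), 4 * sd_bin + 1)
})

test_that("silent limit: no noise, no minis, no input means no spikes", {
  r <- simulate_culture(lone_neuron(), duration_s = 5,
                        params = neuron_params(g_s = 0, lambda_mini = 0),
                        seed = 3)
  expect_equal(n_spikes(r), 0L)
})

test_that("mini-driven spontaneous rate is of order 0.1 Hz", {
  r <- simulate_culture(lone_neuron(), duration_s = 200, seed = 42)
  rate <- n_spikes(r) / 200
  expect_gt(rate, 0.1 / 3)
  expect_lt(rate, 0.1 * 3)
})

test_that("simulation is deterministic under a fixed seed", {
  net <- two_neurons()
  r1 <- simulate_culture(net, duration_s = 20, seed = 8)
  r2 <- simulate_culture(net, duration_s = 20, seed = 8)
  expect_identical(r1$time, r2$time)
  expect_identical(r1$neuron, r2$neuron)
  r3 <- simulate_culture(net, duration_s = 20, seed = 9)
  expect_false(identical(r1$time, r3$time))
})

test_that("depression bounds and reset semantics", {
  # tonically driven deterministic neuron: I_ext above the excitability
  # barrier, no noise, no minis
  dt <- 0.1
  r <- simulate_culture(lone_neuron(), duration_s = 10,
                        params = neuron_params(g_s = 0, lambda_mini = 0),
                        I_ext = 100, seed = 4, record_neuron = 1)
  st <- attr(r, "state")
  expect_gt(n_spikes(r), 10)
  # D stays in (0, 1] throughout
  expect_true(all(st$D > 0 & st$D <= 1))
  spike_steps <- round(r$time * 1000 / dt)
  # immediately after each spike v = v_c
  expect_true(all(abs(st$v[spike_steps] - (-50)) < 1e-9))
  # u jumps by exactly d on top of its Euler increment
  pre <- spike_steps[-1] - 1L
  u_before <- st$u[pre]
  v_before <- st$v[pre]
  euler_inc <- (dt / 33) * (-2 * (v_before - (-60)) - u_before)
  expect_true(all(abs(st$u[pre + 1L] - (u_before + euler_inc + 100)) < 1e-9))
  # between consecutive spikes D recovers toward 1 with time constant
  # tau_D (2 s for an excitatory cell), discretized by forward Euler
  gap <- which(diff(spike_steps) == max(diff(spike_steps)))[1]
  i0 <- spike_steps[gap]; i1 <- spike_steps[gap + 1] - 1L
  steps <- i1 - i0
  predicted <- 1 - (1 - st$D[i0]) * (1 - dt / 2000)^steps
  expect_equal(st$D[i1], predicted, tolerance = 1e-6)
})

test_that("population variants produce the documented compositions", {
  net <- culture_network(side_length_mm = 0.5, seed = 21)
  pp_h <- apply_variant(net, "heterogeneous", seed = 1)
  expect_equal(sum(pp_h$is_inh), round(0.2 * net$n))
  expect_equal(sum(pp_h$bursty), round(0.1 * net$n))
  expect_equal(sum(!pp_h$is_inh & !pp_h$bursty), net$n - round(0.2 * net$n) -
                 round(0.1 * net$n))
  # bursty overrides
  expect_true(all(pp_h$v_c[pp_h$bursty] == -40))
  expect_true(all(pp_h$d[pp_h$bursty] == 50))
  # excitatory resting potentials: -62 plus a non-negative Rayleigh offset
  expect_true(all(pp_h$v_r[!pp_h$is_inh] >= -62))
  # inhibition blocked: inhibitory outputs zeroed, identity on E cells
  pp_b <- apply_variant(net, inhibition_blocked = TRUE)
  expect_true(all(pp_b$g_out[pp_b$is_inh] == 0))
  expect_true(all(pp_b$g_out[!pp_b$is_inh] == 40))
  # no-op when there are no inhibitory cells
  net_e <- net; net_e$ei <- rep("E", net$n)
  expect_equal(apply_variant(net_e, inhibition_blocked = TRUE)$g_out,
               apply_variant(net_e)$g_out)
})

test_that("branching process matches closed-form small cases", {
  set.seed(2)
  # m = 0: every avalanche is a single activation
  b0 <- branching_process(500, m = 0)$avalanches
  expect_true(all(b0$S == 1))
  expect_true(all(b0$T == 1))
  # m = 0.5: mean size 1/(1-m) = 2
  b5 <- branching_process(20000, m = 0.5)$avalanches
  expect_equal(mean(b5$S), 2, tolerance = 0.05)
  expect_true(all(b5$S >= b5$T))
  # capping flags long-lived critical avalanches
  bc <- branching_process(5000, m = 1, max_generations = 50)$avalanches
  expect_true(any(bc$capped))
  expect_true(all(bc$T[bc$capped] == 50))
})
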