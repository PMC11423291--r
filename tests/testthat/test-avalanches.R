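binned_totals <- function(totals, bin_width = 0.005) {
  # build a one-neuron binned raster with prescribed per-bin totals
  t <- unlist(lapply(seq_along(totals), function(j)
    if (totals[j] > 0) (j - 1) * bin_width + seq_len(totals[j]) * bin_width /
      (totals[j] + 1)))
  r <- spike_raster(rep(1L, length(t)), t,
                    duration = length(totals) * bin_width)
  bin_raster(r, bin_width)
}

test_that("avalanche detection finds maximal runs of occupied bins", {
  b <- binned_totals(c(0, 2, 1, 0, 0, 3, 0))
  av <- detect_avalanches(b)$avalanches
  expect_equal(av$S, c(3L, 3L))
  expect_equal(av$T, c(2L, 1L))
  expect_equal(av$start_bin, c(2L, 6L))

  # all bins occupied: one avalanche
  av1 <- detect_avalanches(binned_totals(c(1, 1, 1, 1)))$avalanches
  expect_equal(nrow(av1), 1L)
  expect_equal(av1$S, 4L)
  expect_equal(av1$T, 4L)

  # empty input
  silent <- spike_raster(integer(0), numeric(0), n_neurons = 2,
                         duration = 0.1)
  expect_equal(nrow(detect_avalanches(bin_raster(silent, 0.005))$avalanches),
               0L)
})

test_that("interval boundaries cut runs", {
  b <- binned_totals(c(1, 1, 1, 1, 1, 1))
  av <- detect_avalanches(b, boundaries = 3 * 0.005)$avalanches
  expect_equal(nrow(av), 2L)
  expect_equal(av$T, c(3L, 3L))
})

test_that("avalanche invariants hold on random rasters", {
  for (seed in 1:4) {
    r <- poisson_raster(30, rate = 8, duration = 5, seed = seed)
    av <- state_avalanches(r, bin_width = 0.01)
    a <- av$avalanches
    # conservation: sizes sum to all spikes
    expect_equal(sum(a$S), n_spikes(r))
    expect_true(all(a$S >= a$T))
    expect_true(all(a$T >= 1))
    # count non-increasing under aligned bin doubling
    n1 <- nrow(a)
    n2 <- nrow(state_avalanches(r, bin_width = 0.02)$avalanches)
    expect_lte(n2, n1)
  }
})

test_that("state restriction censors spikes and avalanches correctly", {
  seg <- structure(list(
    intervals = data.frame(start = c(0, 1, 2, 3, 4),
                           end = c(1, 2, 3, 4, 5),
                           label = c("down", "up", "down", "up", "down")),
    t_up = c(1, 1), t_down = 1, frame_width = 0.005, duration = 5),
    class = "state_segmentation")
  times <- c(0.5, 1.2, 1.8, 2.5, 3.1, 3.9, 4.5, 1.5, 3.5, 0.9)
  r <- spike_raster(rep(1:2, c(7, 3)), times, n_neurons = 2, duration = 5)

  up <- restrict_to_state(r, seg, "up")
  expect_equal(n_spikes(up), 6L)   # brute-force membership count
  expect_true(all((up$time >= 1 & up$time < 2) |
                    (up$time >= 3 & up$time < 4)))
  dn <- restrict_to_state(r, seg, "down")
  expect_equal(n_spikes(dn) + n_spikes(up), n_spikes(r))

  # all-up segmentation is the identity on spikes
  seg_all <- structure(list(
    intervals = data.frame(start = 0, end = 5, label = "up"),
    t_up = numeric(0), t_down = numeric(0), frame_width = 0.005,
    duration = 5), class = "state_segmentation")
  expect_equal(n_spikes(restrict_to_state(r, seg_all, "up")), n_spikes(r))
  expect_warning(empty <- restrict_to_state(r, seg_all, "down"), "no 'down'")
  expect_equal(n_spikes(empty), 0L)

  # avalanches never bridge two up intervals: spikes at the edges of the
  # two up intervals stay in separate avalanches even at huge bin width
  av <- state_avalanches(up, bin_width = 5)$avalanches
  expect_equal(nrow(av), 2L)
})

test_that("patch subsampling has the right size, determinism and pooling", {
  r <- poisson_raster(40, 3, 4, seed = 2)
  ps <- sample_patches(r, fraction = 0.5, n_patches = 5, seed = 99)
  expect_length(ps, 5)
  expect_true(all(vapply(ps, function(p) p$n_neurons, 0L) == 20L))
  ps2 <- sample_patches(r, fraction = 0.5, n_patches = 5, seed = 99)
  expect_identical(lapply(ps2, `[[`, "time"), lapply(ps, `[[`, "time"))

  # fraction 1, one patch: the original raster
  p1 <- sample_patches(r, fraction = 1, n_patches = 1, seed = 1)[[1]]
  expect_equal(n_spikes(p1), n_spikes(r))
  expect_error(sample_patches(r, fraction = 0), "fraction")
  expect_error(sample_patches(r, mode = "circular", radius = 10),
               "positions")

  # circular mode keeps only in-disk neurons
  r$positions <- cbind(seq(0, 390, by = 10), rep(0, 40))
  pc <- sample_patches(r, mode = "circular", fraction = 1, n_patches = 1,
                       radius = 100, center = c(0, 0), seed = 1)[[1]]
  expect_equal(pc$n_neurons, 11L)  # x = 0..100

  # pooled size histogram equals the sum of per-patch histograms
  pooled <- unlist(lapply(ps, function(p)
    state_avalanches(p, 0.01)$avalanches$S))
  per_patch <- lapply(ps, function(p)
    table(factor(state_avalanches(p, 0.01)$avalanches$S,
                 levels = sort(unique(pooled)))))
  expect_equal(as.vector(Reduce(`+`, per_patch)),
               as.vector(table(factor(pooled,
                                      levels = sort(unique(pooled))))))
})

test_that("gamma estimation recovers exact power-law size-duration scaling", {
  S <- round(10^seq(0.2, 4, length.out = 4000))
  # exact gamma = 0.5
  g <- mean_duration_vs_size(S, pmax(1, round(sqrt(S))), min_count = 1)
  expect_true(g$ok)
  expect_equal(g$gamma, 0.5, tolerance = 0.02)
  # identity scaling gamma = 1
  g1 <- mean_duration_vs_size(S, S, min_count = 1)
  expect_equal(g1$gamma, 1, tolerance = 0.01)
  # degenerate data flagged
  expect_false(mean_duration_vs_size(rep(7, 100), rep(3, 100))$ok)
})

test_that("per-state ISIs never bridge a state transition", {
  seg <- structure(list(
    intervals = data.frame(start = c(0, 1, 2, 3, 4),
                           end = c(1, 2, 3, 4, 5),
                           label = c("down", "up", "down", "up", "down")),
    t_up = c(1, 1), t_down = 1, frame_width = 0.005, duration = 5),
    class = "state_segmentation")
  # one neuron spiking every 100 ms inside the first up interval
  t_up1 <- seq(1.05, 1.95, by = 0.1)
  # plus one spike in each up interval: no ISI across the down state
  r <- spike_raster(c(rep(1L, length(t_up1)), 2L, 2L),
                    c(t_up1, 1.5, 3.5), n_neurons = 2, duration = 5)
  isi <- isi_stats(r, seg)
  up_row <- isi[isi$state == "up", ]
  expect_equal(up_row$mean_isi, 0.1, tolerance = 1e-9)
  expect_equal(up_row$n_isi, length(t_up1) - 1L)  # neuron 2 contributes none
  expect_equal(isi[isi$state == "down", ]$n_isi, 0L)
})
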