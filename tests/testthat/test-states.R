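make_trace <- function(values, frame_width = 0.005) {
  structure(list(values = values, frame_width = frame_width,
                 smoothed = FALSE, sigma_frames = NA_real_),
            class = "rate_trace")
}

test_that("population rate is the normalized per-frame spike count", {
  r <- spike_raster(rep(1:10, each = 1), rep(0.001, 10) + (0:9) * 1e-5,
                    n_neurons = 100, duration = 0.015)
  b <- bin_raster(r, 0.005)
  tr <- population_rate(b)
  expect_equal(tr$values[1], 10 / 100)
  expect_equal(tr$values[-1], rep(0, length(tr$values) - 1))
  # explicit n_neurons overrides
  expect_equal(population_rate(b, 10)$values[1], 1)
  expect_error(population_rate(b, 0), "n_neurons")

  silent <- spike_raster(integer(0), numeric(0), n_neurons = 5, duration = 0.05)
  expect_true(all(population_rate(bin_raster(silent, 0.005))$values == 0))
})

test_that("Gaussian smoothing is unit-sum, shape-correct and conservative", {
  # constant trace is a fixed point
  tr <- make_trace(rep(0.4, 100))
  expect_equal(smooth_rate(tr, 5)$values, rep(0.4, 100), tolerance = 1e-12)

  # interior unit impulse reproduces the normalized discrete Gaussian
  n <- 201
  imp <- make_trace(c(rep(0, 100), 1, rep(0, 100)))
  sm <- smooth_rate(imp, 5)$values
  half <- ceiling(4 * 5)
  kern <- dnorm(seq(-half, half), sd = 5); kern <- kern / sum(kern)
  expect_equal(sm[(101 - half):(101 + half)], kern, tolerance = 1e-12)
  expect_equal(max(sm), kern[half + 1])
  expect_equal(which.max(sm), 101)
  # kernel normalization conserves the mass of an interior impulse
  expect_equal(sum(sm), 1, tolerance = 1e-12)

  expect_error(smooth_rate(imp, 0), "sigma")
})

test_that("Schmitt trigger implements hysteretic up/down switching", {
  # hand-executed state machine: up starts at frame 2, band keeps it,
  # drops below lower at frame 5
  tr <- make_trace(c(0.0002, 0.002, 0.0005, 0.0005, 0.0001))
  seg <- schmitt_segment(tr, upper = 0.001, lower = 0.0003)
  expect_equal(seg$intervals$label, c("down", "up", "down"))
  expect_equal(seg$intervals$start, c(0, 1, 4) * 0.005)
  expect_equal(seg$intervals$end, c(1, 4, 5) * 0.005)

  # constant above upper: single up interval spanning the trace
  hi <- make_trace(rep(0.01, 50))
  seg_hi <- schmitt_segment(hi)
  expect_equal(seg_hi$intervals$label, "up")
  expect_equal(nrow(seg_hi$intervals), 1L)
  expect_equal(seg_hi$intervals$end - seg_hi$intervals$start, 50 * 0.005)

  # constant below lower: single down interval
  lo <- make_trace(rep(1e-5, 50))
  expect_equal(schmitt_segment(lo)$intervals$label, "down")

  expect_error(schmitt_segment(tr, upper = 0.0003, lower = 0.001), "upper")
})

test_that("segmentation is invariant to in-band perturbations and rescaling", {
  set.seed(5)
  base <- abs(sin(seq(0, 8 * pi, length.out = 400))) * 0.002
  tr <- make_trace(base)
  seg <- schmitt_segment(tr)
  # perturb frames strictly inside the open band without crossing
  v <- base
  in_band <- v > 0.0003 & v < 0.001
  v[in_band] <- runif(sum(in_band), 0.00035, 0.00095)
  seg2 <- schmitt_segment(make_trace(v))
  expect_equal(seg2$intervals, seg$intervals)

  # common positive rescaling of trace and thresholds changes nothing
  seg3 <- schmitt_segment(make_trace(base * 7.3), upper = 0.001 * 7.3,
                          lower = 0.0003 * 7.3)
  expect_equal(seg3$intervals$label, seg$intervals$label)
  expect_equal(seg3$intervals$start, seg$intervals$start)

  # intervals tile the trace exactly
  expect_equal(sum(seg$intervals$end - seg$intervals$start), seg$duration)
  # alternation
  labs <- seg$intervals$label
  expect_true(all(labs[-1] != labs[-length(labs)]))
})

test_that("state duration statistics summarize uncensored intervals", {
  seg <- structure(list(
    intervals = data.frame(start = c(0, 1, 2, 3, 4, 5, 7, 8),
                           end = c(1, 2, 3, 4, 5, 7, 8, 9),
                           label = rep(c("down", "up"), 4)),
    t_up = c(1, 1, 1), t_down = c(2, 4), frame_width = 0.005,
    duration = 9), class = "state_segmentation")
  st <- state_duration_stats(seg)
  expect_equal(st$up$mean, 1)
  expect_equal(st$down$mean, 3)
  # degenerate distribution: normalized PDF mass entirely at 1
  expect_equal(st$up$pdf_normalized$mid, 1)
  seg$t_down <- numeric(0)
  expect_warning(st2 <- state_duration_stats(seg), "down")
  expect_null(st2$down)
})
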