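#' Restrict a raster to one state
#'
#' Keeps only the spikes falling inside intervals of the requested label and
#' records those intervals on the returned raster (`$state_intervals`), so
#' that avalanche detection never bridges two intervals of the same state
#' across an intervening opposite state.
#'
#' @param raster a [spike_raster()].
#' @param seg a `state_segmentation` from [schmitt_segment()].
#' @param state `"up"` or `"down"`.
#' @return A [spike_raster()] with an extra element `state_intervals`
#'   (data.frame `start`, `end`).
#' @export
restrict_to_state <- function(raster, seg, state = c("up", "down")) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(seg, "state_segmentation"))
  state <- match.arg(state)
  iv <- seg$intervals[seg$intervals$label == state, , drop = FALSE]
  if (!nrow(iv)) {
    warning("no '", state, "' intervals in the segmentation; empty raster")
    out <- spike_raster(integer(0), numeric(0), n_neurons = raster$n_neurons,
                        duration = raster$duration,
                        frame_interval = raster$frame_interval,
                        positions = raster$positions, ei = raster$ei)
    out$state_intervals <- data.frame(start = numeric(0), end = numeric(0))
    return(out)
  }
  # intervals are ordered and disjoint: membership via findInterval
  k <- findInterval(raster$time, iv$start)
  keep <- k >= 1 & raster$time < iv$end[pmax(k, 1L)]
  out <- raster
  out$neuron <- raster$neuron[keep]
  out$time <- raster$time[keep]
  out$state_intervals <- iv[, c("start", "end")]
  out
}

.avalanches_from_totals <- function(totals) {
  nz <- totals > 0
  if (!any(nz)) {
    return(data.frame(start_bin = integer(0), T = integer(0), S = integer(0)))
  }
  d <- diff(c(0L, as.integer(nz), 0L))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  cs <- c(0, cumsum(totals))
  data.frame(start_bin = starts,
             T = ends - starts + 1L,
             S = as.integer(cs[ends + 1L] - cs[starts]))
}

#' Detect neuronal avalanches in a binned raster
#'
#' An avalanche is a maximal sequence of consecutive time bins that each
#' contain at least one spike (from any neuron), bounded by empty bins. Its
#' duration `T` is the number of bins in the run and its size `S` the total
#' number of spikes. When `boundaries` is given (interval edge times, e.g.
#' state-interval edges), runs are additionally cut at those edges so that an
#' avalanche never spans two analysis intervals.
#'
#' @param binned a `binned_raster`.
#' @param boundaries optional numeric vector of interval edge times
#'   (seconds) at which runs must be cut.
#' @return An `avalanche_set`: list with `avalanches` (data.frame
#'   `start_bin`, `T`, `S`), `bin_width`, `state`, `patch_id`, `n_spikes`.
#' @export
detect_avalanches <- function(binned, boundaries = NULL) {
  stopifnot(inherits(binned, "binned_raster"))
  totals <- as.numeric(Matrix::colSums(binned$counts))
  if (is.null(boundaries)) {
    av <- .avalanches_from_totals(totals)
  } else {
    cut_bins <- unique(pmin(pmax(ceiling(
      (boundaries - binned$origin) / binned$bin_width), 0), length(totals)))
    edges <- sort(unique(c(0L, as.integer(cut_bins), length(totals))))
    pieces <- lapply(seq_len(length(edges) - 1L), function(i) {
      lo <- edges[i] + 1L; hi <- edges[i + 1L]
      a <- .avalanches_from_totals(totals[lo:hi])
      a$start_bin <- a$start_bin + lo - 1L
      a
    })
    av <- do.call(rbind, pieces)
  }
  structure(list(avalanches = av, bin_width = binned$bin_width,
                 state = "all", patch_id = NA_integer_,
                 n_spikes = as.integer(sum(totals))),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf(
    "Avalanche set: %d avalanches (%d spikes) at bin width %.4g ms [%s]\n",
    nrow(x$avalanches), x$n_spikes, 1000 * x$bin_width, x$state))
  invisible(x)
}

#' Per-state avalanche detection with interval-local bin grids
#'
#' Detects avalanches separately inside each state interval, with the bin
#' grid restarting at every interval start (this avoids partial bins of
#' heterogeneous width inside intervals and guarantees that no avalanche
#' crosses a state transition).
#'
#' @param raster a [spike_raster()], typically from [restrict_to_state()].
#' @param bin_width bin width in seconds.
#' @param intervals data.frame with `start`, `end` (seconds); defaults to
#'   the raster's recorded `state_intervals`, or to the whole recording.
#' @param state label stored on the result.
#' @return An `avalanche_set`.
#' @export
state_avalanches <- function(raster, bin_width, intervals = NULL,
                             state = "all") {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(intervals)) intervals <- raster$state_intervals
  if (is.null(intervals))
    intervals <- data.frame(start = 0, end = raster$duration)
  t <- sort(raster$time)
  # locate each interval's spike slice by binary search
  lo_idx <- findInterval(intervals$start, t, left.open = TRUE) + 1L
  hi_idx <- findInterval(intervals$end, t, left.open = TRUE)
  pieces <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (hi_idx[i] < lo_idx[i]) next
    ti <- t[lo_idx[i]:hi_idx[i]]
    ti <- ti[ti < e]   # half-open interval
    if (!length(ti)) next
    nb <- max(1L, as.integer(ceiling((e - s) / bin_width - 1e-9)))
    totals <- tabulate(pmin(as.integer(floor((ti - s) / bin_width)) + 1L, nb),
                       nbins = nb)
    a <- .avalanches_from_totals(totals)
    if (nrow(a)) {
      a$interval <- i
      pieces[[i]] <- a
    }
  }
  av <- do.call(rbind, pieces)
  if (is.null(av))
    av <- data.frame(start_bin = integer(0), T = integer(0), S = integer(0),
                     interval = integer(0))
  structure(list(avalanches = av, bin_width = bin_width, state = state,
                 patch_id = NA_integer_,
                 n_spikes = sum(av$S)),
            class = "avalanche_set")
}

#' Subsample neuron patches from a raster
#'
#' Emulates restricted fields of view: either a random fraction of the
#' population (`mode = "random_fraction"`), or a circular spatial patch of
#' given radius followed by the random fraction (`mode = "circular"`,
#' requires positions). Patches are drawn independently; with a fixed seed
#' the patch membership is reproducible.
#'
#' @param raster a [spike_raster()].
#' @param mode `"random_fraction"` or `"circular"`.
#' @param fraction fraction of (patch) neurons kept, in (0, 1].
#' @param n_patches number of patches.
#' @param radius patch radius in micrometres (circular mode).
#' @param center patch centre `c(x, y)` in micrometres (circular mode);
#'   defaults to the centroid of the positions.
#' @param seed optional RNG seed (integer); uses the current R RNG stream
#'   when `NULL`.
#' @return A list of [spike_raster()] objects (each keeps the
#'   `state_intervals` of the input, if present).
#' @export
sample_patches <- function(raster, mode = c("random_fraction", "circular"),
                           fraction = 0.5, n_patches = 100,
                           radius = NULL, center = NULL, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pool <- seq_len(raster$n_neurons)
  if (mode == "circular") {
    if (is.null(raster$positions))
      stop("circular patches require neuron positions")
    if (is.null(radius)) stop("circular patches require a radius")
    if (is.null(center)) center <- colMeans(raster$positions)
    d2 <- (raster$positions[, 1] - center[1])^2 +
      (raster$positions[, 2] - center[2])^2
    pool <- pool[d2 <= radius^2]
    if (!length(pool)) stop("no neurons inside the circular patch")
  }
  k <- max(1L, floor(fraction * length(pool)))
  lapply(seq_len(n_patches), function(p) {
    ids <- if (k == length(pool)) pool else sort(sample(pool, k))
    out <- subset_neurons(raster, ids)
    out$state_intervals <- raster$state_intervals
    out
  })
}

#' Size--duration scaling exponent gamma
#'
#' Estimates the exponent `gamma` of the conditional mean duration versus
#' size law `<T>(S) ~ S^gamma` by averaging `T` within logarithmically
#' spaced size classes and fitting a least-squares line to
#' `log10 <T>` versus `log10 S` (class geometric mean of the sizes).
#' Classes below `s_min` are excluded (discreteness corrections dominate at
#' the smallest sizes) as are classes with fewer than `min_count` avalanches.
#'
#' @param S,T integer vectors of avalanche sizes and durations (paired), or
#'   an `avalanche_set` as `S` with `T` missing.
#' @param n_per_decade number of size classes per decade.
#' @param s_min smallest size entering the fit.
#' @param min_count minimum avalanches per class.
#' @return A list with `gamma`, `se`, `n_classes`, `classes` (data.frame
#'   `s_mid`, `t_mean`, `count`). `gamma` is `NA` (flagged via `ok = FALSE`)
#'   when fewer than 3 usable classes exist.
#' @export
mean_duration_vs_size <- function(S, T = NULL, n_per_decade = 8, s_min = 10,
                                  min_count = 10) {
  if (inherits(S, "avalanche_set")) {
    T <- S$avalanches$T
    S <- S$avalanches$S
  }
  stopifnot(length(S) == length(T))
  keep <- S >= 1 & T >= 1
  S <- S[keep]; T <- T[keep]
  if (length(unique(S)) < 2)
    return(list(gamma = NA_real_, se = NA_real_, n_classes = 0L,
                classes = NULL, ok = FALSE))
  ls <- log10(S)
  breaks <- seq(floor(min(ls) * n_per_decade) / n_per_decade,
                max(ls) + 1 / n_per_decade, by = 1 / n_per_decade)
  cls <- findInterval(ls, breaks, rightmost.closed = TRUE)
  t_mean <- tapply(T, cls, mean)
  s_mid <- 10^tapply(ls, cls, mean)
  count <- as.integer(table(cls))
  classes <- data.frame(class = as.integer(names(t_mean)),
                        s_mid = as.numeric(s_mid),
                        t_mean = as.numeric(t_mean), count = count)
  classes <- classes[order(classes$s_mid), ]
  use <- classes$count >= min_count & classes$s_mid >= s_min
  # restrict to the contiguous scaling range: occupied classes separated
  # from the main body by a gap of empty or under-populated classes (e.g.
  # detached whole-burst events) would otherwise dominate the fit through
  # leverage
  idx <- which(use)
  if (length(idx) > 1) {
    gap <- which(diff(classes$class[idx]) > 1)
    if (length(gap)) use[idx[(gap[1] + 1):length(idx)]] <- FALSE
  }
  if (sum(use) < 3) {
    return(list(gamma = NA_real_, se = NA_real_, n_classes = sum(use),
                classes = classes, ok = FALSE))
  }
  fit <- stats::lm(log10(t_mean) ~ log10(s_mid), data = classes[use, ])
  list(gamma = unname(stats::coef(fit)[2]),
       se = unname(sqrt(diag(stats::vcov(fit)))[2]),
       n_classes = sum(use), classes = classes, ok = TRUE)
}

#' Per-state single-cell interspike intervals
#'
#' Computes interspike intervals between consecutive spikes of the same
#' neuron that fall within the same state interval (an ISI never bridges a
#' state transition), pools them over neurons, and reports the mean per
#' state.
#'
#' @param raster a [spike_raster()].
#' @param seg a `state_segmentation`.
#' @return A data.frame with one row per state: `state`, `mean_isi` (s),
#'   `n_isi`.
#' @export
isi_stats <- function(raster, seg) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(seg, "state_segmentation"))
  iv <- seg$intervals
  k <- findInterval(raster$time, iv$start)
  inside <- k >= 1 & raster$time < iv$end[pmax(k, 1L)]
  one_state <- function(state) {
    sel <- inside & iv$label[pmax(k, 1L)] == state
    nrn <- raster$neuron[sel]; tm <- raster$time[sel]; ivl <- k[sel]
    if (length(tm) < 2) return(c(mean = NA_real_, n = 0))
    # data are neuron-major, time-ascending: consecutive rows of the same
    # neuron in the same interval are consecutive spikes
    same <- nrn[-1] == nrn[-length(nrn)] & ivl[-1] == ivl[-length(ivl)]
    isis <- (tm[-1] - tm[-length(tm)])[same]
    c(mean = if (length(isis)) mean(isis) else NA_real_, n = length(isis))
  }
  up <- one_state("up"); dn <- one_state("down")
  data.frame(state = c("up", "down"),
             mean_isi = c(up["mean"], dn["mean"]),
             n_isi = as.integer(c(up["n"], dn["n"])),
             row.names = NULL)
}
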