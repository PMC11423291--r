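#' Spike raster objects
#'
#' A `spike_raster` holds per-neuron spike times from a population recording
#' (calcium-imaging spike inference or simulation output), together with the
#' recording metadata needed downstream: the number of observed neurons
#' (including silent ones, which enter rate normalization), the recording
#' duration, the acquisition frame interval (5 ms for 200 fps imaging, the
#' integration step for simulations), and optionally per-neuron spatial
#' positions (micrometres) and excitatory/inhibitory labels.
#'
#' Internally spikes are stored in long format (one row per spike), sorted by
#' neuron then time. Neuron ids are integers in `1:n_neurons`; neurons without
#' spikes are legitimate members of the population.
#'
#' @param neuron integer vector of neuron ids (1-based), one entry per spike.
#' @param time numeric vector of spike times in seconds, same length as
#'   `neuron`.
#' @param n_neurons number of neurons in the observed population. Defaults to
#'   `max(neuron)` (0 for an empty raster).
#' @param duration recording duration in seconds. Defaults to the last spike
#'   time.
#' @param frame_interval acquisition frame width in seconds (default 0.005,
#'   i.e. 200 fps).
#' @param positions optional numeric matrix (`n_neurons` x 2) of (x, y)
#'   positions in micrometres.
#' @param ei optional character vector of length `n_neurons` with values
#'   `"E"` or `"I"`.
#' @return An object of class `spike_raster`.
#' @examples
#' r <- spike_raster(neuron = c(1L, 2L, 1L), time = c(0.010, 0.020, 0.030))
#' n_spikes(r)
#' @export
spike_raster <- function(neuron, time, n_neurons = NULL, duration = NULL,
                         frame_interval = 0.005, positions = NULL, ei = NULL) {
  neuron <- as.integer(neuron)
  time <- as.numeric(time)
  if (length(neuron) != length(time))
    stop("'neuron' and 'time' must have the same length")
  if (anyNA(neuron) || anyNA(time))
    stop("spike table contains missing values")
  if (length(time) && any(time < 0))
    stop("negative spike times are not allowed")
  if (length(neuron) && any(neuron < 1L))
    stop("neuron ids must be >= 1")
  if (is.null(n_neurons)) n_neurons <- if (length(neuron)) max(neuron) else 0L
  n_neurons <- as.integer(n_neurons)
  if (length(neuron) && n_neurons < max(neuron))
    stop("n_neurons is smaller than the largest neuron id")
  if (is.null(duration)) duration <- if (length(time)) max(time) else 0
  duration <- as.numeric(duration)
  if (length(time) && any(time > duration))
    stop("spike times beyond the stated duration")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  ord <- order(neuron, time)
  neuron <- neuron[ord]; time <- time[ord]
  if (length(time) > 1) {
    same <- neuron[-1] == neuron[-length(neuron)] &
      time[-1] == time[-length(time)]
    if (any(same))
      stop("duplicate spike times within a neuron")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_neurons || ncol(positions) != 2)
      stop("'positions' must be an n_neurons x 2 matrix")
  }
  if (!is.null(ei)) {
    ei <- as.character(ei)
    if (length(ei) != n_neurons || !all(ei %in% c("E", "I")))
      stop("'ei' must have one \"E\"/\"I\" entry per neuron")
  }
  structure(
    list(neuron = neuron, time = time, n_neurons = n_neurons,
         duration = duration, frame_interval = frame_interval,
         positions = positions, ei = ei),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d neurons, %d spikes, %.3f s (frame %.4g ms)\n",
              x$n_neurons, length(x$time), x$duration,
              1000 * x$frame_interval))
  if (!is.null(x$positions)) cat("  with spatial positions (um)\n")
  if (!is.null(x$ei))
    cat(sprintf("  E/I labels: %d E, %d I\n", sum(x$ei == "E"),
                sum(x$ei == "I")))
  invisible(x)
}

#' Number of spikes in a raster
#' @param raster a `spike_raster`.
#' @return Integer spike count.
#' @export
n_spikes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  length(raster$time)
}

#' Keep a subset of neurons
#'
#' Restricts a raster to the given neuron ids. Ids are renumbered to
#' `1:length(ids)` (in the order given); positions and E/I labels follow.
#'
#' @param raster a `spike_raster`.
#' @param ids integer vector of neuron ids to keep.
#' @return A `spike_raster` over the selected neurons.
#' @export
subset_neurons <- function(raster, ids) {
  stopifnot(inherits(raster, "spike_raster"))
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("duplicate neuron ids in subset")
  if (length(ids) && (min(ids) < 1L || max(ids) > raster$n_neurons))
    stop("neuron ids outside the population")
  keep <- raster$neuron %in% ids
  map <- integer(raster$n_neurons)
  map[ids] <- seq_along(ids)
  spike_raster(map[raster$neuron[keep]], raster$time[keep],
               n_neurons = length(ids), duration = raster$duration,
               frame_interval = raster$frame_interval,
               positions = if (!is.null(raster$positions))
                 raster$positions[ids, , drop = FALSE],
               ei = if (!is.null(raster$ei)) raster$ei[ids])
}

#' Read a spike raster from a delimited file
#'
#' The delimited format is UTF-8 text with two columns, `neuron_id` (integer,
#' 1-based) and `time_s` (seconds), separated by commas or tabs. Lines
#' beginning with `#` are metadata of the form `# key = value` and may declare
#' `n_neurons`, `duration`, and `frame_interval`; `# positions:` and
#' `# ei:` introduce inline per-neuron blocks written by
#' [write_spike_raster()]. A column header line (`neuron_id,time_s`) is
#' optional.
#'
#' @param path path to the file.
#' @return A [spike_raster()].
#' @seealso [write_spike_raster()]
#' @export
read_spike_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  positions <- NULL; ei <- NULL
  header_idx <- grep("^#", lines)
  for (i in header_idx) {
    ln <- sub("^#\\s*", "", lines[i])
    if (grepl("^positions:", ln)) {
      vals <- strsplit(sub("^positions:\\s*", "", ln), ";", fixed = TRUE)[[1]]
      positions <- do.call(rbind, lapply(strsplit(vals, ","), as.numeric))
    } else if (grepl("^ei:", ln)) {
      ei <- strsplit(sub("^ei:\\s*", "", ln), "", fixed = TRUE)[[1]]
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  data_lines <- if (length(header_idx)) lines[-header_idx] else lines
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  # drop an optional column-name header
  if (length(data_lines) && grepl("neuron", data_lines[1], ignore.case = TRUE))
    data_lines <- data_lines[-1]
  if (length(data_lines)) {
    parts <- strsplit(data_lines, "[,\t]")
    nf <- lengths(parts)
    if (any(nf != 2))
      stop("malformed row at line ", which(nf != 2)[1], " of the data block")
    neuron <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    time <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    bad <- which(is.na(neuron) | is.na(time))
    if (length(bad))
      stop("malformed row at line ", bad[1], " of the data block")
  } else {
    neuron <- integer(0); time <- numeric(0)
  }
  spike_raster(
    neuron, time,
    n_neurons = if (!is.null(meta$n_neurons)) as.integer(meta$n_neurons),
    duration = if (!is.null(meta$duration)) as.numeric(meta$duration),
    frame_interval = if (!is.null(meta$frame_interval))
      as.numeric(meta$frame_interval) else 0.005,
    positions = positions, ei = ei)
}

#' Write a spike raster to a delimited file
#'
#' Writes the format documented in [read_spike_raster()]: metadata header
#' lines, then one `neuron_id,time_s` row per spike. Spike times are written
#' with full double precision (17 significant digits), so a write/read
#' round trip reproduces the raster exactly.
#'
#' @param raster a [spike_raster()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_spike_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_neurons = %d", raster$n_neurons),
    sprintf("# duration = %.17g", raster$duration),
    sprintf("# frame_interval = %.17g", raster$frame_interval)), con)
  if (!is.null(raster$positions))
    writeLines(paste0("# positions: ", paste(
      sprintf("%.17g,%.17g", raster$positions[, 1], raster$positions[, 2]),
      collapse = ";")), con)
  if (!is.null(raster$ei))
    writeLines(paste0("# ei: ", paste(raster$ei, collapse = "")), con)
  writeLines("neuron_id,time_s", con)
  if (length(raster$time))
    writeLines(sprintf("%d,%.17g", raster$neuron, raster$time), con)
  invisible(path)
}

#' Bin a spike raster onto a regular time grid
#'
#' Counts spikes of each neuron in half-open bins
#' `[origin + j*bin_width, origin + (j+1)*bin_width)`. The grid tiles
#' `[origin, duration]`; a spike exactly at `duration` falls in the last bin.
#' Total counts are conserved: `sum(counts)` equals the number of spikes in
#' the covered window.
#'
#' @param raster a [spike_raster()].
#' @param bin_width bin width in seconds (> 0).
#' @param origin start of bin 0, seconds (default 0).
#' @return A `binned_raster`: list with `counts` (sparse `n_neurons` x
#'   `n_bins` matrix), `bin_width`, `origin`, `n_neurons`.
#' @export
bin_raster <- function(raster, bin_width, origin = 0) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  span <- raster$duration - origin
  n_bins <- max(1L, as.integer(ceiling(span / bin_width - 1e-9)))
  # half-open bins; a spike exactly at the grid end (the duration) is kept
  # in the last bin rather than dropped
  keep <- raster$time >= origin & raster$time <= origin + n_bins * bin_width
  j <- pmin(floor((raster$time[keep] - origin) / bin_width), n_bins - 1L)
  counts <- Matrix::sparseMatrix(
    i = raster$neuron[keep], j = as.integer(j) + 1L, x = 1,
    dims = c(raster$n_neurons, n_bins))
  structure(list(counts = counts, bin_width = bin_width, origin = origin,
                 n_neurons = raster$n_neurons),
            class = "binned_raster")
}

#' @export
print.binned_raster <- function(x, ...) {
  cat(sprintf("Binned raster: %d neurons x %d bins of %.4g ms (%d spikes)\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_width,
              as.integer(sum(x$counts))))
  invisible(x)
}
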