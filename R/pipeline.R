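#' Reference summary of dissociated-culture recordings
#'
#' Bundled summary of nine 200 fps calcium-imaging recordings of
#' dissociated hippocampal cultures with up/down alternation: population
#' size, whether inhibition was intact (`"E+I"`) or blocked (`"E"`), and
#' the per-state mean single-cell interspike intervals (ms). These values
#' serve as reference inputs: they set the natural avalanche time-bin
#' scales of the two states and are the data behind the package's default
#' ISI expectations (grand means of about 217 ms in the up state and about
#' 1065 ms in the down state).
#'
#' @return A data.frame with columns `recording`, `type`, `n_cells`,
#'   `isi_up_ms`, `isi_down_ms`.
#' @export
culture_recordings <- function() {
  data.frame(
    recording = 1:9,
    type = c("E+I", "E+I", "E", "E+I", "E", "E+I", "E", "E+I", "E"),
    n_cells = c(1374L, 1510L, 1426L, 825L, 813L, 998L, 1001L, 893L, 875L),
    isi_up_ms = c(216, 211, 210, 86, 407, 70, 248, 106, 404),
    isi_down_ms = c(2955, 1438, 419, 449, 1444, 245, 613, 620, 1409))
}

#' Default avalanche bin-width grids
#'
#' Up-state avalanches use bins of a few multiples of the acquisition
#' frame (the time scale of fast glutamatergic transmission); down-state
#' avalanches need bins of the order of the much longer down-state
#' interspike interval, i.e. tens to hundreds of ms. For 5 ms frames
#' (200 fps recordings) the down grid spans 40--640 ms; for sub-ms frames
#' (simulations) it spans about 6--205 ms.
#'
#' @param frame_interval acquisition frame (s).
#' @param state `"up"` or `"down"`.
#' @return Numeric vector of bin widths in seconds.
#' @export
default_bin_grid <- function(frame_interval, state = c("up", "down")) {
  state <- match.arg(state)
  mult <- if (state == "up") {
    c(1, 2, 4, 8, 16, 32)
  } else if (frame_interval <= 1e-3) {
    c(64, 128, 256, 512, 1024, 2048)
  } else {
    c(8, 16, 32, 64, 128)
  }
  mult * frame_interval
}

# Pool avalanches over patch subsamples at one bin width.
.pooled_avalanches <- function(patches, bin_width, state) {
  S <- integer(0); T <- integer(0); patch_id <- integer(0)
  for (p in seq_along(patches)) {
    av <- state_avalanches(patches[[p]], bin_width, state = state)
    if (nrow(av$avalanches)) {
      S <- c(S, av$avalanches$S)
      T <- c(T, av$avalanches$T)
      patch_id <- c(patch_id, rep(p, nrow(av$avalanches)))
    }
  }
  list(S = S, T = T, patch_id = patch_id)
}

.analyze_state <- function(raster, seg, state, bins, patch, n_pdf_classes,
                           collapse_grids) {
  empty <- list(state = state, family = "none", n_avalanches = 0L)
  restricted <- suppressWarnings(restrict_to_state(raster, seg, state))
  if (!length(restricted$time)) return(empty)
  patches <- if (is.null(patch)) {
    list(restricted)
  } else {
    do.call(sample_patches, c(list(raster = restricted), patch))
  }
  pooled <- lapply(bins, function(w) .pooled_avalanches(patches, w, state))
  names(pooled) <- signif(bins, 6)
  n_av <- vapply(pooled, function(p) length(p$S), 0L)
  if (sum(n_av) == 0) return(empty)
  pdf_or_null <- function(values, obs, w) {
    if (length(unique(values)) < 2 || length(values) < 10) return(NULL)
    empirical_pdf(values, n_classes = n_pdf_classes, observable = obs,
                  bin_width = w)
  }
  pdfs_S <- Filter(Negate(is.null), lapply(seq_along(bins), function(i)
    pdf_or_null(pooled[[i]]$S, "size", bins[i])))
  pdfs_T <- Filter(Negate(is.null), lapply(seq_along(bins), function(i)
    pdf_or_null(pooled[[i]]$T, "duration", bins[i])))
  # extended-range power-law fits per bin width; the state passes the
  # power-law gate when any bin width admits a qualifying range for the
  # sizes
  fit_one <- function(v) {
    if (length(v) >= 50 && length(unique(v)) >= 5)
      tryCatch(fit_power_law_range(v, max_n = 5e4),
               error = function(e) NULL)
  }
  fits_S <- lapply(pooled, function(p) fit_one(p$S))
  fits_T <- lapply(pooled, function(p) fit_one(p$T))
  ok_S <- vapply(fits_S, function(f) !is.null(f) && f$ok, TRUE)
  ok_T <- vapply(fits_T, function(f) !is.null(f) && f$ok, TRUE)
  pick <- function(fits, ok) if (any(ok)) fits[[which(ok)[1]]] else
    fits[[which.max(n_av)]]
  fit_S <- pick(fits_S, ok_S)
  fit_T <- pick(fits_T, ok_T)
  # gamma per bin width, combined by inverse variance: the bin-scaling
  # relation beta_T = gamma * beta_S presumes a single gamma across bins
  gams <- lapply(pooled, function(p) mean_duration_vs_size(p$S, p$T))
  gok <- vapply(gams, function(g) isTRUE(g$ok) && is.finite(g$se) &&
                  g$se > 0, TRUE)
  gam <- if (any(gok)) {
    est <- vapply(gams[gok], `[[`, 0, "gamma")
    w <- 1 / vapply(gams[gok], `[[`, 0, "se")^2
    list(gamma = sum(w * est) / sum(w),
         se = max(sqrt(1 / sum(w)),
                  if (length(est) > 1)
                    sqrt(sum(w * (est - sum(w * est) / sum(w))^2) /
                           sum(w) / max(1, length(est) - 1)) else 0),
         per_bin = est, ok = TRUE)
  } else {
    list(gamma = NA_real_, se = NA_real_, per_bin = NULL, ok = FALSE)
  }
  powerlaw_ok <- any(ok_S)
  family <- if (powerlaw_ok) "power_law" else "exponential_like"
  collapse_S <- collapse_T <- NULL
  if (length(pdfs_S) >= 3) {
    collapse_S <- tryCatch(
      if (powerlaw_ok)
        do.call(collapse_power_law, c(list(pdfs_S), collapse_grids))
      else collapse_exponential(pdfs_S),
      error = function(e) NULL)
  }
  if (length(pdfs_T) >= 3) {
    collapse_T <- tryCatch(
      if (powerlaw_ok)
        do.call(collapse_power_law, c(list(pdfs_T), collapse_grids))
      else collapse_exponential(pdfs_T),
      error = function(e) NULL)
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else x
  tau <- num_or_na(collapse_S$exponent)
  alpha <- num_or_na(collapse_T$exponent)
  beta_S <- num_or_na(collapse_S$beta)
  beta_T <- num_or_na(collapse_T$beta)
  rel <- if (powerlaw_ok && is.finite(tau) && is.finite(alpha) &&
             isTRUE(gam$ok)) {
    check_scaling_relation(tau, alpha, gam$gamma,
                           num_or_na(collapse_S$exponent_unc),
                           num_or_na(collapse_T$exponent_unc), gam$se)
  }
  rel_beta <- if (is.finite(beta_S) && is.finite(beta_T) && isTRUE(gam$ok)) {
    check_beta_relation(beta_T, beta_S, gam$gamma,
                        num_or_na(collapse_T$beta_unc),
                        num_or_na(collapse_S$beta_unc), gam$se)
  }
  list(state = state, family = family,
       n_avalanches = as.integer(sum(n_av)),
       n_avalanches_per_bin = n_av,
       bins = bins,
       tau = tau, tau_unc = num_or_na(collapse_S$exponent_unc),
       alpha = alpha, alpha_unc = num_or_na(collapse_T$exponent_unc),
       beta_S = beta_S, beta_S_unc = num_or_na(collapse_S$beta_unc),
       beta_T = beta_T, beta_T_unc = num_or_na(collapse_T$beta_unc),
       gamma = gam$gamma, gamma_unc = gam$se,
       gamma_per_bin = gam$per_bin,
       fit_S = fit_S, fit_T = fit_T,
       fits_S = fits_S, fits_T = fits_T,
       scaling_relation = rel, beta_relation = rel_beta,
       pdfs_S = pdfs_S, pdfs_T = pdfs_T,
       pooled = pooled)
}

#' Full up/down avalanche-criticality analysis of one recording
#'
#' Runs the complete chain on a spike raster: population rate at the
#' acquisition frame, Gaussian smoothing, Schmitt-trigger segmentation into
#' up and down states, per-state avalanche detection over a grid of bin
#' widths with patch subsampling, log-binned size and duration
#' distributions, finite-size scaling collapse (power-law family when an
#' extended power-law range passes the KS p-value gate, exponential-like
#' otherwise), the size--duration exponent gamma, and the exponent
#' relations. Deterministic for a fixed `seed`.
#'
#' @param raster a [spike_raster()].
#' @param sigma_frames smoothing sd in frames (5 for 200 fps recordings,
#'   20 for simulations; the default picks by frame interval).
#' @param upper,lower Schmitt thresholds (spikes/frame/neuron).
#' @param up_bins,down_bins avalanche bin-width grids (s); see
#'   [default_bin_grid()].
#' @param patch `NULL` (no subsampling) or a list of arguments for
#'   [sample_patches()] (e.g. `list(mode = "random_fraction",
#'   fraction = 0.5, n_patches = 100, seed = 1)`).
#' @param n_pdf_classes log classes for the empirical PDFs.
#' @param collapse_grids optional list of grid arguments passed to
#'   [collapse_power_law()].
#' @param seed integer seed for patch subsampling and p-value iterations.
#' @return A `recording_report`: list with `segmentation`, `duration_stats`,
#'   `isi`, and per-state analysis under `up` and `down` (exponents,
#'   uncertainties, fits, relations).
#' @export
run_full_analysis <- function(raster,
                              sigma_frames = NULL,
                              upper = 1e-3, lower = 3e-4,
                              up_bins = NULL, down_bins = NULL,
                              patch = list(mode = "random_fraction",
                                           fraction = 0.5,
                                           n_patches = 100),
                              n_pdf_classes = 30,
                              collapse_grids = NULL,
                              seed = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  set.seed(seed)
  fw <- raster$frame_interval
  if (is.null(sigma_frames)) sigma_frames <- if (fw <= 1e-3) 20 else 5
  if (is.null(up_bins)) up_bins <- default_bin_grid(fw, "up")
  if (is.null(down_bins)) down_bins <- default_bin_grid(fw, "down")
  if (!length(raster$time)) {
    warning("empty raster: nothing to analyze")
    return(structure(list(segmentation = NULL, duration_stats = NULL,
                          isi = NULL,
                          up = list(state = "up", family = "none",
                                    n_avalanches = 0L),
                          down = list(state = "down", family = "none",
                                      n_avalanches = 0L),
                          n_neurons = raster$n_neurons,
                          frame_interval = fw),
                     class = "recording_report"))
  }
  binned <- bin_raster(raster, fw)
  rate <- smooth_rate(population_rate(binned), sigma_frames)
  seg <- schmitt_segment(rate, upper = upper, lower = lower)
  dur_stats <- suppressWarnings(state_duration_stats(seg))
  isi <- isi_stats(raster, seg)
  if (!is.null(patch) && is.null(patch$seed)) patch$seed <- seed + 1
  up <- .analyze_state(raster, seg, "up", up_bins, patch, n_pdf_classes,
                       collapse_grids)
  down <- .analyze_state(raster, seg, "down", down_bins, patch,
                         n_pdf_classes, collapse_grids)
  structure(list(segmentation = seg, duration_stats = dur_stats, isi = isi,
                 up = up, down = down, n_neurons = raster$n_neurons,
                 frame_interval = fw),
            class = "recording_report")
}

#' @export
print.recording_report <- function(x, ...) {
  cat("Up/down avalanche-criticality report\n")
  if (!is.null(x$segmentation)) print(x$segmentation)
  fmt <- function(v, u) {
    if (!is.finite(v)) "NA" else sprintf("%.2f +/- %.2f", v,
                                         if (is.finite(u)) u else 0)
  }
  for (st in c("up", "down")) {
    s <- x[[st]]
    cat(sprintf("  %s state: family %s, %d avalanches\n", st, s$family,
                s$n_avalanches))
    if (s$n_avalanches > 0 && !is.null(s$bins)) {
      if (s$family == "power_law")
        cat(sprintf("    tau = %s, alpha = %s\n",
                    fmt(s$tau, s$tau_unc), fmt(s$alpha, s$alpha_unc)))
      cat(sprintf("    beta_S = %s, beta_T = %s, gamma = %s\n",
                  fmt(s$beta_S, s$beta_S_unc), fmt(s$beta_T, s$beta_T_unc),
                  fmt(s$gamma, s$gamma_unc)))
    }
  }
  invisible(x)
}

.report_state_json <- function(s) {
  num <- function(v) if (is.null(v) || !length(v) || !is.finite(v[1]))
    NULL else unname(v[1])
  out <- list(family = s$family, n_avalanches = s$n_avalanches,
              tau = num(s$tau), tau_unc = num(s$tau_unc),
              alpha = num(s$alpha), alpha_unc = num(s$alpha_unc),
              beta_S = num(s$beta_S), beta_S_unc = num(s$beta_S_unc),
              beta_T = num(s$beta_T), beta_T_unc = num(s$beta_T_unc),
              gamma = num(s$gamma), gamma_unc = num(s$gamma_unc))
  if (!is.null(s$fit_S) && s$fit_S$ok) {
    out$p_size <- list(mean = s$fit_S$p_mean, sem = s$fit_S$p_sem,
                       x_low = s$fit_S$x_low, x_high = s$fit_S$x_high)
  }
  if (!is.null(s$fit_T) && s$fit_T$ok) {
    out$p_duration <- list(mean = s$fit_T$p_mean, sem = s$fit_T$p_sem,
                           x_low = s$fit_T$x_low, x_high = s$fit_T$x_high)
  }
  if (!is.null(s$scaling_relation)) {
    out$scaling_relation_residual <- num(s$scaling_relation$residual)
    out$scaling_relation_pass <- isTRUE(s$scaling_relation$pass)
  }
  if (!is.null(s$beta_relation)) {
    out$beta_relation_residual <- num(s$beta_relation$residual)
    out$beta_relation_pass <- isTRUE(s$beta_relation$pass)
  }
  out
}

#' Export a recording report as JSON
#'
#' Writes the machine-readable twin of the per-recording exponent table:
#' per state the distribution family, exponents with uncertainties, KS
#' p-values of the fitted ranges, relation residuals, plus state-duration
#' and ISI summaries. The document structure is described by the JSON
#' schema shipped at `system.file("schema", "recording_report.json",
#' package = "avalanchr")`.
#'
#' @param report a `recording_report`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "recording_report"))
  doc <- list(
    n_neurons = report$n_neurons,
    frame_interval_s = report$frame_interval,
    states = list(up = .report_state_json(report$up),
                  down = .report_state_json(report$down)))
  if (!is.null(report$segmentation)) {
    doc$state_durations <- list(
      t_up_mean = if (length(report$segmentation$t_up))
        mean(report$segmentation$t_up),
      t_down_mean = if (length(report$segmentation$t_down))
        mean(report$segmentation$t_down),
      n_up = length(report$segmentation$t_up),
      n_down = length(report$segmentation$t_down))
  }
  if (!is.null(report$isi)) {
    doc$isi_s <- list(up = unname(report$isi$mean_isi[1]),
                      down = unname(report$isi$mean_isi[2]))
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Check a report document against the shipped schema
#'
#' Lightweight structural validation: verifies that the required fields of
#' the report schema are present with the expected JSON types.
#'
#' @param json JSON string or path to a JSON file.
#' @return `TRUE` (invisibly) if conformant, otherwise an error.
#' @export
check_report_schema <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("schema", "recording_report.json",
                                           package = "avalanchr"),
                               simplifyVector = FALSE)
  need <- unlist(schema$required)
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("report is missing required fields: ",
         paste(missing, collapse = ", "))
  for (st in c("up", "down")) {
    if (!st %in% names(doc$states))
      stop("report is missing state block: ", st)
    blk <- doc$states[[st]]
    for (fld in unlist(schema$properties$states$required_per_state))
      if (!fld %in% names(blk))
        stop("state block '", st, "' is missing field: ", fld)
  }
  invisible(TRUE)
}
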