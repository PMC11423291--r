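#' Logarithmically binned empirical PDF
#'
#' Builds a normalized probability density over logarithmically spaced
#' classes between the sample minimum and maximum: density = class count /
#' (n * class width). Empty classes are dropped. This is the standard
#' log-log representation of avalanche size/duration distributions.
#'
#' @param values positive values (avalanche sizes or durations), at least 2
#'   distinct.
#' @param n_classes number of log-spaced classes (>= 3).
#' @param observable label, `"size"` or `"duration"`.
#' @param bin_width the avalanche time-bin width (seconds) the values were
#'   measured at; carried along for the collapse.
#' @return An `empirical_pdf`: list with `x` (class geometric centers),
#'   `density`, `counts`, `n_samples`, `observable`, `bin_width`.
#' @export
empirical_pdf <- function(values, n_classes = 30,
                          observable = c("size", "duration"),
                          bin_width = NA_real_) {
  observable <- match.arg(observable)
  if (any(values < 1)) stop("values must be >= 1")
  if (n_classes < 3) stop("n_classes must be >= 3")
  if (length(unique(values)) < 2)
    stop("degenerate distribution: fewer than 2 distinct values")
  lo <- min(values); hi <- max(values)
  breaks <- exp(seq(log(lo), log(hi), length.out = n_classes + 1))
  breaks[length(breaks)] <- hi * (1 + 1e-9)
  cls <- findInterval(values, breaks, rightmost.closed = TRUE)
  cls[cls > n_classes] <- n_classes
  counts <- tabulate(cls, nbins = n_classes)
  width <- diff(breaks)
  centers <- sqrt(breaks[-length(breaks)] * breaks[-1])
  keep <- counts > 0
  structure(list(x = centers[keep],
                 density = counts[keep] / (length(values) * width[keep]),
                 counts = counts[keep], n_samples = length(values),
                 observable = observable, bin_width = bin_width),
            class = "empirical_pdf")
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf(
    "Empirical %s PDF: %d occupied log classes, n = %d, bin width %.4g ms\n",
    x$observable, length(x$x), x$n_samples, 1000 * x$bin_width))
  invisible(x)
}

# Collapse quality: weighted mean squared vertical log10-dispersion between
# curves interpolated onto a common log-x grid. Weights increase linearly
# toward the right-hand (large-argument) side, where the distinctive
# features of the scaling function must align.
.collapse_quality <- function(log_x_list, log_y_list, n_grid = 60) {
  lo <- max(vapply(log_x_list, min, 0))
  hi <- min(vapply(log_x_list, max, 0))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NA_real_)
  grid <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(seq_along(log_x_list), function(i)
    stats::approx(log_x_list[[i]], log_y_list[[i]], xout = grid)$y,
    numeric(n_grid))
  w <- 0.2 + seq(0, 1, length.out = n_grid)
  disp <- apply(ys, 1, stats::var)
  sum(w * disp) / sum(w)
}

.as_pdf_list <- function(dists) {
  if (inherits(dists, "empirical_pdf")) dists <- list(dists)
  stopifnot(all(vapply(dists, inherits, TRUE, "empirical_pdf")))
  bins <- vapply(dists, function(d) d$bin_width, 0)
  if (anyNA(bins)) stop("every distribution needs its bin_width")
  list(dists = dists, rel_bin = bins / min(bins))
}

#' Finite-size scaling collapse, power-law family
#'
#' Estimates the exponents `(tau, beta)` of the scaling ansatz
#' `P(S) ~ S^-tau f(S / bin^beta)` by a grid search: each distribution
#' measured at time-bin width `bin` is rescaled to
#' `(x, y) = (S / bin^beta, P(S) * S^tau)` and the pair minimizing the
#' weighted vertical log-dispersion between the rescaled curves on their
#' common support is returned. The quality-based uncertainty is half the
#' grid extent over which the quality stays within `(1 + tol)` of the
#' minimum. The same machinery applies to durations
#' (`P(T) ~ T^-alpha f(T / bin^betaT)`).
#'
#' @param dists list of [empirical_pdf()] objects, one per bin width (>= 3
#'   widths with overlapping rescaled support).
#' @param tau_grid,beta_grid exponent search grids.
#' @param tol relative quality tolerance defining the uncertainty region.
#' @return A `collapse_result`: list with `family = "power_law"`,
#'   `exponent` (tau or alpha), `beta`, `quality`, `exponent_unc`,
#'   `beta_unc`, `grid` (quality matrix).
#' @export
collapse_power_law <- function(dists, tau_grid = seq(1.0, 2.5, by = 0.05),
                               beta_grid = seq(0, 3, by = 0.05),
                               tol = 0.05) {
  pl <- .as_pdf_list(dists)
  if (length(pl$dists) < 3) stop("need distributions at >= 3 bin widths")
  log_x0 <- lapply(pl$dists, function(d) log10(d$x))
  log_y0 <- lapply(pl$dists, function(d) log10(d$density))
  lb <- log10(pl$rel_bin)
  q <- matrix(NA_real_, length(tau_grid), length(beta_grid),
              dimnames = list(tau = tau_grid, beta = beta_grid))
  for (j in seq_along(beta_grid)) {
    lx <- lapply(seq_along(log_x0), function(i) log_x0[[i]] - beta_grid[j] * lb[i])
    for (i in seq_along(tau_grid)) {
      ly <- lapply(seq_along(log_y0), function(k)
        log_y0[[k]] + tau_grid[i] * log_x0[[k]])
      q[i, j] <- .collapse_quality(lx, ly)
    }
  }
  if (all(is.na(q))) stop("no common support: collapse infeasible")
  best <- which(q == min(q, na.rm = TRUE), arr.ind = TRUE)[1, ]
  region <- which(q <= (1 + tol) * min(q, na.rm = TRUE), arr.ind = TRUE)
  structure(list(
    family = "power_law",
    exponent = tau_grid[best[1]], beta = beta_grid[best[2]],
    quality = min(q, na.rm = TRUE),
    exponent_unc = max(diff(range(tau_grid[region[, 1]])) / 2,
                       diff(tau_grid[1:2]) / 2),
    beta_unc = max(diff(range(beta_grid[region[, 2]])) / 2,
                   diff(beta_grid[1:2]) / 2),
    grid = q), class = "collapse_result")
}

#' Finite-size scaling collapse, exponential-like family
#'
#' For exponential-like avalanche statistics (`tau = 0`) the collapse is
#' one-dimensional: `P(S) * bin^beta` versus `S / bin^beta`. Returns the
#' `beta` minimizing the same dispersion objective as
#' [collapse_power_law()].
#'
#' @inheritParams collapse_power_law
#' @return A `collapse_result` with `family = "exponential_like"`, `beta`,
#'   `quality`, `beta_unc`, and `exponent = NA`.
#' @export
collapse_exponential <- function(dists, beta_grid = seq(0, 3, by = 0.05),
                                 tol = 0.05) {
  pl <- .as_pdf_list(dists)
  if (length(pl$dists) < 3) stop("need distributions at >= 3 bin widths")
  log_x0 <- lapply(pl$dists, function(d) log10(d$x))
  log_y0 <- lapply(pl$dists, function(d) log10(d$density))
  lb <- log10(pl$rel_bin)
  q <- vapply(beta_grid, function(b) {
    lx <- lapply(seq_along(log_x0), function(i) log_x0[[i]] - b * lb[i])
    ly <- lapply(seq_along(log_y0), function(i) log_y0[[i]] + b * lb[i])
    .collapse_quality(lx, ly)
  }, 0)
  if (all(is.na(q))) stop("no common support: collapse infeasible")
  best <- which.min(q)
  region <- which(q <= (1 + tol) * min(q, na.rm = TRUE))
  structure(list(
    family = "exponential_like",
    exponent = NA_real_, beta = beta_grid[best],
    quality = q[best],
    exponent_unc = NA_real_,
    beta_unc = max(diff(range(beta_grid[region])) / 2,
                   diff(beta_grid[1:2]) / 2),
    grid = q), class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  if (x$family == "power_law") {
    cat(sprintf(
      "Scaling collapse (power law): exponent %.2f +/- %.2f, beta %.2f +/- %.2f (quality %.3g)\n",
      x$exponent, x$exponent_unc, x$beta, x$beta_unc, x$quality))
  } else {
    cat(sprintf(
      "Scaling collapse (exponential-like): beta %.2f +/- %.2f (quality %.3g)\n",
      x$beta, x$beta_unc, x$quality))
  }
  invisible(x)
}

#' Crackling-noise scaling relation between avalanche exponents
#'
#' At criticality the size, duration and size--duration exponents obey
#' `(alpha - 1) / (tau - 1) = 1 / gamma`. The residual
#' `(alpha - 1)/(tau - 1) - 1/gamma` is reported with first-order
#' propagated uncertainty, and the relation passes when the residual is
#' consistent with zero within the combined uncertainty.
#'
#' @param tau size exponent (> 1).
#' @param alpha duration exponent.
#' @param gamma size--duration exponent.
#' @param tau_unc,alpha_unc,gamma_unc one-sigma uncertainties (0 if
#'   omitted).
#' @return A list with `residual`, `uncertainty`, `pass`.
#' @export
check_scaling_relation <- function(tau, alpha, gamma, tau_unc = 0,
                                   alpha_unc = 0, gamma_unc = 0) {
  if (!is.finite(tau) || tau <= 1)
    return(list(residual = NA_real_, uncertainty = NA_real_, pass = NA,
                flag = "relation undefined for tau <= 1"))
  residual <- (alpha - 1) / (tau - 1) - 1 / gamma
  unc <- sqrt((alpha_unc / (tau - 1))^2 +
                ((alpha - 1) * tau_unc / (tau - 1)^2)^2 +
                (gamma_unc / gamma^2)^2)
  list(residual = residual, uncertainty = unc,
       pass = abs(residual) <= unc)
}

#' Bin-scaling exponent relation
#'
#' The finite-size scaling exponents of sizes and durations are linked by
#' `beta_T = gamma * beta_S`. Reports the residual `beta_T - gamma * beta_S`
#' with propagated uncertainty.
#'
#' @param beta_T,beta_S bin-scaling exponents for durations and sizes.
#' @param gamma size--duration exponent.
#' @param beta_T_unc,beta_S_unc,gamma_unc one-sigma uncertainties.
#' @return A list with `residual`, `uncertainty`, `pass`.
#' @export
check_beta_relation <- function(beta_T, beta_S, gamma, beta_T_unc = 0,
                                beta_S_unc = 0, gamma_unc = 0) {
  residual <- beta_T - gamma * beta_S
  unc <- sqrt(beta_T_unc^2 + (gamma * beta_S_unc)^2 +
                (beta_S * gamma_unc)^2)
  list(residual = residual, uncertainty = unc,
       pass = abs(residual) <= unc)
}
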