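# Analytic scaling families used as ground truth for the collapse:
# P(S) = S^-tau * g(S / bin^beta) evaluated on a log grid, with g an
# exponential cutoff. The generator's (tau, beta) are the oracle.
family_powerlaw <- function(tau, beta, bins, n_pts = 80, cutoff = 50) {
  lapply(bins, function(b) {
    x <- 10^seq(0, 4, length.out = n_pts)
    y <- x^(-tau) * exp(-x / (cutoff * b^beta))
    structure(list(x = x, density = y, counts = rep(1000L, n_pts),
                   n_samples = 1e5L, observable = "size", bin_width = b),
              class = "empirical_pdf")
  })
}

family_exponential <- function(beta, bins, n_pts = 80, cutoff = 30) {
  lapply(bins, function(b) {
    x <- 10^seq(0, 3.5, length.out = n_pts)
    y <- b^(-beta) * exp(-x / (cutoff * b^beta))
    structure(list(x = x, density = y, counts = rep(1000L, n_pts),
                   n_samples = 1e5L, observable = "size", bin_width = b),
              class = "empirical_pdf")
  })
}

test_that("empirical_pdf normalizes and recovers log-log slopes", {
  set.seed(1)
  v <- rpowerlaw(1e5, 1.5, 1, 1000)
  pdf <- empirical_pdf(v, n_classes = 25)
  # density integrates to ~1 over the classes
  # (reconstruct class widths from centers)
  lw <- diff(log(pdf$x))[1]
  widths <- pdf$x * (exp(lw / 2) - exp(-lw / 2))
  expect_equal(sum(pdf$density * widths), 1, tolerance = 0.1)
  # log-log slope ~ -1.5 over the bulk
  fit <- lm(log10(density) ~ log10(x),
            data = data.frame(x = pdf$x, density = pdf$density),
            subset = pdf$x < 100)
  expect_equal(unname(coef(fit)[2]), -1.5, tolerance = 0.1)

  # uniform values: flat density
  u <- runif(2e4, 1, 100)
  pu <- empirical_pdf(u, n_classes = 10)
  mid <- pu$density[pu$x > 5 & pu$x < 80]
  expect_lt(max(abs(mid - 1 / 99)) / (1 / 99), 0.15)

  expect_error(empirical_pdf(rep(7, 100)), "degenerate")
  expect_error(empirical_pdf(c(0.5, 2, 3)), ">= 1")
  expect_error(empirical_pdf(c(1, 2, 3), n_classes = 2), "n_classes")
})

test_that("power-law collapse recovers generator exponents", {
  bins <- c(1, 2, 4, 8)
  for (truth in list(c(1.5, 2.0), c(1.2, 1.0), c(1.8, 0.5))) {
    fam <- family_powerlaw(truth[1], truth[2], bins)
    res <- collapse_power_law(fam)
    expect_equal(res$exponent, truth[1], tolerance = 0.051 + res$exponent_unc)
    expect_equal(res$beta, truth[2], tolerance = 0.051 + res$beta_unc)
  }
  # identical distributions across bins: no bin dependence, beta = 0
  fam0 <- family_powerlaw(1.5, 0, bins)
  expect_equal(collapse_power_law(fam0)$beta, 0, tolerance = 0.051)
  expect_error(collapse_power_law(fam0[1:2]), ">= 3")
})

test_that("exponential-like collapse recovers beta", {
  bins <- c(1, 2, 4, 8)
  for (beta in c(0.5, 1.3, 2.0)) {
    fam <- family_exponential(beta, bins)
    res <- collapse_exponential(fam)
    expect_equal(res$beta, beta, tolerance = 0.051 + res$beta_unc)
    expect_true(is.na(res$exponent))
  }
  fam0 <- family_exponential(0, bins)
  expect_equal(collapse_exponential(fam0)$beta, 0, tolerance = 0.051)
})

test_that("each family collapses its own kind better than the other", {
  bins <- c(1, 2, 4, 8)
  pl <- family_powerlaw(1.5, 2.0, bins)
  ex <- family_exponential(1.3, bins)
  # on a pure power-law family the 2-parameter collapse is better
  expect_lt(collapse_power_law(pl)$quality, collapse_exponential(pl)$quality)
  # on a pure exponential family the beta-only collapse is better
  expect_lt(collapse_exponential(ex)$quality, collapse_power_law(ex)$quality)
})

test_that("collapse quality is invariant under reordering of bin widths", {
  fam <- family_powerlaw(1.5, 1.0, c(1, 2, 4, 8))
  r1 <- collapse_power_law(fam)
  r2 <- collapse_power_law(rev(fam))
  expect_equal(r1$quality, r2$quality, tolerance = 1e-12)
  expect_equal(r1$exponent, r2$exponent)
  expect_equal(r1$beta, r2$beta)
})

test_that("exponent relations compute residuals and propagate uncertainty", {
  # mean-field identity
  r <- check_scaling_relation(1.5, 2.0, 0.5)
  expect_equal(r$residual, 0)
  expect_true(r$pass)
  # arithmetic case
  r2 <- check_scaling_relation(1.5, 2.0, 0.6)
  expect_equal(r2$residual, 2 - 1 / 0.6)
  # undefined below tau = 1
  r3 <- check_scaling_relation(0.9, 2.0, 0.5)
  expect_true(is.na(r3$residual))
  # uncertainty grows the pass region
  r4 <- check_scaling_relation(1.5, 2.0, 0.6, 0.1, 0.2, 0.05)
  expect_true(r4$uncertainty > 0)

  b <- check_beta_relation(1.0, 2.0, 0.5)
  expect_equal(b$residual, 0)
  b2 <- check_beta_relation(1.2, 1.8, 0.73)
  expect_equal(b2$residual, 1.2 - 0.73 * 1.8, tolerance = 1e-12)
  b3 <- check_beta_relation(0, 0, 0.7)
  expect_equal(b3$residual, 0)
})

test_that("beta relation holds on synthetic scale-free ensembles", {
  # build S with tau = 1.5 and T = S^gamma exactly; measure beta_S and
  # beta_T from collapses of the induced families, then check
  # beta_T = gamma * beta_S
  gamma <- 0.5
  bins <- c(1, 2, 4, 8)
  beta_S <- 2.0
  fam_S <- family_powerlaw(1.5, beta_S, bins)
  # duration family implied by T = S^gamma: P(T) ~ T^-alpha h(T/bin^(gamma*betaS))
  fam_T <- family_powerlaw(2.0, gamma * beta_S, bins)
  rS <- collapse_power_law(fam_S)
  rT <- collapse_power_law(fam_T)
  chk <- check_beta_relation(rT$beta, rS$beta, gamma,
                             rT$beta_unc, rS$beta_unc, 0.01)
  expect_true(chk$pass)
})
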