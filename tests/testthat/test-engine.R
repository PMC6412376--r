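test_that("misfit energy is the symmetric quadratic charge penalty", {
  p <- energy_parameters()
  expect_equal(misfit_energy(0.01, -0.01, p), 0)
  expect_equal(misfit_energy(0, 0, p), 0)
  # hand-computed: 8419/2 * (0.02)^2
  expect_equal(misfit_energy(0.01, 0.01, p), 8419 / 2 * 4e-4)
  expect_equal(misfit_energy(0.013, -0.002, p),
               misfit_energy(-0.002, 0.013, p))
  expect_true(all(misfit_energy(seq(-0.02, 0.02, 0.005), 0.007, p) >= 0))
})

test_that("hydrogen-bond energy activates only across the donor/acceptor thresholds", {
  p <- energy_parameters()
  expect_equal(hb_energy(0, 0, p), 0)
  expect_equal(hb_energy(0.008, -0.008, p), 0)    # both inside +-sigma_hb
  expect_equal(hb_energy(0.02, 0.02, p), 0)       # no donor side
  # hand-computed: 85580 * (0.02 - 0.0084) * (-0.02 + 0.0084)
  expect_equal(hb_energy(0.02, -0.02, p), 85580 * 0.0116 * -0.0116)
  expect_equal(hb_energy(0.02, -0.02, p), hb_energy(-0.02, 0.02, p))
  s <- seq(-0.025, 0.025, 0.001)
  expect_true(all(outer(s, s, hb_energy, params = p) <= 0))
})

test_that("sigma potential vanishes in the zero-interaction limit", {
  p0 <- energy_parameters(alpha_prime = 0, c_hb = 0)
  pr <- bump_profile(grid51, 0.002, 0.004, 90)
  pot <- solve_sigma_potential(pr, p0)
  expect_equal(pot$mu, numeric(grid51$n_bins), tolerance = 1e-10)
})

test_that("a symmetric solvent profile yields a symmetric sigma potential", {
  p <- energy_parameters()
  sym <- stats::dnorm(grid51$centers, 0, 0.005) +
    0.3 * stats::dnorm(abs(grid51$centers), 0.015, 0.002)
  pr <- sigma_profile(grid51, 100 * sym / sum(sym), compound_id = "sym",
                      check_charge = FALSE)
  pot <- solve_sigma_potential(pr, p)
  expect_equal(pot$mu, rev(pot$mu), tolerance = 1e-8)
})

test_that("the converged potential satisfies the discretized equation", {
  p <- energy_parameters()
  pr <- normalize_profile(bump_profile(grid51, -0.004, 0.005, 150))
  pot <- solve_sigma_potential(pr, p, tol = 1e-8)
  # independent residual evaluation, direct summation per grid point
  beta <- p$a_eff / (p$R * p$T)
  s <- grid51$centers
  resid <- vapply(seq_along(s), function(i) {
    e <- misfit_energy(s[i], s, p) + hb_energy(s[i], s, p)
    pot$mu[i] + log(sum(pr$p * exp(beta * (pot$mu - e)))) / beta
  }, 0)
  expect_lt(max(abs(resid)), 1e-8)
  expect_lt(pot$residual, 1e-8)
})

test_that("fixed-point solution matches an independent root-finder on toys", {
  skip_if_not_installed("pracma")
  p <- energy_parameters(alpha_prime = 1000, c_hb = 5000)
  beta <- p$a_eff / (p$R * p$T)
  cases <- list(
    list(grid = grid5, ps = c(0.1, 0.25, 0.3, 0.25, 0.1)),
    list(grid = sigma_grid(-0.021, 0.021, 8L),
         ps = c(0.05, 0.1, 0.2, 0.25, 0.2, 0.1, 0.05, 0.05)))
  for (cs in cases) {
    s <- cs$grid$centers
    ps <- cs$ps
    solv <- sigma_profile(cs$grid, ps, normalized = TRUE, total_area = 50,
                          compound_id = "toy")
    pot <- solve_sigma_potential(solv, p)
    f_map <- function(mu) vapply(seq_along(s), function(i)
      -log(sum(ps * exp(beta * (mu - misfit_energy(s[i], s, p) -
                                  hb_energy(s[i], s, p))))) / beta, 0)
    root <- pracma::fsolve(function(mu) mu - f_map(mu),
                           numeric(length(s)), tol = 1e-12)
    expect_lt(max(abs(pot$mu - root$x)), 1e-8)
  }
})

test_that("solver reports non-convergence with diagnostics", {
  p <- energy_parameters()
  pr <- bump_profile(grid51, -0.004, 0.005, 150)
  expect_error(solve_sigma_potential(pr, p, max_iter = 2L),
               "no convergence after 2 iterations")
})

test_that("pseudo-chemical potential is linear in the solute profile", {
  p <- energy_parameters()
  solvent <- bump_profile(grid51, 0.001, 0.004, 120)
  pot <- solve_sigma_potential(solvent, p)

  zero <- sigma_profile(grid51, numeric(51), compound_id = "void",
                        check_charge = FALSE)
  expect_equal(pseudo_chemical_potential(zero, pot), 0)

  delta <- sigma_profile(grid51, replace(numeric(51), 30, 12),
                         compound_id = "delta", check_charge = FALSE)
  expect_equal(pseudo_chemical_potential(delta, pot), 12 * pot$mu[30])

  # quadrature oracle: plain sum over bins
  solute <- bump_profile(grid51, -0.003, 0.004, 300)
  expect_equal(pseudo_chemical_potential(solute, pot),
               sum(solute$p * pot$mu), tolerance = 1e-12)
  fine <- sigma_grid(-0.025, 0.025, 101L)
  expect_error(
    pseudo_chemical_potential(bump_profile(fine, 0, 0.004, 10), pot),
    "grid mismatch")
})

test_that("self-solvation and zero interactions give unit activity coefficient", {
  p <- energy_parameters()
  lib <- fixture_library()
  r_self <- ln_gamma_infinite_dilution(lib$EPA, lib$EPA, p)
  expect_equal(r_self$gamma_inf, 1, tolerance = 1e-6)

  p0 <- energy_parameters(alpha_prime = 0, c_hb = 0)
  a <- bump_profile(grid51, -0.004, 0.003, 200, id = "a")
  b <- bump_profile(grid51, 0.007, 0.002, 90, id = "b")
  r0 <- ln_gamma_infinite_dilution(a, b, p0)
  expect_equal(r0$gamma_inf, 1, tolerance = 1e-8)
})

test_that("activity coefficient matches an end-to-end brute-force recomputation", {
  skip_if_not_installed("pracma")
  p <- energy_parameters(alpha_prime = 1000, c_hb = 5000)
  beta <- p$a_eff / (p$R * p$T)
  s <- grid5$centers
  solute <- sigma_profile(grid5, c(2, 8, 20, 8, 2), compound_id = "sol",
                          check_charge = FALSE)
  solvent <- sigma_profile(grid5, c(6, 10, 4, 10, 6), compound_id = "slv",
                           check_charge = FALSE)
  res <- ln_gamma_infinite_dilution(solute, solvent, p)

  # independent path: fsolve both ensembles, then assemble ln gamma directly
  mu_of <- function(pvec) {
    ps <- pvec / sum(pvec)
    f_map <- function(mu) vapply(seq_along(s), function(i)
      -log(sum(ps * exp(beta * (mu - misfit_energy(s[i], s, p) -
                                  hb_energy(s[i], s, p))))) / beta, 0)
    pracma::fsolve(function(mu) mu - f_map(mu), numeric(length(s)),
                   tol = 1e-12)$x
  }
  ln_g <- sum(solute$p * (mu_of(solvent$p) - mu_of(solute$p))) / (p$R * p$T)
  expect_equal(res$ln_gamma_inf, ln_g, tolerance = 1e-7)
})

test_that("capacity is the reciprocal activity coefficient", {
  expect_equal(capacity(1), 1)
  expect_equal(capacity(9.52e-10), 1.05e9, tolerance = 5e-3)
  expect_equal(capacity(6.61e-4), 1.513e3, tolerance = 5e-3)
  expect_error(capacity(0), "positive")
  expect_error(capacity(-2), "positive")
  r <- activity_result(-3.5, "s", "v")
  expect_equal(r$capacity_inf * r$gamma_inf, 1)
  expect_equal(capacity(r)$capacity_inf, 1 / exp(-3.5))
})

test_that("doubling grid resolution changes ln gamma by under 1 percent", {
  p <- energy_parameters()
  mk <- function(g) list(
    sol = generate_profile(
      profile_spec(300, 0L, data.frame(center = c(0, -0.012, 0.012),
                                       width = c(0.004, 0.003, 0.003),
                                       weight = c(0.8, 0.1, 0.1)),
                   seed = 5, compound_id = "sol"), g, jitter_sd = 0),
    solv = generate_profile(
      profile_spec(200, 0L, data.frame(center = c(0.002, -0.01),
                                       width = c(0.004, 0.003),
                                       weight = c(0.7, 0.3)),
                   seed = 6, compound_id = "solv"), g, jitter_sd = 0))
  a <- mk(sigma_grid(n_bins = 51L))
  b <- mk(sigma_grid(n_bins = 101L))
  r1 <- ln_gamma_infinite_dilution(a$sol, a$solv, p)$ln_gamma_inf
  r2 <- ln_gamma_infinite_dilution(b$sol, b$solv, p)$ln_gamma_inf
  expect_lt(abs(r2 - r1) / abs(r1), 0.01)
})

test_that("growing the solvent acceptor surface never lowers capacity", {
  p <- energy_parameters()
  donor_solute <- sigma_profile(
    grid51,
    {q <- stats::dnorm(grid51$centers, 0, 0.003)
     q <- 250 * q / sum(q)
     d <- stats::dnorm(grid51$centers, -0.015, 0.0015)
     q + 20 * d / sum(d)},
    compound_id = "donor_solute", check_charge = FALSE)
  caps <- vapply(c(0, 5, 10, 20, 40), function(acc_area) {
    base <- stats::dnorm(grid51$centers, 0, 0.003)
    base <- 200 * base / sum(base)
    acc <- stats::dnorm(grid51$centers, 0.016, 0.0015)
    acc <- if (acc_area > 0) acc_area * acc / sum(acc) else 0 * acc
    solvent <- sigma_profile(grid51, base + acc, compound_id = "solv",
                             check_charge = FALSE)
    ln_gamma_infinite_dilution(donor_solute, solvent, p)$capacity_inf
  }, 0)
  expect_true(all(diff(caps) >= 0))
})

test_that("combinatorial term needs volumes and shifts ln gamma deterministically", {
  p <- energy_parameters()
  a <- bump_profile(grid51, -0.002, 0.004, 250, id = "a")
  b <- bump_profile(grid51, 0.003, 0.004, 120, id = "b")
  expect_error(ln_gamma_infinite_dilution(a, b, p, combinatorial = TRUE),
               "volume")
  a$volume <- 300; b$volume <- 130
  r0 <- ln_gamma_infinite_dilution(a, b, p)
  r1 <- ln_gamma_infinite_dilution(a, b, p, combinatorial = TRUE)
  expect_false(isTRUE(all.equal(r0$ln_gamma_inf, r1$ln_gamma_inf)))
  # identical compound: combinatorial term vanishes
  r_self <- ln_gamma_infinite_dilution(a, a, p, combinatorial = TRUE)
  expect_equal(r_self$ln_gamma_inf, 0, tolerance = 1e-8)
})
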