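#' Solve the self-consistent sigma-potential equation for a solvent
#'
#' The sigma potential mu_s(sigma) is the chemical potential per unit area
#' that a surface patch of density sigma experiences in the solvent
#' ensemble described by the (probability-normalized) profile p_s. It is the
#' fixed point of
#' \deqn{\mu_s(\sigma) = -\frac{RT}{a_{eff}} \ln \sum_{\sigma'} p_s(\sigma')
#'   \exp\!\left(\frac{a_{eff}}{RT}\left[\mu_s(\sigma') -
#'   E_{mf}(\sigma,\sigma') - E_{HB}(\sigma,\sigma')\right]\right)}
#' discretized on the profile's grid. The solver starts from mu = 0 with
#' damped successive substitution to enter the contraction basin, then
#' switches to Newton steps on \code{mu - F(mu)} (the Jacobian
#' \code{I + W}, with W the softmax weight matrix, is available for free
#' from the map evaluation); any Newton step that does not reduce the
#' max-norm residual falls back to a damped substitution step. The residual
#' is measured in max norm on the undamped update; evaluation uses
#' log-sum-exp so large interaction energies cannot overflow. The result is
#' deterministic for fixed inputs.
#'
#' @param solvent A \code{\link{sigma_profile}} of the solvent ensemble;
#'   converted to normalized (probability) form internally.
#' @param params \code{\link{energy_parameters}}.
#' @param tol Max-norm residual tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param damping Fraction of the new iterate kept per step (default 0.4).
#' @return An object of class \code{sigma_potential}: list with \code{grid},
#'   \code{mu} (kcal mol^-1 A^-2 at each bin center), \code{solvent_profile}
#'   (normalized), \code{params}, \code{residual} and \code{iterations}.
#' @examples
#' lib <- fixture_library()
#' pot <- solve_sigma_potential(lib$Cl, energy_parameters())
#' pot$residual < 1e-8
#' @export
solve_sigma_potential <- function(solvent, params = energy_parameters(),
                                  tol = 1e-8, max_iter = 500L,
                                  damping = 0.4) {
  stopifnot(inherits(solvent, "sigma_profile"),
            inherits(params, "energy_parameters"))
  ps <- normalize_profile(solvent)
  g <- ps$grid
  beta <- params$a_eff / (params$R * params$T)   # A^2 mol kcal^-1
  s <- g$centers
  S <- matrix(s, g$n_bins, g$n_bins)        # rows: sigma, cols: sigma'
  e <- misfit_energy(S, t(S), params) + hb_energy(S, t(S), params)
  # log of p_s(sigma') - beta*E(sigma, sigma'); columns are sigma'
  base <- sweep(-beta * e, 2L, log(ps$p), `+`)   # -Inf columns where p = 0

  # evaluates the map F(mu) and, on request, the softmax weight matrix W
  # whose rows sum to 1; the Jacobian of mu - F(mu) is I + W
  fixed_point_map <- function(mu, weights = FALSE) {
    a <- sweep(base, 2L, beta * mu, `+`)
    m <- apply(a, 1L, max)
    ex <- exp(a - m)
    rs <- rowSums(ex)
    out <- list(f = -(m + log(rs)) / beta)
    if (weights) out$w <- ex / rs
    out
  }

  mu <- numeric(g$n_bins)
  residual <- Inf
  iter <- 0L
  burn_in <- 20L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (iter <= burn_in) {            # damped substitution to enter the basin
      f <- fixed_point_map(mu)$f
      residual <- max(abs(f - mu))
      mu <- (1 - damping) * mu + damping * f
    } else {                          # Newton on G(mu) = mu - F(mu)
      fw <- fixed_point_map(mu, weights = TRUE)
      gvec <- mu - fw$f
      residual <- max(abs(gvec))
      if (residual < tol) break
      # truncated-SVD solve: the misfit kernel carries a near-null gauge
      # direction (~ mu + c*sigma) that makes the Jacobian ill-conditioned;
      # near the fixed point the residual along it is itself negligible
      sv <- svd(diag(g$n_bins) + fw$w)
      keep <- sv$d > 1e-8 * sv$d[1L]
      step <- as.vector(sv$v[, keep, drop = FALSE] %*%
                          ((t(sv$u[, keep, drop = FALSE]) %*% gvec) /
                             sv$d[keep]))
      accepted <- FALSE
      for (tstep in c(1, 0.5, 0.25, 0.1)) {   # backtracking line search
        cand <- mu - tstep * step
        res_cand <- max(abs(cand - fixed_point_map(cand)$f))
        if (is.finite(res_cand) && res_cand < residual) {
          mu <- cand
          accepted <- TRUE
          break
        }
      }
      if (!accepted) mu <- (1 - damping) * mu + damping * fw$f
    }
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf(paste0("solve_sigma_potential: no convergence after %d ",
                        "iterations (last max-norm residual %.3e)"),
                 iter, residual), call. = FALSE)
  structure(
    list(grid = g, mu = mu, solvent_profile = ps,
         params = params, residual = residual, iterations = iter),
    class = "sigma_potential")
}

#' @export
print.sigma_potential <- function(x, ...) {
  cat(sprintf("sigma_potential of '%s': grid %s, converged in %d iterations (residual %.2e)\n",
              x$solvent_profile$compound_id, format(x$grid), x$iterations,
              x$residual))
  invisible(x)
}

#' Pseudo-chemical potential of a solute in a solvent ensemble
#'
#' Assembles the residual pseudo-chemical potential of a solute from its
#' absolute sigma profile and the solvent's sigma potential:
#' \code{mu_X^S = sum_sigma p_X(sigma) mu_s(sigma)} (kcal/mol). Linear in
#' the solute profile; zero for a zero-area solute.
#'
#' @param solute An absolute-form \code{\link{sigma_profile}}.
#' @param potential A \code{\link{sigma_potential}}.
#' @return Energy in kcal/mol.
#' @export
pseudo_chemical_potential <- function(solute, potential) {
  stopifnot(inherits(solute, "sigma_profile"),
            inherits(potential, "sigma_potential"))
  assert_same_grid(solute$grid, potential$grid, "solute and potential")
  if (solute$normalized)
    stop("pseudo_chemical_potential: solute profile must be in absolute form",
         call. = FALSE)
  sum(solute$p * potential$mu)
}
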