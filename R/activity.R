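#' Infinite-dilution activity coefficient of a solute in a solvent
#'
#' Computes ln gamma at infinite dilution from the residual pseudo-chemical
#' potentials: the solvent sigma potential is solved from the solvent
#' profile alone (the exact x -> 0 limit; the solute contributes nothing to
#' the ensemble), and
#' \deqn{\ln\gamma^\infty = \frac{\mu_X^{solvent} - \mu_X^{pure\,X}}{RT}
#'   \; (+ \; \ln\gamma^{comb}) .}
#' The optional combinatorial term is the Staverman-Guggenheim expression at
#' infinite dilution (coordination number 10); it requires cavity volumes on
#' both profiles and is off by default. The extraction capacity
#' \code{1/gamma} is attached to the result.
#'
#' @param solute,solvent Absolute-form \code{\link{sigma_profile}} objects
#'   on one grid.
#' @param params \code{\link{energy_parameters}}.
#' @param combinatorial Logical; include the Staverman-Guggenheim
#'   combinatorial contribution (default \code{FALSE}).
#' @param tol,max_iter Passed to \code{\link{solve_sigma_potential}}.
#' @return An object of class \code{activity_result}: list with
#'   \code{ln_gamma_inf}, \code{gamma_inf}, \code{capacity_inf},
#'   \code{solute_id}, \code{solvent_id}, \code{T}.
#' @examples
#' lib <- fixture_library()
#' res <- ln_gamma_infinite_dilution(lib$EPA, lib$Cl)
#' res$gamma_inf * res$capacity_inf   # 1
#' @export
ln_gamma_infinite_dilution <- function(solute, solvent,
                                       params = energy_parameters(),
                                       combinatorial = FALSE,
                                       tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(solute, "sigma_profile"),
            inherits(solvent, "sigma_profile"))
  assert_same_grid(solute$grid, solvent$grid, "solute and solvent")
  pot_solvent <- solve_sigma_potential(solvent, params, tol = tol,
                                       max_iter = max_iter)
  pot_pure <- solve_sigma_potential(solute, params, tol = tol,
                                    max_iter = max_iter)
  rt <- params$R * params$T
  ln_g <- (pseudo_chemical_potential(solute, pot_solvent) -
           pseudo_chemical_potential(solute, pot_pure)) / rt
  if (combinatorial)
    ln_g <- ln_g + sg_combinatorial_inf(solute, solvent)
  activity_result(ln_g, solute$compound_id, solvent$compound_id, params$T)
}

# Staverman-Guggenheim combinatorial ln gamma at infinite dilution,
# coordination number z = 10; r, q from cavity volume/area against the
# conventional normalization references.
sg_combinatorial_inf <- function(solute, solvent, z = 10,
                                 v_ref = 66.69, a_ref = 79.53) {
  if (is.na(solute$volume) || is.na(solvent$volume))
    stop(paste0("combinatorial term requires cavity volumes on both ",
                "profiles (set 'volume')"), call. = FALSE)
  r_x <- solute$volume / v_ref;  q_x <- solute$total_area / a_ref
  r_s <- solvent$volume / v_ref; q_s <- solvent$total_area / a_ref
  rr <- r_x / r_s
  tt <- (q_x / r_x) / (q_s / r_s)    # theta/phi ratio at infinite dilution
  log(rr) + 1 - rr - (z / 2) * q_x * (log(1 / tt) + 1 - 1 / tt)
}

#' Construct an activity result
#'
#' @param ln_gamma_inf Natural log of the infinite-dilution activity
#'   coefficient.
#' @param solute_id,solvent_id Identifiers.
#' @param T Temperature, K.
#' @return An \code{activity_result} with \code{gamma_inf = exp(ln_gamma_inf)}
#'   and \code{capacity_inf = 1/gamma_inf}.
#' @export
activity_result <- function(ln_gamma_inf, solute_id = "solute",
                            solvent_id = "solvent", T = 298.15) {
  stopifnot(is.numeric(ln_gamma_inf), length(ln_gamma_inf) == 1L,
            is.finite(ln_gamma_inf))
  g <- exp(ln_gamma_inf)
  structure(
    list(ln_gamma_inf = ln_gamma_inf, gamma_inf = g, capacity_inf = 1 / g,
         solute_id = solute_id, solvent_id = solvent_id, T = T),
    class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity_result: %s in %s at %.2f K\n", x$solute_id,
              x$solvent_id, x$T))
  cat(sprintf("  ln gamma_inf = %.6g; gamma_inf = %.4g; C_inf = %.4g\n",
              x$ln_gamma_inf, x$gamma_inf, x$capacity_inf))
  invisible(x)
}

#' Extraction capacity at infinite dilution
#'
#' The capacity is the reciprocal of the infinite-dilution activity
#' coefficient, \code{C_inf = 1/gamma_inf}: the screening score used to rank
#' solvents (higher capacity predicts more solute extracted per solvent).
#' Accepts either a bare positive gamma value or an
#' \code{\link{activity_result}} (returned with its capacity field
#' recomputed).
#'
#' @param x A positive numeric gamma_inf (vectorized) or an
#'   \code{activity_result}.
#' @return Numeric capacity, or the updated \code{activity_result}.
#' @examples
#' capacity(9.52e-10)   # 1.05e9
#' capacity(1)          # 1
#' @export
capacity <- function(x) UseMethod("capacity")

#' @export
capacity.numeric <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("capacity: gamma_inf must be positive and finite", call. = FALSE)
  1 / x
}

#' @export
capacity.activity_result <- function(x) {
  x$capacity_inf <- capacity(x$gamma_inf)
  x
}
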