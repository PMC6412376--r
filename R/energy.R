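#' Interaction-model constants
#'
#' Bundles the segment-interaction parameters of the model: the misfit
#' prefactor alpha' (kcal mol^-1 A^2 e^-2 per unit area), the effective
#' contact area a_eff (A^2), the hydrogen-bond strength c_hb and threshold
#' sigma_hb, the temperature and the gas constant. Defaults are
#' open-literature COSMO-RS/COSMO-SAC-lineage constants; the screening
#' temperature defaults to 298.15 K.
#'
#' @param alpha_prime Misfit prefactor, kcal A^4 mol^-1 e^-2.
#' @param a_eff Effective contact area, A^2 (> 0).
#' @param c_hb Hydrogen-bond strength, kcal A^4 mol^-1 e^-2 (>= 0).
#' @param sigma_hb Hydrogen-bond threshold, e/A^2 (>= 0).
#' @param T Absolute temperature, K (> 0).
#' @param R Gas constant, kcal mol^-1 K^-1.
#' @return An object of class \code{energy_parameters}.
#' @export
energy_parameters <- function(alpha_prime = 8419, a_eff = 7.5,
                              c_hb = 85580, sigma_hb = 0.0084,
                              T = 298.15, R = 1.987e-3) {
  if (a_eff <= 0) stop("energy_parameters: a_eff must be > 0", call. = FALSE)
  if (T <= 0) stop("energy_parameters: T must be > 0", call. = FALSE)
  if (c_hb < 0) stop("energy_parameters: c_hb must be >= 0", call. = FALSE)
  if (sigma_hb < 0) stop("energy_parameters: sigma_hb must be >= 0",
                         call. = FALSE)
  structure(list(alpha_prime = alpha_prime, a_eff = a_eff, c_hb = c_hb,
                 sigma_hb = sigma_hb, T = T, R = R),
            class = "energy_parameters")
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat(sprintf(paste0("energy_parameters: alpha'=%g, a_eff=%g A^2, c_hb=%g, ",
                     "sigma_hb=%g e/A^2, T=%g K\n"),
              x$alpha_prime, x$a_eff, x$c_hb, x$sigma_hb, x$T)
  )
  invisible(x)
}

#' Electrostatic misfit energy of two contacting surface patches
#'
#' The misfit penalty per unit contact area when patches of screening charge
#' density sigma and sigma' meet: \code{(alpha'/2) (sigma + sigma')^2}. It
#' is symmetric, non-negative, and zero exactly when the charges cancel
#' (\code{sigma' = -sigma}). The effective contact area a_eff multiplies the
#' per-area energy once, inside the sigma-potential equation's exponent.
#'
#' @param sigma,sigma_prime Screening charge densities, e/A^2 (vectorized).
#' @param params \code{\link{energy_parameters}}.
#' @return Energy per unit area, kcal mol^-1 A^-2.
#' @examples
#' p <- energy_parameters()
#' misfit_energy(0.01, -0.01, p)  # 0: perfect complementarity
#' misfit_energy(0.01, 0.01, p)   # 8419/2 * 0.02^2
#' @export
misfit_energy <- function(sigma, sigma_prime, params = energy_parameters()) {
  (params$alpha_prime / 2) * (sigma + sigma_prime)^2
}

#' Hydrogen-bond energy of two contacting surface patches
#'
#' Klamt-style donor/acceptor threshold form, per unit contact area:
#' \code{c_hb * max(0, sigma_acc - sigma_hb) * min(0, sigma_don + sigma_hb)}
#' with \code{sigma_acc = max(sigma, sigma')} and
#' \code{sigma_don = min(sigma, sigma')}. The term is symmetric, always
#' <= 0, and non-zero only when one density exceeds \code{+sigma_hb}
#' (acceptor surface) while the other lies below \code{-sigma_hb} (donor
#' surface).
#'
#' @inheritParams misfit_energy
#' @return Energy per unit area, kcal mol^-1 A^-2 (<= 0).
#' @export
hb_energy <- function(sigma, sigma_prime, params = energy_parameters()) {
  acc <- pmax(sigma, sigma_prime)
  don <- pmin(sigma, sigma_prime)
  params$c_hb * pmax(0, acc - params$sigma_hb) * pmin(0, don + params$sigma_hb)
}
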