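#' Molecular sigma surface (charged segment list)
#'
#' Container for a COSMO screening-charge surface: an ordered list of surface
#' segments, each with an area (Angstrom^2) and a screening charge density
#' (e/Angstrom^2), plus the compound's total cavity area, volume and formal
#' charge. The screening charge mirrors the molecular charge with opposite
#' sign, so the area-weighted sum of segment charge densities of an anion
#' with formal charge -1 is approximately +1 e.
#'
#' @param compound_id Character identifier.
#' @param area Numeric vector of per-segment areas (all > 0), Angstrom^2.
#' @param charge_density Numeric vector of per-segment screening charge
#'   densities, e/Angstrom^2; same length as \code{area}.
#' @param volume Cavity volume in Angstrom^3 (\code{NA} if unknown).
#' @param formal_charge Integer molecular charge in e.
#' @param position Optional n x 3 matrix of segment centers (Angstrom); used
#'   by \code{\link{average_charges}}, may be \code{NULL}.
#' @param charge_tol Tolerance (e) for the net-charge consistency check.
#' @return An object of class \code{sigma_surface}.
#' @seealso \code{\link{read_cosmo_file}}, \code{\link{bin_profile}}
#' @export
sigma_surface <- function(compound_id, area, charge_density, volume = NA_real_,
                          formal_charge = 0L, position = NULL,
                          charge_tol = 0.05) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L)
  area <- as.numeric(area)
  charge_density <- as.numeric(charge_density)
  if (length(area) == 0L)
    stop("sigma_surface: segment list must be non-empty", call. = FALSE)
  if (length(area) != length(charge_density))
    stop("sigma_surface: area and charge_density lengths differ", call. = FALSE)
  if (anyNA(area) || anyNA(charge_density))
    stop("sigma_surface: NA in segment data", call. = FALSE)
  if (any(area <= 0))
    stop("sigma_surface: every segment area must be > 0", call. = FALSE)
  if (!is.null(position)) {
    position <- as.matrix(position)
    if (nrow(position) != length(area) || ncol(position) != 3L)
      stop("sigma_surface: position must be an n x 3 matrix", call. = FALSE)
  }
  total_area <- sum(area)
  net_screen <- sum(area * charge_density)
  if (abs(net_screen + formal_charge) > charge_tol)
    stop(sprintf(paste0("sigma_surface '%s': area-weighted screening charge ",
                        "%.4f e is inconsistent with formal charge %+d e ",
                        "(expected %+.2f within %.2f)"),
                 compound_id, net_screen, formal_charge,
                 -formal_charge, charge_tol), call. = FALSE)
  structure(
    list(compound_id = compound_id, area = area,
         charge_density = charge_density, total_area = total_area,
         volume = volume, formal_charge = as.integer(formal_charge),
         position = position),
    class = "sigma_surface")
}

#' @export
print.sigma_surface <- function(x, ...) {
  cat(sprintf("sigma_surface '%s': %d segments, area %.3f A^2, charge %+d e\n",
              x$compound_id, length(x$area), x$total_area, x$formal_charge))
  cat(sprintf("  screening charge sum %.4f e; sigma range [%.4f, %.4f] e/A^2\n",
              sum(x$area * x$charge_density),
              min(x$charge_density), max(x$charge_density)))
  if (!is.null(x$position)) cat("  segment positions present\n")
  invisible(x)
}
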