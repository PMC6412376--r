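#' Discretization grid for screening charge density
#'
#' A uniform grid of bin centers over the screening charge density sigma
#' (e/Angstrom^2). Sigma profiles and sigma potentials are represented as one
#' value per bin center. The default extent \code{[-0.025, 0.025]} with 51
#' bins (width 0.001) is the conventional COSMO-RS discretization.
#'
#' @param sigma_min,sigma_max Grid extent in e/Angstrom^2; must straddle zero.
#' @param n_bins Number of bin centers (>= 2).
#' @return An object of class \code{sigma_grid} with fields \code{sigma_min},
#'   \code{sigma_max}, \code{n_bins}, \code{bin_width} and precomputed
#'   \code{centers}.
#' @examples
#' g <- sigma_grid()
#' g$bin_width    # 0.001
#' range(g$centers)
#' @export
sigma_grid <- function(sigma_min = -0.025, sigma_max = 0.025, n_bins = 51L) {
  stopifnot(is.numeric(sigma_min), is.numeric(sigma_max), length(sigma_min) == 1L,
            length(sigma_max) == 1L)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L)
    stop("sigma_grid: n_bins must be >= 2", call. = FALSE)
  if (!(sigma_min < 0 && sigma_max > 0))
    stop("sigma_grid: grid must straddle zero (sigma_min < 0 < sigma_max)",
         call. = FALSE)
  w <- (sigma_max - sigma_min) / (n_bins - 1L)
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max, n_bins = n_bins,
         bin_width = w,
         centers = seq(sigma_min, sigma_max, length.out = n_bins)),
    class = "sigma_grid")
}

#' @export
print.sigma_grid <- function(x, ...) {
  cat(sprintf("sigma_grid: %d bins on [%g, %g] e/A^2 (width %g)\n",
              x$n_bins, x$sigma_min, x$sigma_max, x$bin_width))
  invisible(x)
}

#' @export
format.sigma_grid <- function(x, ...) {
  sprintf("[%g,%g]x%d", x$sigma_min, x$sigma_max, x$n_bins)
}

same_grid <- function(a, b, tol = 1e-12) {
  inherits(a, "sigma_grid") && inherits(b, "sigma_grid") &&
    a$n_bins == b$n_bins &&
    abs(a$sigma_min - b$sigma_min) < tol &&
    abs(a$sigma_max - b$sigma_max) < tol
}

assert_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share one sigma grid (%s vs %s)",
                 what, format(a), format(b)), call. = FALSE)
  invisible(TRUE)
}
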