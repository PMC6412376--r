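#' Sigma profile: surface area distributed over screening charge density
#'
#' The central COSMO-RS descriptor of a compound: the histogram p(sigma) of
#' molecular surface area (Angstrom^2 per bin) over screening charge density
#' sigma, on a \code{\link{sigma_grid}}. In absolute form the bin values sum
#' to the total cavity area; in normalized form they sum to 1 and p(sigma)
#' is the probability that a surface patch carries density sigma.
#'
#' @param grid A \code{\link{sigma_grid}}.
#' @param p Numeric vector, one non-negative value per grid bin.
#' @param compound_id Character identifier.
#' @param formal_charge Integer molecular charge, e.
#' @param volume Optional cavity volume, Angstrom^3 (used only by the
#'   combinatorial activity-coefficient term).
#' @param normalized Logical; if \code{TRUE}, \code{p} sums to 1 and
#'   \code{total_area} records the original absolute area.
#' @param total_area Total cavity area in Angstrom^2; defaults to
#'   \code{sum(p)} for absolute profiles.
#' @param check_charge If \code{TRUE} (default for absolute profiles),
#'   verify that the first moment \code{sum(sigma * p)} matches
#'   \code{-formal_charge} within \code{charge_tol}.
#' @param charge_tol Net-charge tolerance, e.
#' @return An object of class \code{sigma_profile}.
#' @export
sigma_profile <- function(grid, p, compound_id = "profile", formal_charge = 0L,
                          volume = NA_real_, normalized = FALSE,
                          total_area = NULL, check_charge = !normalized,
                          charge_tol = 0.05) {
  stopifnot(inherits(grid, "sigma_grid"))
  p <- as.numeric(p)
  if (length(p) != grid$n_bins)
    stop("sigma_profile: p must have one value per grid bin", call. = FALSE)
  if (anyNA(p) || any(p < 0))
    stop("sigma_profile: p(sigma) must be non-negative and finite",
         call. = FALSE)
  s <- sum(p)
  if (normalized) {
    if (abs(s - 1) > 1e-9)
      stop("sigma_profile: normalized profile must sum to 1 within 1e-9",
           call. = FALSE)
    if (is.null(total_area))
      stop("sigma_profile: normalized profile needs an explicit total_area",
           call. = FALSE)
  } else {
    if (is.null(total_area)) total_area <- s
    if (s > 0 && abs(s - total_area) > 1e-6 * max(1, abs(total_area)))
      stop("sigma_profile: sum(p) must equal total_area (1e-6 relative)",
           call. = FALSE)
  }
  if (check_charge && s > 0) {
    q_screen <- sum(grid$centers * p)
    if (abs(q_screen + formal_charge) > charge_tol)
      stop(sprintf(paste0("sigma_profile '%s': first moment %.4f e ",
                          "inconsistent with formal charge %+d e"),
                   compound_id, q_screen, formal_charge), call. = FALSE)
  }
  structure(
    list(grid = grid, p = p, total_area = total_area,
         compound_id = compound_id,
         formal_charge = as.integer(formal_charge), volume = volume,
         normalized = isTRUE(normalized)),
    class = "sigma_profile")
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf("sigma_profile '%s' (%s): grid %s, area %.3f A^2, charge %+d e\n",
              x$compound_id, if (x$normalized) "normalized" else "absolute",
              format(x$grid), x$total_area, x$formal_charge))
  invisible(x)
}

#' Convert a sigma profile to normalized (probability) form
#'
#' @param profile A \code{\link{sigma_profile}}.
#' @return The same profile with \code{p} summing to 1.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (profile$normalized) return(profile)
  if (sum(profile$p) <= 0)
    stop("normalize_profile: profile has zero total area", call. = FALSE)
  sigma_profile(profile$grid, profile$p / sum(profile$p),
                compound_id = profile$compound_id,
                formal_charge = profile$formal_charge,
                volume = profile$volume, normalized = TRUE,
                total_area = profile$total_area)
}

#' Smooth segment charge densities with a radial averaging kernel
#'
#' Standard COSMO-RS pre-processing: each segment's raw screening charge
#' density is replaced by a positively weighted average over neighbouring
#' segments, with Klamt-style weights
#' \code{w_j = (r_j^2 r_av^2 / (r_j^2 + r_av^2)) * exp(-d_ij^2 / (r_j^2 + r_av^2))}
#' where \code{r_j^2 = area_j / pi} and \code{d_ij} is the distance between
#' segment centers. After smoothing, a uniform density shift restores the
#' area-weighted net screening charge exactly, so total area and net charge
#' are both conserved. Surfaces without segment positions are returned
#' unchanged with a notice (distances are undefined).
#'
#' @param surface A \code{\link{sigma_surface}}.
#' @param r_av Averaging radius in Angstrom (> 0); default 0.5.
#' @return A \code{\link{sigma_surface}} with smoothed charge densities.
#' @export
average_charges <- function(surface, r_av = 0.5) {
  stopifnot(inherits(surface, "sigma_surface"))
  if (!is.numeric(r_av) || length(r_av) != 1L || r_av <= 0)
    stop("average_charges: r_av must be a positive number", call. = FALSE)
  if (is.null(surface$position)) {
    message("average_charges: surface has no segment positions; ",
            "averaging skipped")
    return(surface)
  }
  a <- surface$area
  r2 <- a / pi
  denom <- outer(rep(r_av^2, length(r2)), r2, `+`)    # r_j^2 + r_av^2, by col j
  d2 <- as.matrix(stats::dist(surface$position))^2
  w <- sweep(exp(-d2 / denom), 2L, r2 * r_av^2 / (r2 + r_av^2), `*`)
  sig <- unname(as.vector(w %*% surface$charge_density) / rowSums(w))
  # uniform shift: restore the exact net screening charge
  sig <- sig + (sum(a * surface$charge_density) - sum(a * sig)) / sum(a)
  out <- surface
  out$charge_density <- sig
  out
}

#' Bin a sigma surface into a sigma profile
#'
#' Distributes each segment's area between the two grid bins bracketing its
#' charge density, linearly by distance to the bin centers. This conserves
#' both the total area and the first moment (net screening charge) of the
#' surface. Densities outside the grid extent are clipped to the edge bins
#' with a warning reporting the clipped count.
#'
#' @param surface A \code{\link{sigma_surface}}.
#' @param grid A \code{\link{sigma_grid}}.
#' @return An absolute-form \code{\link{sigma_profile}}.
#' @export
bin_profile <- function(surface, grid = sigma_grid()) {
  stopifnot(inherits(surface, "sigma_surface"), inherits(grid, "sigma_grid"))
  sig <- surface$charge_density
  n_clip <- sum(sig < grid$sigma_min | sig > grid$sigma_max)
  if (n_clip > 0) {
    warning(sprintf("bin_profile '%s': %d segment(s) outside grid extent %s clipped",
                    surface$compound_id, n_clip, format(grid)), call. = FALSE)
    sig <- pmin(pmax(sig, grid$sigma_min), grid$sigma_max)
  }
  p <- spread_mass(sig, surface$area, grid)
  sigma_profile(grid, p, compound_id = surface$compound_id,
                formal_charge = surface$formal_charge,
                volume = surface$volume,
                check_charge = n_clip == 0L)
}

# linear split of masses at positions x between bracketing bin centers
spread_mass <- function(x, mass, grid) {
  u <- (x - grid$sigma_min) / grid$bin_width
  j <- pmin(pmax(floor(u), 0), grid$n_bins - 2L)
  f <- pmin(pmax(u - j, 0), 1)
  p <- numeric(grid$n_bins)
  lo <- rowsum(mass * (1 - f), j, reorder = FALSE)
  hi <- rowsum(mass * f, j, reorder = FALSE)
  jlo <- as.integer(rownames(lo)) + 1L
  p[jlo] <- p[jlo] + lo[, 1L]
  p[jlo + 1L] <- p[jlo + 1L] + hi[, 1L]
  p
}

#' Mix component sigma profiles by mole fraction
#'
#' The mixture (solvent ensemble) profile is the mole-fraction-weighted sum
#' of the component profiles, bin by bin: \code{ps = sum_i X_i p_i}. All
#' components must live on one grid and share the absolute/normalized
#' convention.
#'
#' @param profiles List of \code{\link{sigma_profile}} objects.
#' @param x Numeric mole fractions (non-negative, summing to 1 within 1e-12).
#' @param compound_id Identifier for the mixture profile.
#' @return A \code{\link{sigma_profile}} of the mixture. Its
#'   \code{formal_charge} is the mole-fraction-weighted mean of the component
#'   charges rounded to the nearest integer only when that is exact;
#'   otherwise the (possibly fractional) value is stored unrounded in
#'   attribute \code{"mean_charge"} and the integer field carries its
#'   rounded value with the charge check relaxed.
#' @export
mix_profiles <- function(profiles, x, compound_id = "mixture") {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  x <- as.numeric(x)
  if (length(x) != length(profiles))
    stop("mix_profiles: one mole fraction per component required", call. = FALSE)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
    stop("mix_profiles: mole fractions must be >= 0 and sum to 1 within 1e-12",
         call. = FALSE)
  g <- profiles[[1L]]$grid
  norm <- profiles[[1L]]$normalized
  for (pr in profiles) {
    stopifnot(inherits(pr, "sigma_profile"))
    assert_same_grid(g, pr$grid, "mixture components")
    if (pr$normalized != norm)
      stop("mix_profiles: components mix absolute with normalized form",
           call. = FALSE)
  }
  p <- Reduce(`+`, Map(function(pr, xi) xi * pr$p, profiles, x))
  mean_q <- sum(x * vapply(profiles, `[[`, 0, "formal_charge"))
  vols <- vapply(profiles, `[[`, 0, "volume")
  out <- sigma_profile(
    g, p, compound_id = compound_id,
    formal_charge = as.integer(round(mean_q)),
    volume = if (anyNA(vols)) NA_real_ else sum(x * vols),
    normalized = norm,
    total_area = if (norm) sum(x * vapply(profiles, `[[`, 0, "total_area"))
                 else sum(p),
    check_charge = FALSE)
  attr(out, "mean_charge") <- mean_q
  out
}

#' Decompose a sigma profile into polarity regions
#'
#' Splits the profile's area into the three conventional regions of the
#' sigma scale: hydrogen-bond donor surface (sigma < -cutoff), non-polar
#' surface (|sigma| <= cutoff) and hydrogen-bond acceptor surface
#' (sigma > +cutoff). The default cutoff is 0.01 e/Angstrom^2.
#'
#' @param profile A \code{\link{sigma_profile}}.
#' @param cutoff Positive region boundary, e/Angstrom^2.
#' @return An object of class \code{region_decomposition}: a list with
#'   \code{hbd_area}, \code{nonpolar_area}, \code{hba_area} (same unit as
#'   the profile), \code{total_area}, \code{cutoff} and \code{compound_id}.
#' @examples
#' lib <- fixture_library()
#' classify_regions(lib$EPA)
#' @export
classify_regions <- function(profile, cutoff = 0.01) {
  stopifnot(inherits(profile, "sigma_profile"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("classify_regions: cutoff must be a positive number", call. = FALSE)
  # each bin's mass is treated as uniform over its support
  # [center - w/2, center + w/2] and split fractionally at the cutoffs, so
  # region areas are stable under grid refinement
  w <- profile$grid$bin_width
  lo <- profile$grid$centers - w / 2
  hi <- profile$grid$centers + w / 2
  overlap <- function(a, b)  # fraction of each bin inside [a, b]
    pmax(0, pmin(hi, b) - pmax(lo, a)) / w
  structure(
    list(hbd_area = sum(profile$p * overlap(-Inf, -cutoff)),
         nonpolar_area = sum(profile$p * overlap(-cutoff, cutoff)),
         hba_area = sum(profile$p * overlap(cutoff, Inf)),
         total_area = sum(profile$p), cutoff = cutoff,
         compound_id = profile$compound_id),
    class = "region_decomposition")
}

#' @export
print.region_decomposition <- function(x, ...) {
  tot <- max(x$total_area, .Machine$double.xmin)
  cat(sprintf("regions of '%s' (cutoff %g e/A^2):\n", x$compound_id, x$cutoff))
  cat(sprintf("  HB donor   %10.3f (%5.1f%%)\n", x$hbd_area,
              100 * x$hbd_area / tot))
  cat(sprintf("  non-polar  %10.3f (%5.1f%%)\n", x$nonpolar_area,
              100 * x$nonpolar_area / tot))
  cat(sprintf("  HB acceptor%10.3f (%5.1f%%)\n", x$hba_area,
              100 * x$hba_area / tot))
  invisible(x)
}

#' @export
as.data.frame.region_decomposition <- function(x, ...) {
  data.frame(compound = x$compound_id, hbd = x$hbd_area,
             nonpolar = x$nonpolar_area, hba = x$hba_area,
             cutoff = x$cutoff, stringsAsFactors = FALSE)
}
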