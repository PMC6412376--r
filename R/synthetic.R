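#' Specification of a synthetic sigma profile
#'
#' Describes a compound's synthetic sigma profile as a Gaussian mixture over
#' screening charge density plus exact moment constraints: realized profiles
#' are projected so that the total area equals \code{total_area} and the
#' first moment equals \code{-formal_charge} (screening charge mirrors the
#' molecular charge).
#'
#' @param total_area Cavity area, Angstrom^2 (> 0).
#' @param formal_charge Integer molecular charge, e.
#' @param peaks Data frame with columns \code{center} (e/A^2), \code{width}
#'   (Gaussian sd, e/A^2, > 0) and \code{weight} (non-negative, summing
#'   to 1).
#' @param seed Integer seed controlling the profile's reproducible shape
#'   jitter.
#' @param volume Optional cavity volume, Angstrom^3.
#' @param compound_id Identifier.
#' @return An object of class \code{profile_spec}.
#' @export
profile_spec <- function(total_area, formal_charge = 0L, peaks,
                         seed = 1L, volume = NA_real_,
                         compound_id = "synthetic") {
  stopifnot(is.numeric(total_area), total_area > 0)
  peaks <- as.data.frame(peaks)
  if (!all(c("center", "width", "weight") %in% names(peaks)))
    stop("profile_spec: peaks needs columns center, width, weight",
         call. = FALSE)
  if (any(peaks$width <= 0))
    stop("profile_spec: peak widths must be > 0", call. = FALSE)
  if (any(peaks$weight < 0) || abs(sum(peaks$weight) - 1) > 1e-9)
    stop("profile_spec: peak weights must be >= 0 and sum to 1", call. = FALSE)
  structure(list(total_area = total_area,
                 formal_charge = as.integer(formal_charge),
                 peaks = peaks, seed = as.integer(seed), volume = volume,
                 compound_id = compound_id),
            class = "profile_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic sigma profile
#'
#' Evaluates the spec's Gaussian mixture on the grid, applies a small
#' seed-controlled multiplicative shape jitter, and projects the result onto
#' the constraint set \code{sum(p) = total_area},
#' \code{sum(sigma p) = -formal_charge}, \code{p >= 0} by non-negative
#' least-squares (minimal L2 correction with an active-set loop, so peak
#' shapes are preserved). Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{profile_spec}}.
#' @param grid A \code{\link{sigma_grid}}.
#' @param jitter_sd Relative amplitude of the shape jitter (default 0.02;
#'   0 disables it).
#' @return An absolute-form \code{\link{sigma_profile}}.
#' @examples
#' sp <- profile_spec(100, 0, data.frame(center = 0, width = 0.004, weight = 1))
#' pr <- generate_profile(sp)
#' sum(pr$p)                       # 100
#' sum(pr$grid$centers * pr$p)     # 0
#' @export
generate_profile <- function(spec, grid = sigma_grid(), jitter_sd = 0.02) {
  stopifnot(inherits(spec, "profile_spec"), inherits(grid, "sigma_grid"))
  s <- grid$centers
  p0 <- numeric(grid$n_bins)
  for (k in seq_len(nrow(spec$peaks)))
    p0 <- p0 + spec$peaks$weight[k] *
      stats::dnorm(s, spec$peaks$center[k], spec$peaks$width[k])
  if (sum(p0) <= 0)
    stop("generate_profile: mixture has no mass on the grid", call. = FALSE)
  if (jitter_sd > 0)
    p0 <- p0 * with_seed(spec$seed,
                         exp(stats::rnorm(grid$n_bins, 0, jitter_sd)))
  p0 <- p0 * spec$total_area / sum(p0)
  p <- project_moments(p0, s, spec$total_area, -spec$formal_charge)
  sigma_profile(grid, p, compound_id = spec$compound_id,
                formal_charge = spec$formal_charge, volume = spec$volume,
                charge_tol = 1e-6)
}

# projection of p0 onto {p >= 0, sum(p) = m0, sum(s*p) = m1}, least squares
# weighted by p0 itself (minimize sum (p-p0)^2/p0): the correction is then
# p0*(a + b*s), proportional to the local mass, so near-empty tail bins stay
# near-empty instead of acquiring an additive linear ramp. Negative bins are
# clamped and the equality system re-solved (active set).
project_moments <- function(p0, s, m0, m1, max_pass = 100L) {
  mean_target <- m1 / m0
  free <- p0 > 0
  for (pass in seq_len(max_pass)) {
    sf <- s[free]
    if (sum(free) < 2L || mean_target < min(sf) || mean_target > max(sf))
      stop(sprintf(paste0("generate_profile: moment constraints infeasible ",
                          "(required mean sigma %.4g outside reachable ",
                          "support)"), mean_target), call. = FALSE)
    A <- rbind(rep(1, sum(free)), sf)
    w <- p0[free]
    G <- A %*% (w * t(A))
    if (abs(det(G)) < 1e-300)
      stop("generate_profile: degenerate constraint system", call. = FALSE)
    b <- c(m0, m1) - A %*% p0[free]
    p <- p0
    p[!free] <- 0
    p[free] <- p0[free] + w * as.vector(t(A) %*% solve(G, b))
    neg <- p < 0
    if (!any(neg & free)) return(pmax(p, 0))
    free <- free & !neg
  }
  stop("generate_profile: constraint projection did not settle", call. = FALSE)
}

#' Generate a synthetic sigma surface realizing a profile spec
#'
#' Draws \code{n_segments} equal-area segments whose charge densities are a
#' low-variance systematic sample from the spec's realized profile (so the
#' re-binned surface converges to \code{\link{generate_profile}}'s output as
#' \code{n_segments} grows), with segment centers placed on a sphere of the
#' matching surface area. Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{profile_spec}}.
#' @param n_segments Number of segments (>= 1).
#' @param grid Grid used to realize the profile.
#' @return A \code{\link{sigma_surface}}.
#' @export
generate_surface <- function(spec, n_segments, grid = sigma_grid()) {
  stopifnot(inherits(spec, "profile_spec"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L)
    stop("generate_surface: n_segments must be >= 1", call. = FALSE)
  prof <- generate_profile(spec, grid)
  w <- prof$p / sum(prof$p)
  with_seed(spec$seed + 1L, {
    # systematic (stratified) inverse-CDF sample of bin centers
    u <- (seq_len(n_segments) - stats::runif(1)) / n_segments
    j <- findInterval(u, cumsum(w), left.open = TRUE) + 1L
    sig <- grid$centers[j]
    # segment centers on a sphere with the compound's surface area
    radius <- sqrt(spec$total_area / (4 * pi))
    z <- stats::runif(n_segments, -1, 1)
    phi <- stats::runif(n_segments, 0, 2 * pi)
    rho <- sqrt(pmax(0, 1 - z^2))
    pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  })
  area <- rep(spec$total_area / n_segments, n_segments)
  # enforce the exact net screening charge on the sampled densities
  sig <- sig + (-spec$formal_charge - sum(area * sig)) / sum(area)
  sigma_surface(spec$compound_id, area, sig, volume = spec$volume,
                formal_charge = spec$formal_charge, position = pos,
                charge_tol = 1e-6)
}

# Internal catalogue of synthetic ion/solute specs: plausible cavity areas
# (A^2), formal charges, and Gaussian peak placements on the sigma scale.
# Anion screening charge is positive (peak at +|q|/area); cations carry a
# polar ring peak near -0.009 and a non-polar alkyl peak near -0.001 whose
# balance meets the +1 first moment. Alkyl-chain growth within each cation
# family shows up as growing total (and non-polar) area.
ion_catalogue <- function() {
  an <- function(id, area, width, charge = -1L)
    list(id = id, kind = "anion", charge = charge, area = area,
         peaks = data.frame(center = -charge / area, width = width,
                            weight = 1))
  # cation: polar ring peak (kept inside the HB threshold so cations are not
  # artificial HB donors) plus a non-polar alkyl peak near zero; the peak
  # balance meets the +1 first moment, so the polar ring area shrinks and
  # the non-polar area grows as the alkyl chain lengthens, falling back to a
  # single peak at the required mean when the ring center cannot reach it
  cat_ <- function(id, area, ring = -0.0070) {
    w <- (1 / area - 0.001) / (abs(ring) - 0.001)
    peaks <- if (w < 1)
      data.frame(center = c(ring, -0.001), width = c(0.0008, 0.003),
                 weight = c(w, 1 - w))
    else
      data.frame(center = -1 / area, width = 0.0008, weight = 1)
    list(id = id, kind = "cation", charge = +1L, area = area, peaks = peaks)
  }
  entries <- list(
    list(id = "EPA", kind = "solute", charge = 0L, area = 457,
         peaks = data.frame(center = c(0, -0.015, 0.014),
                            width = c(0.0033, 0.0015, 0.0018),
                            weight = c(0.91, 0.04, 0.05))),
    cat_("EMIM", 236, -0.0070), cat_("BMIM", 278, -0.0070),
    cat_("HMIM", 320, -0.0070), cat_("OMIM", 362, -0.0070),
    cat_("EMPyr", 248, -0.0068), cat_("BMPyr", 290, -0.0068),
    cat_("HMPyr", 332, -0.0068), cat_("OMPyr", 374, -0.0068),
    cat_("EMPyrro", 244, -0.0066), cat_("BMPyrro", 286, -0.0066),
    cat_("HMPyrro", 328, -0.0066), cat_("MOPyrro", 370, -0.0066),
    cat_("MPPIP", 281, -0.0064), cat_("BMPIP", 302, -0.0064),
    cat_("HMPIP", 344, -0.0064), cat_("TMAm", 165, -0.0078),
    an("Cl", 79, 0.0016), an("Br", 91, 0.0017),
    an("BF4", 110, 0.002), an("PF6", 128, 0.002),
    an("NO3", 95, 0.0018), an("DCN", 125, 0.0025),
    an("DEP", 185, 0.003), an("AlCl4", 150, 0.0025),
    an("MeSO4", 135, 0.0025), an("SCN", 105, 0.002),
    an("MeSO3", 125, 0.0025), an("EtSO4", 155, 0.003),
    an("Benzoate", 150, 0.003), an("SO4", 122, 0.002, charge = -2L),
    an("HSO4", 115, 0.002), an("DMP", 165, 0.003),
    an("Propanoate", 118, 0.0022), an("TsO", 185, 0.003),
    an("TfO", 140, 0.003), an("NHC2F6", 175, 0.003),
    an("TFA", 125, 0.0025), an("Tf2N", 228, 0.003))
  stats::setNames(entries, vapply(entries, `[[`, "", "id"))
}

spec_from_catalogue <- function(entry, seed) {
  profile_spec(total_area = entry$area, formal_charge = entry$charge,
               peaks = entry$peaks,
               seed = seed + fnv1a32(entry$id) %% 100000L,
               volume = 0.08 * entry$area^1.5, compound_id = entry$id)
}

#' Synthetic sigma profiles for a set of compounds
#'
#' Generates seeded synthetic profiles for every id in \code{ids} (default:
#' the full default-manifest cast of 16 cations, 22 anions and the EPA-like
#' solute) from the package's internal catalogue of plausible cavity areas
#' and peak placements.
#'
#' @param ids Character vector of compound ids (must be in the catalogue).
#' @param grid A \code{\link{sigma_grid}}.
#' @param seed Integer master seed.
#' @return Named list of absolute-form \code{\link{sigma_profile}} objects.
#' @export
synthetic_profile_set <- function(ids = NULL, grid = sigma_grid(),
                                  seed = 1L) {
  cat_ <- ion_catalogue()
  if (is.null(ids)) ids <- names(cat_)
  missing <- setdiff(ids, names(cat_))
  if (length(missing))
    stop(sprintf("synthetic_profile_set: unknown compound id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  stats::setNames(
    lapply(ids, function(id)
      generate_profile(spec_from_catalogue(cat_[[id]], seed), grid)),
    ids)
}

#' Canonical synthetic fixture library
#'
#' A small named set of synthetic profiles exercising the screening model's
#' qualitative structure: an EPA-like solute (>= 90 percent non-polar area
#' with small hydrogen-bond donor and acceptor shoulders), compact
#' high-charge-density anions (Cl-, Br-like and a divalent sulfate-like
#' profile), a diffuse large anion (Tf2N-like), and an imidazolium-like
#' cation family whose non-polar area grows with alkyl chain length
#' (EMIM to OMIM).
#'
#' @inheritParams synthetic_profile_set
#' @return Named list of \code{\link{sigma_profile}} objects: \code{EPA},
#'   \code{Cl}, \code{Br}, \code{SO4}, \code{Tf2N}, \code{EMIM},
#'   \code{BMIM}, \code{HMIM}, \code{OMIM}.
#' @examples
#' lib <- fixture_library()
#' classify_regions(lib$EPA)
#' @export
fixture_library <- function(grid = sigma_grid(), seed = 1L) {
  synthetic_profile_set(c("EPA", "Cl", "Br", "SO4", "Tf2N",
                          "EMIM", "BMIM", "HMIM", "OMIM"),
                        grid = grid, seed = seed)
}
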