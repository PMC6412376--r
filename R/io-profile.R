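#' Read a two-column sigma-profile table
#'
#' Reads a VT-2005-style text table of \code{(sigma, p(sigma))} rows
#' (whitespace- or comma-separated, \code{#} comments allowed) and places it
#' on the requested grid. When the tabulated sigma values coincide with the
#' grid's bin centers the values are copied verbatim; otherwise each row's
#' area mass is redistributed onto the grid by linear splitting between the
#' bracketing bins, which preserves the total area exactly.
#'
#' @param path Path to the table.
#' @param grid Target \code{\link{sigma_grid}}.
#' @param compound_id Identifier; defaults to the file name stem.
#' @param formal_charge,volume Optional compound metadata.
#' @return An absolute-form \code{\link{sigma_profile}}.
#' @export
read_sigma_profile <- function(path, grid = sigma_grid(),
                               compound_id = NULL, formal_charge = 0L,
                               volume = NA_real_) {
  if (!file.exists(path))
    stop(sprintf("sigma-profile file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    stop(sprintf("parse error in '%s': no data rows", path), call. = FALSE)
  toks <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  if (any(lengths(toks) < 2L))
    stop(sprintf("parse error in '%s': rows must have two columns", path),
         call. = FALSE)
  sig <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1L)))
  p <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2L)))
  if (anyNA(sig) || anyNA(p))
    stop(sprintf("parse error in '%s': non-numeric field in row %d", path,
                 which(is.na(sig) | is.na(p))[1L]), call. = FALSE)
  if (is.unsorted(sig, strictly = TRUE))
    stop(sprintf("validation error in '%s': sigma column must be strictly increasing",
                 path), call. = FALSE)
  if (any(p < 0))
    stop(sprintf("validation error in '%s': negative p(sigma) in row %d",
                 path, which(p < 0)[1L]), call. = FALSE)

  on_grid <- length(sig) == grid$n_bins &&
    max(abs(sig - grid$centers)) < 1e-9 * max(1, grid$bin_width)
  if (on_grid) {
    pg <- p
  } else {
    outside <- sig < grid$sigma_min | sig > grid$sigma_max
    if (any(p[outside] > 0))
      warning(sprintf("read_sigma_profile '%s': %d row(s) outside grid extent clipped",
                      path, sum(p[outside] > 0)), call. = FALSE)
    pg <- spread_mass(pmin(pmax(sig, grid$sigma_min), grid$sigma_max), p, grid)
  }
  sigma_profile(grid, pg,
                compound_id = compound_id %||%
                  sub("\\.[^.]*$", "", basename(path)),
                formal_charge = formal_charge, volume = volume,
                check_charge = FALSE)
}

#' Write a sigma profile as a two-column table
#'
#' @param profile A \code{\link{sigma_profile}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  txt <- c(sprintf("# sigma profile of %s", profile$compound_id),
           sprintf("# total_area = %.15g A^2; formal_charge = %+d e",
                   profile$total_area, profile$formal_charge),
           "# sigma[e/A^2]  p(sigma)[A^2]",
           sprintf("%.15g %.15g", profile$grid$centers, profile$p))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(sprintf("cannot write sigma profile to '%s'", path), call. = FALSE)
  invisible(path)
}
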