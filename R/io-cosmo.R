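#' Read a TURBOMOLE-style COSMO segment file
#'
#' Parses the \code{$segment_information} block of a \code{.cosmo} file into
#' a \code{\link{sigma_surface}}. The expected layout is the TURBOMOLE one:
#' one whitespace-separated row per segment with columns
#' \code{n atom x y z charge area charge/area potential}; column positions
#' are configurable through \code{cols} and unknown trailing columns are
#' ignored. Compound metadata (\code{compound}, \code{charge},
#' \code{volume}, \code{area}) is taken from \code{key = value} lines in the
#' header blocks when present.
#'
#' Charge densities are interpreted in e/Angstrom^2. Files declaring
#' \code{units = e/nm^2} in the header are converted on read (factor 1e-2)
#' with a notice.
#'
#' @param path Path to the file.
#' @param cols Named integer vector giving 1-based column positions of
#'   \code{area} and \code{density} (charge/area), optionally \code{x},
#'   \code{y}, \code{z}.
#' @param charge_tol Net-charge consistency tolerance passed to
#'   \code{\link{sigma_surface}}.
#' @return A \code{\link{sigma_surface}}.
#' @examples
#' s <- generate_surface(profile_spec(total_area = 100, peaks =
#'        data.frame(center = 0, width = 0.003, weight = 1)), n_segments = 50)
#' f <- tempfile(fileext = ".cosmo")
#' write_cosmo_file(s, f)
#' s2 <- read_cosmo_file(f)
#' all.equal(s$area, s2$area)
#' @export
read_cosmo_file <- function(path,
                            cols = c(x = 3L, y = 4L, z = 5L, area = 7L,
                                     density = 8L),
                            charge_tol = 0.05) {
  if (!file.exists(path))
    stop(sprintf("COSMO file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  seg_start <- grep("^\\$segment_information", lines)
  if (length(seg_start) == 0L)
    stop(sprintf("parse error in '%s': no $segment_information section",
                 path), call. = FALSE)
  seg_start <- seg_start[1L]

  header <- lines[seq_len(seg_start - 1L)]
  meta <- parse_kv_lines(header)
  unit_factor <- 1
  if (!is.null(meta$units) && grepl("nm", meta$units)) {
    unit_factor <- 1e-2
    message("read_cosmo_file: converting charge densities from e/nm^2 to e/A^2")
  }

  body <- lines[seq(seg_start + 1L, length(lines))]
  stop_at <- grep("^\\$", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1L] - 1L)]
  line_no <- seq(seg_start + 1L, seg_start + length(body))
  keep <- !grepl("^\\s*(#|$)", body)
  body <- body[keep]; line_no <- line_no[keep]
  if (length(body) == 0L)
    stop(sprintf("parse error in '%s': $segment_information block is empty",
                 path), call. = FALSE)

  need <- max(cols)
  toks <- strsplit(trimws(body), "\\s+")
  n_tok <- lengths(toks)
  if (any(n_tok < need)) {
    i <- which(n_tok < need)[1L]
    stop(sprintf("parse error in '%s' line %d: expected >= %d columns, found %d",
                 path, line_no[i], need, n_tok[i]), call. = FALSE)
  }
  pick <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", j)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("parse error in '%s' line %d: non-numeric field in column %d",
                   path, line_no[i], j), call. = FALSE)
    }
    v
  }
  area <- pick(cols[["area"]])
  density <- pick(cols[["density"]]) * unit_factor
  position <- NULL
  if (all(c("x", "y", "z") %in% names(cols)))
    position <- cbind(pick(cols[["x"]]), pick(cols[["y"]]), pick(cols[["z"]]))

  sigma_surface(
    compound_id = meta$compound %||% sub("\\.cosmo$", "", basename(path)),
    area = area, charge_density = density,
    volume = as.numeric(meta$volume %||% NA_real_),
    formal_charge = as.integer(meta$charge %||% 0L),
    position = position, charge_tol = charge_tol)
}

#' Write a sigma surface as a TURBOMOLE-style COSMO file
#'
#' Emits a header with compound metadata and a \code{$segment_information}
#' block re-readable by \code{\link{read_cosmo_file}}; numeric fields carry
#' 15 significant digits so a read/write round trip reproduces the surface.
#'
#' @param surface A valid \code{\link{sigma_surface}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cosmo_file <- function(surface, path) {
  stopifnot(inherits(surface, "sigma_surface"))
  n <- length(surface$area)
  pos <- surface$position
  if (is.null(pos)) pos <- matrix(0, n, 3L)
  seg <- sprintf("%6d %4d %.15g %.15g %.15g %.15g %.15g %.15g %.15g",
                 seq_len(n), rep(1L, n), pos[, 1L], pos[, 2L], pos[, 3L],
                 surface$area * surface$charge_density, surface$area,
                 surface$charge_density, rep(0, n))
  txt <- c("$info",
           sprintf("compound = %s", surface$compound_id),
           sprintf("charge = %d", surface$formal_charge),
           "$cosmo_data",
           sprintf("area = %.15g", surface$total_area),
           if (!is.na(surface$volume))
             sprintf("volume = %.15g", surface$volume),
           "$segment_information",
           "#  n  atom  x  y  z  charge  area  charge/area  potential",
           seg,
           "$end")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(sprintf("cannot write COSMO file to '%s'", path), call. = FALSE)
  invisible(path)
}

parse_kv_lines <- function(lines) {
  kv <- grep("^\\s*[A-Za-z_]+\\s*=", lines, value = TRUE)
  out <- list()
  for (l in kv) {
    parts <- strsplit(l, "=", fixed = TRUE)[[1L]]
    out[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
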