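#' Read a screening manifest
#'
#' A manifest is a small YAML document naming the solute, the screening
#' temperature and the cation and anion id lists whose Cartesian product
#' defines the ionic-liquid screen. Cations default to formal charge +1 and
#' anions to -1; a \code{cation_charges} / \code{anion_charges} mapping
#' overrides individual ions (e.g. sulfate at -2).
#'
#' @param path Path to the YAML manifest.
#' @return An object of class \code{screening_manifest}: a list with
#'   \code{cations} and \code{anions} (data frames of \code{id},
#'   \code{charge}), \code{solute_id}, \code{temperature} (K) and
#'   \code{n_combinations}.
#' @examples
#' m <- read_manifest(default_manifest_path())
#' m$n_combinations   # 352
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (key in c("cations", "anions"))
    if (is.null(doc[[key]]) || length(doc[[key]]) == 0L)
      stop(sprintf("manifest '%s': missing or empty '%s' list", path, key),
           call. = FALSE)
  if (is.null(doc$solute))
    stop(sprintf("manifest '%s': missing 'solute'", path), call. = FALSE)
  temperature <- doc$temperature
  if (is.null(temperature)) {
    temperature <- 298.15
    message(sprintf("read_manifest '%s': no temperature given; using 298.15 K",
                    path))
  }
  ion_table <- function(ids, default_charge, overrides) {
    ids <- as.character(unlist(ids))
    if (anyDuplicated(ids))
      stop(sprintf("manifest '%s': duplicate ion id '%s'", path,
                   ids[duplicated(ids)][1L]), call. = FALSE)
    charge <- rep(default_charge, length(ids))
    if (!is.null(overrides)) {
      unknown <- setdiff(names(overrides), ids)
      if (length(unknown))
        stop(sprintf("manifest '%s': charge override for unknown id '%s'",
                     path, unknown[1L]), call. = FALSE)
      charge[match(names(overrides), ids)] <- as.integer(unlist(overrides))
    }
    data.frame(id = ids, charge = as.integer(charge),
               stringsAsFactors = FALSE)
  }
  cations <- ion_table(doc$cations, +1L, doc$cation_charges)
  anions <- ion_table(doc$anions, -1L, doc$anion_charges)
  if (any(cations$charge <= 0L))
    stop(sprintf("manifest '%s': cation charges must be positive", path),
         call. = FALSE)
  if (any(anions$charge >= 0L))
    stop(sprintf("manifest '%s': anion charges must be negative", path),
         call. = FALSE)
  if (any(anions$id %in% cations$id))
    stop(sprintf("manifest '%s': id appears as both cation and anion", path),
         call. = FALSE)
  structure(
    list(cations = cations, anions = anions,
         solute_id = as.character(doc$solute),
         temperature = as.numeric(temperature),
         n_combinations = nrow(cations) * nrow(anions)),
    class = "screening_manifest")
}

#' @export
print.screening_manifest <- function(x, ...) {
  cat(sprintf("screening_manifest: %d cations x %d anions = %d combinations\n",
              nrow(x$cations), nrow(x$anions), x$n_combinations))
  cat(sprintf("  solute %s at %.2f K\n", x$solute_id, x$temperature))
  invisible(x)
}

#' Path to the packaged default screening manifest
#'
#' The packaged manifest lists the 16 cations (imidazolium, pyridinium,
#' pyrrolidinium, piperidinium and tetramethylammonium families) and 22
#' anions of the 352-combination EPA screen, with sulfate carrying formal
#' charge -2.
#'
#' @return File path inside the installed package.
#' @export
default_manifest_path <- function() {
  system.file("extdata", "manifest_default.yaml", package = "ilscreen",
              mustWork = TRUE)
}
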