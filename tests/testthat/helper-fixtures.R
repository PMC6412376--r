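# Shared fixtures, built in code at test time.

# small grids used across tests
grid51 <- sigma_grid()
grid5 <- sigma_grid(-0.02, 0.02, 5L)

# a smooth Gaussian-bump profile placed directly on a grid (no constructor
# charge check; used where ion-level invariants are not the point)
bump_profile <- function(grid, center, sd, area, id = "bump",
                         charge = 0L, check = FALSE) {
  p <- stats::dnorm(grid$centers, center, sd)
  p <- p * area / sum(p)
  sigma_profile(grid, p, compound_id = id, formal_charge = charge,
                check_charge = check)
}

# deterministic random surface (areas, densities, positions on a sphere)
random_surface <- function(n, seed = 1L, id = "rand", spread = 0.006) {
  set.seed(seed)
  area <- stats::runif(n, 0.2, 2)
  sig <- stats::rnorm(n, 0, spread)
  sig <- sig - sum(area * sig) / sum(area)   # neutral compound
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(sum(area) / (4 * pi))
  pos <- r * cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  sigma_surface(id, area, sig, formal_charge = 0L, position = pos)
}

# text of a tiny valid COSMO file with the given segment rows
cosmo_text <- function(area, density, compound = "toy", charge = 0L) {
  n <- length(area)
  c("$info",
    sprintf("compound = %s", compound),
    sprintf("charge = %d", charge),
    "$segment_information",
    "# n atom x y z charge area charge/area potential",
    sprintf("%d 1 0 0 0 %.10g %.10g %.10g 0",
            seq_len(n), area * density, area, density),
    "$end")
}

write_tmp <- function(lines, ext = ".cosmo") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# manifest yaml helper
manifest_text <- function(cations, anions, solute = "X", temperature = 298.15,
                          extra = character()) {
  c(sprintf("solute: %s", solute),
    if (!is.null(temperature)) sprintf("temperature: %s", temperature),
    "cations:", sprintf("  - %s", cations),
    "anions:", sprintf("  - %s", anions),
    extra)
}

# shortlist of published infinite-dilution activity coefficients and
# capacities for the EPA / ionic-liquid screen at 298.15 K (values as
# printed, 3 significant figures); used to check reciprocal capacity
# arithmetic
reference_shortlist <- function() {
  read.delim(system.file("extdata", "shortlist_reference.tsv",
                         package = "ilscreen"),
             stringsAsFactors = FALSE)
}
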