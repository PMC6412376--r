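#' Assemble an ionic-liquid solvent ensemble from two ion profiles
#'
#' An ionic liquid is modeled as a mole-fraction ensemble of its two ions.
#' Pairing mode \code{"equimolar"} uses a 1:1 ensemble regardless of ion
#' valence (so a monocation paired with a divalent sulfate-like anion keeps
#' a net charge of -1 e); mode \code{"electroneutral"} chooses the smallest
#' integer stoichiometry with zero net charge (2:1 for a divalent anion).
#'
#' @param cation,anion Absolute-form \code{\link{sigma_profile}} objects on
#'   one grid with declared formal charges.
#' @param mode \code{"equimolar"} (default) or \code{"electroneutral"}.
#' @return An object of class \code{il_solvent}: list with \code{cation_id},
#'   \code{anion_id}, \code{stoichiometry} (n_cat, n_an), \code{net_charge}
#'   (e, recorded as-is) and \code{profile} (the mixture sigma profile).
#' @examples
#' lib <- fixture_library()
#' il <- build_il_solvent(lib$EMIM, lib$SO4, mode = "electroneutral")
#' il$stoichiometry   # 2:1
#' @export
build_il_solvent <- function(cation, anion, mode = "equimolar") {
  stopifnot(inherits(cation, "sigma_profile"), inherits(anion, "sigma_profile"))
  assert_same_grid(cation$grid, anion$grid, "cation and anion")
  q_cat <- cation$formal_charge
  q_an <- anion$formal_charge
  if (q_cat <= 0L || q_an >= 0L)
    stop("build_il_solvent: cation must have charge > 0 and anion < 0",
         call. = FALSE)
  if (mode == "equimolar") {
    n_cat <- 1L; n_an <- 1L
  } else if (mode == "electroneutral") {
    g <- gcd_int(abs(q_cat), abs(q_an))
    n_cat <- abs(q_an) %/% g
    n_an <- abs(q_cat) %/% g
  } else {
    stop(sprintf("build_il_solvent: unknown pairing mode '%s'", mode),
         call. = FALSE)
  }
  x <- c(n_cat, n_an) / (n_cat + n_an)
  id <- sprintf("[%s][%s]", cation$compound_id, anion$compound_id)
  structure(
    list(cation_id = cation$compound_id, anion_id = anion$compound_id,
         stoichiometry = c(n_cat = n_cat, n_an = n_an),
         net_charge = n_cat * q_cat + n_an * q_an, mode = mode,
         profile = mix_profiles(list(cation, anion), x, compound_id = id)),
    class = "il_solvent")
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' @export
print.il_solvent <- function(x, ...) {
  cat(sprintf("il_solvent %s: stoichiometry %d:%d (%s), net charge %+d e\n",
              x$profile$compound_id, x$stoichiometry[1L], x$stoichiometry[2L],
              x$mode, x$net_charge))
  invisible(x)
}

#' Screen every cation-anion combination of a manifest
#'
#' Drives the full screening grid: for each cation x anion pair, assembles
#' the ionic-liquid solvent ensemble, solves its sigma potential, computes
#' the solute's infinite-dilution activity coefficient and capacity, and
#' returns all records ranked by capacity (descending, with a deterministic
#' lexicographic tie-break on cation then anion id). Per-combination solver
#' failures are recorded as failed rows and do not abort the screen.
#'
#' @param manifest A \code{\link{read_manifest}} result.
#' @param profiles Named list mapping every manifest id (ions and solute) to
#'   an absolute-form \code{\link{sigma_profile}}.
#' @param params \code{\link{energy_parameters}}; its temperature is
#'   replaced by the manifest temperature.
#' @param mode Ion pairing mode, see \code{\link{build_il_solvent}}.
#' @param combinatorial Include the combinatorial term, see
#'   \code{\link{ln_gamma_infinite_dilution}}.
#' @return An object of class \code{ranking_table}: a data frame with
#'   columns \code{rank}, \code{il}, \code{cation}, \code{anion}, \code{T},
#'   \code{ln_gamma_inf}, \code{gamma_inf}, \code{capacity_inf},
#'   \code{status}, plus attributes \code{temperature}, \code{n_failed} and
#'   \code{fingerprint}.
#' @examples
#' \donttest{
#' m <- read_manifest(default_manifest_path())
#' prof <- synthetic_profile_set(seed = 1)
#' rt <- run_screen(m, prof)
#' head(rt, 3)
#' }
#' @export
run_screen <- function(manifest, profiles, params = energy_parameters(),
                       mode = "equimolar", combinatorial = FALSE) {
  stopifnot(inherits(manifest, "screening_manifest"), is.list(profiles))
  ids <- c(manifest$solute_id, manifest$cations$id, manifest$anions$id)
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop(sprintf("run_screen: no profile for id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  params$T <- manifest$temperature
  solute <- profiles[[manifest$solute_id]]
  # declared charges in the manifest override profile metadata
  set_charge <- function(pr, q) { pr$formal_charge <- as.integer(q); pr }

  grid_combos <- expand.grid(cation = manifest$cations$id,
                             anion = manifest$anions$id,
                             stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid_combos))
  solute_pot <- solve_sigma_potential(solute, params)
  for (i in seq_len(nrow(grid_combos))) {
    cid <- grid_combos$cation[i]; aid <- grid_combos$anion[i]
    res <- tryCatch({
      il <- build_il_solvent(
        set_charge(profiles[[cid]],
                   manifest$cations$charge[manifest$cations$id == cid]),
        set_charge(profiles[[aid]],
                   manifest$anions$charge[manifest$anions$id == aid]),
        mode = mode)
      pot <- solve_sigma_potential(il$profile, params)
      rt <- params$R * params$T
      ln_g <- (pseudo_chemical_potential(solute, pot) -
               pseudo_chemical_potential(solute, solute_pot)) / rt
      if (combinatorial)
        ln_g <- ln_g + sg_combinatorial_inf(solute, il$profile)
      data.frame(il = il$profile$compound_id, cation = cid, anion = aid,
                 T = params$T, ln_gamma_inf = ln_g, gamma_inf = exp(ln_g),
                 capacity_inf = exp(-ln_g), status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(il = sprintf("[%s][%s]", cid, aid), cation = cid,
                 anion = aid, T = params$T, ln_gamma_inf = NA_real_,
                 gamma_inf = NA_real_, capacity_inf = NA_real_,
                 status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ord <- order(-xtfrm(tab$capacity_inf), tab$cation, tab$anion,
               na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(tab,
            class = c("ranking_table", "data.frame"),
            temperature = manifest$temperature,
            n_failed = sum(tab$status != "ok"),
            fingerprint = fingerprint(
              unlist(params), manifest$cations$id, manifest$anions$id,
              manifest$solute_id, mode, combinatorial))
}

#' @export
print.ranking_table <- function(x, ..., n = 10L) {
  cat(sprintf("ranking_table: %d ionic liquids at %.2f K (%d failed), fingerprint %s\n",
              nrow(x), attr(x, "temperature"), attr(x, "n_failed"),
              attr(x, "fingerprint")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Human-readable shortlist of a ranking table
#'
#' Formats the top of a ranking as the conventional screening shortlist:
#' rank, ionic liquid, infinite-dilution activity coefficient and capacity,
#' with values shown to 3 significant figures (the machine TSV written by
#' \code{\link{write_ranking}} keeps full precision).
#'
#' @param ranking A \code{\link{run_screen}} result.
#' @param top_n Number of rows to keep (>= 1).
#' @return A data frame with columns \code{rank}, \code{il},
#'   \code{gamma_inf}, \code{capacity_inf} (formatted character columns).
#' @export
report_table <- function(ranking, top_n = 21L) {
  stopifnot(inherits(ranking, "ranking_table"))
  top_n <- as.integer(top_n)
  if (top_n < 1L)
    stop("report_table: top_n must be >= 1", call. = FALSE)
  ok <- ranking[ranking$status == "ok", , drop = FALSE]
  top <- utils::head(ok, top_n)
  data.frame(rank = top$rank, il = top$il,
             gamma_inf = sprintf("%.3g", top$gamma_inf),
             capacity_inf = sprintf("%.3g", top$capacity_inf),
             stringsAsFactors = FALSE)
}

#' Write / read a ranking table as TSV
#'
#' Full-precision (17 significant digit) machine output; a re-read ranking
#' reproduces the ordering and values. Ranking runs with identical inputs
#' and parameters produce byte-identical files.
#'
#' @param ranking A \code{ranking_table}.
#' @param path Output TSV path.
#' @return \code{write_ranking}: invisibly, \code{path}.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking_table"))
  df <- as.data.frame(ranking)
  for (col in c("T", "ln_gamma_inf", "gamma_inf", "capacity_inf"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @return \code{read_ranking}: the ranking as a data frame (numeric columns
#'   restored; attributes other than the data are not persisted).
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("T", "ln_gamma_inf", "gamma_inf", "capacity_inf"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
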