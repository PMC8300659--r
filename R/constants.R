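#' Assay constants
#'
#' Fixed physical constants and default assay compositions used across the
#' kinetics, competition and gel workflows. Values reflect the published
#' experimental design for recombinant human vimentin: the 280 nm molar
#' absorptivity used for protein quantification, the monobromobimane (MBB)
#' alkylation mix (2.5 uM protein, 10 uM probe, i.e. a 1:4 mol/mol
#' protein:probe ratio), and the Zincon competition mix (40 uM Zincon,
#' 5 uM protein, Zincon-Zn K_D 214 nM).
#'
#' @param vimentin_extinction Molar absorptivity at 280 nm (M^-1 cm^-1).
#' @param kinetics_protein_conc Protein concentration in the kinetic assay (uM).
#' @param kinetics_probe_conc MBB concentration in the kinetic assay (uM).
#' @param zincon_conc Zincon concentration in the competition assay (uM).
#' @param competition_protein_conc Protein concentration in the competition
#'   assay (uM).
#' @param zincon_kd_nM Zincon-Zn dissociation constant (nM).
#'
#' @return A list of class `assay_constants`; the derived `probe_ratio`
#'   (probe:protein, mol/mol) is included.
#' @export
#' @examples
#' assay_constants()$probe_ratio # 4
assay_constants <- function(vimentin_extinction = 22450,
                            kinetics_protein_conc = 2.5,
                            kinetics_probe_conc = 10,
                            zincon_conc = 40,
                            competition_protein_conc = 5,
                            zincon_kd_nM = 214) {
  check_scalar(vimentin_extinction, "vimentin_extinction")
  check_scalar(kinetics_protein_conc, "kinetics_protein_conc")
  check_scalar(kinetics_probe_conc, "kinetics_probe_conc")
  check_scalar(zincon_conc, "zincon_conc")
  check_scalar(competition_protein_conc, "competition_protein_conc")
  check_scalar(zincon_kd_nM, "zincon_kd_nM")
  out <- list(
    vimentin_extinction = vimentin_extinction,
    kinetics_protein_conc = kinetics_protein_conc,
    kinetics_probe_conc = kinetics_probe_conc,
    probe_ratio = kinetics_probe_conc / kinetics_protein_conc,
    zincon_conc = zincon_conc,
    competition_protein_conc = competition_protein_conc,
    zincon_kd_nM = zincon_kd_nM
  )
  structure(out, class = "assay_constants")
}

#' Crosslinker and oxidant registry
#'
#' Registry of the cysteine crosslinkers, the amine-reactive control
#' crosslinker and the thiol oxidants used in the protection experiments,
#' with their spacer-arm lengths (Angstrom), number of reactive arms,
#' reaction chemistry and reversibility. Spacer arms: DBB 4.88, TMEA 10.3,
#' BMH 13.0, DST 6.4. Oxidants (diamide, H2O2) form reversible disulfides
#' and carry no spacer arm.
#'
#' @return A tibble with columns `name`, `chemistry` (`thiol`, `amine` or
#'   `oxidant`), `spacer_arm_a` (Angstrom, `NA` for oxidants), `arms`,
#'   `reversible`.
#' @export
#' @examples
#' crosslinker_registry()
crosslinker_registry <- function() {
  tibble(
    name = c("DBB", "TMEA", "BMH", "DST", "diamide", "H2O2"),
    chemistry = c("thiol", "thiol", "thiol", "amine", "oxidant", "oxidant"),
    spacer_arm_a = c(4.88, 10.3, 13.0, 6.4, NA_real_, NA_real_),
    arms = c(2L, 3L, 2L, 2L, NA_integer_, NA_integer_),
    reversible = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

#' Read or write the crosslinker registry as JSON
#'
#' The registry is an editable table; these helpers round-trip it through a
#' plain JSON file so modified spacer arms or additional reagents can be
#' shared between the gel-densitometry and structure-geometry workflows.
#'
#' @param registry A registry tibble as returned by [crosslinker_registry()].
#' @param path File path.
#' @return `read_crosslinker_registry()` returns the registry tibble;
#'   `write_crosslinker_registry()` returns `path` invisibly.
#' @export
write_crosslinker_registry <- function(registry, path) {
  check_columns(registry, c("name", "chemistry", "spacer_arm_a"), "registry")
  if (anyDuplicated(registry$name)) abort("registry names must be unique.")
  jsonlite::write_json(registry, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_crosslinker_registry
#' @export
read_crosslinker_registry <- function(path) {
  out <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  check_columns(out, c("name", "chemistry", "spacer_arm_a"), "registry file")
  out$arms <- as.integer(out$arms)
  out
}
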