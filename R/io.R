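#' Read and write the package's CSV schemas
#'
#' Thin readr wrappers over the three tabular interchange formats:
#' kinetics plates (`well_id, role, variant, ph_nominal, ph_final,
#' replicate, time_min, fluorescence_au`), gel lane tables (`lane_id,
#' variant, agent, agent_conc_um, pre_salt, salt_conc_um, replicate,
#' band, intensity_au`), competition titrations (`curve_id,
#' protein_total_um, zn_total_um, a620`), and the derived k_obs table
#' (`ph_final, kobs, stderr, n, r_squared`). Writers simply persist the
#' corresponding tibbles; readers validate the columns.
#'
#' @param path File path.
#' @param x A tibble with the matching schema.
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name zincys_csv
NULL

read_schema <- function(path, cols, what) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, cols, what)
  out
}

write_schema <- function(x, path, cols, what) {
  check_columns(x, cols, what)
  readr::write_csv(as_tibble(x)[, cols], path, progress = FALSE)
  invisible(path)
}

kinetics_cols <- c("well_id", "role", "variant", "ph_nominal", "ph_final",
                   "replicate", "time_min", "fluorescence_au")
gel_cols <- c("lane_id", "variant", "agent", "agent_conc_um", "pre_salt",
              "salt_conc_um", "replicate", "band", "intensity_au")
competition_cols <- c("curve_id", "protein_total_um", "zn_total_um", "a620")
kobs_cols <- c("ph_final", "kobs_mean", "sem", "n")

#' @rdname zincys_csv
#' @export
read_kinetics_csv <- function(path) {
  read_schema(path, kinetics_cols, "kinetics CSV")
}

#' @rdname zincys_csv
#' @export
write_kinetics_csv <- function(x, path) {
  write_schema(x, path, kinetics_cols, "kinetics table")
}

#' @rdname zincys_csv
#' @export
read_gel_csv <- function(path) read_schema(path, gel_cols, "gel CSV")

#' @rdname zincys_csv
#' @export
write_gel_csv <- function(x, path) write_schema(x, path, gel_cols, "gel table")

#' @rdname zincys_csv
#' @export
read_competition_csv <- function(path) {
  out <- read_schema(path, competition_cols, "competition CSV")
  structure(out, class = c("competition_assay", class(out)))
}

#' @rdname zincys_csv
#' @export
write_competition_csv <- function(x, path) {
  write_schema(x, path, competition_cols, "competition table")
}

#' @rdname zincys_csv
#' @export
read_kobs_csv <- function(path) {
  out <- read_schema(path, kobs_cols, "k_obs CSV")
  structure(out, class = c("titration_curve", class(out)))
}

#' @rdname zincys_csv
#' @export
write_kobs_csv <- function(x, path) {
  write_schema(x, path, kobs_cols, "k_obs table")
}
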