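#' Closed-form observed alkylation rate
#'
#' Evaluates the generator's rate law: a pH-independent baseline plus one
#' Henderson-Hasselbalch term per ionizable site, each contributing its
#' limiting rate scaled by the thiolate fraction
#' `1 / (1 + 10^(pKa - pH))`. This is the ground truth against which the
#' `ln(Ft/Fo)` slope estimator and the titration fit are checked.
#'
#' @param preset A [kinetics_preset()].
#' @param ph pH value(s); vectorised.
#' @return Observed rate(s) k_obs in min^-1; non-decreasing in pH.
#' @export
#' @examples
#' true_kobs(kinetics_preset("wt"), 7.39)
true_kobs <- function(preset, ph) {
  stopifnot(inherits(preset, "kinetics_preset"))
  if (!all(is.finite(ph))) abort("`ph` must be finite.")
  vapply(ph, function(p) {
    preset$baseline_rate +
      sum(preset$limiting_rates / (1 + 10^(preset$pka_values - p)))
  }, numeric(1))
}

# noiseless fluorescence trajectory for one well
kinetic_curve <- function(times, f0, fmax, k,
                          family = c("logistic", "exponential")) {
  family <- match.arg(family)
  if (family == "logistic") {
    # logistic growth anchored at F(0) = f0, upper asymptote fmax;
    # written with exp(-k t) so large k t cannot overflow
    fmax / (1 + ((fmax - f0) / f0) * exp(-k * times))
  } else {
    # saturating exponential with the same endpoints
    fmax - (fmax - f0) * exp(-k * times)
  }
}

#' Simulate an alkylation kinetics plate
#'
#' Generates per-well fluorescence time series for an MBB-style alkylation
#' assay: for every nominal pH and replicate, a sample well following the
#' preset's growth-curve family with rate `true_kobs(preset, ph)` plus
#' additive Gaussian noise, and one protein-free background well per pH,
#' flat at the bottom plateau plus noise. The measured pH (`ph_final`) is
#' simulated once per buffer (shared by the wells at that nominal pH) as
#' nominal + N(0, 0.03).
#'
#' Output is deterministic given the preset (including its seed); the
#' global RNG state is left untouched.
#'
#' @param preset A [kinetics_preset()].
#' @return A tibble in long format with columns `well_id`, `role`
#'   (`sample`/`background`), `variant`, `ph_nominal`, `ph_final`,
#'   `replicate`, `time_min`, `fluorescence_au`, carrying the preset in the
#'   `"preset"` attribute (noise magnitude and curve family are thereby
#'   reported with the data).
#' @export
#' @examples
#' plate <- make_kinetics_plate(kinetics_preset("wt", seed = 1))
#' dplyr::count(plate, role)
make_kinetics_plate <- function(preset) {
  stopifnot(inherits(preset, "kinetics_preset"))
  withr::with_seed(preset$seed, {
    ph_final <- preset$ph_grid + rnorm(length(preset$ph_grid), 0, 0.03)
    nt <- length(preset$times)
    wells <- purrr::map_dfr(seq_along(preset$ph_grid), function(i) {
      ph_nom <- preset$ph_grid[i]
      k <- true_kobs(preset, ph_final[i])
      sample_wells <- purrr::map_dfr(seq_len(preset$replicates), function(r) {
        f <- kinetic_curve(preset$times, preset$f0, preset$fmax, k,
                           preset$curve_family) +
          rnorm(nt, 0, preset$noise_sd)
        tibble(
          well_id = sprintf("%s_pH%04.1f_r%d", preset$variant, ph_nom, r),
          role = "sample", variant = preset$variant,
          ph_nominal = ph_nom, ph_final = ph_final[i],
          replicate = r, time_min = preset$times, fluorescence_au = f
        )
      })
      bg <- tibble(
        well_id = sprintf("bg_pH%04.1f", ph_nom),
        role = "background", variant = preset$variant,
        ph_nominal = ph_nom, ph_final = ph_final[i],
        replicate = 1L, time_min = preset$times,
        fluorescence_au = preset$f0 + rnorm(nt, 0, preset$noise_sd)
      )
      bind_rows(sample_wells, bg)
    })
    attr(wells, "preset") <- preset
    wells
  })
}
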