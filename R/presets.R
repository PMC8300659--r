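#' Kinetics simulation presets
#'
#' Parameter sets for the synthetic plate-reader generator
#' ([make_kinetics_plate()]). The `"wt"` preset encodes the published
#' wild-type behaviour of the vimentin Cys328 thiol: two ionization steps
#' with pK_a 4.61 and 7.39 whose deprotonation accelerates alkylation by
#' monobromomimane, sampled every 3 min for 90 min over a 17-point buffer
#' grid from pH 3 to 10.8 in triplicate. The `"C328S"` preset is the
#' cysteine-free control: a small pH-independent background rate only.
#'
#' Fluorescence-scale parameters (plateaus, noise) are instrument-side
#' choices not tied to published numbers; see the methods vignette for the
#' rationale behind the defaults.
#'
#' @param variant `"wt"` or `"C328S"`.
#' @param pka_values Site pK_a values (pH units), ascending. Length 2 for
#'   `"wt"`, empty for `"C328S"`.
#' @param limiting_rates Per-site maximal contribution to k_obs (min^-1),
#'   same length as `pka_values`.
#' @param baseline_rate pH-independent background rate (min^-1).
#' @param f0,fmax Bottom and top fluorescence plateaus (AU); `fmax > f0 > 0`.
#' @param noise_sd Additive Gaussian fluorescence noise SD (AU).
#' @param ph_grid Nominal buffer pH values.
#' @param times Sampling times (min), strictly increasing, at least 5 points.
#' @param replicates Sample wells per pH.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   preset.
#' @param curve_family `"logistic"` (default) or `"exponential"`; the
#'   alternative saturating-exponential family exists to probe estimator
#'   robustness against a curve whose early log-phase is not exactly the
#'   rate constant.
#'
#' @return A list of class `kinetics_preset`.
#' @export
#' @examples
#' kinetics_preset("wt", seed = 1)$pka_values
kinetics_preset <- function(variant = c("wt", "C328S"),
                            pka_values = NULL,
                            limiting_rates = NULL,
                            baseline_rate = 0.002,
                            f0 = 50,
                            fmax = 500,
                            noise_sd = 2,
                            ph_grid = c(3, 3.5, 4, 4.5, 5, 5.5, 6, 6.5, 7,
                                        7.5, 8, 8.5, 9, 9.5, 10, 10.4, 10.8),
                            times = seq(0, 90, by = 3),
                            replicates = 3L,
                            seed = 1L,
                            curve_family = c("logistic", "exponential")) {
  variant <- match.arg(variant)
  curve_family <- match.arg(curve_family)
  if (is.null(pka_values)) {
    pka_values <- if (variant == "wt") c(4.61, 7.39) else numeric(0)
  }
  if (is.null(limiting_rates)) {
    limiting_rates <- if (variant == "wt") c(0.015, 0.030) else numeric(0)
  }
  if (variant == "wt" && length(pka_values) != 2L) {
    abort("the `wt` preset has exactly 2 ionization sites.")
  }
  if (variant == "C328S" && length(pka_values) != 0L) {
    abort("the `C328S` preset has no ionization sites (baseline only).")
  }
  if (length(limiting_rates) != length(pka_values)) {
    abort("`limiting_rates` must have the same length as `pka_values`.")
  }
  if (length(pka_values) > 1 && is.unsorted(pka_values, strictly = TRUE)) {
    abort("`pka_values` must be sorted ascending.")
  }
  for (nm in c("baseline_rate", "f0", "fmax")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(noise_sd, "noise_sd", positive = FALSE)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!all(is.finite(pka_values)) || !all(is.finite(limiting_rates))) {
    abort("`pka_values` and `limiting_rates` must be finite.")
  }
  if (any(limiting_rates < 0)) abort("`limiting_rates` must be non-negative.")
  if (fmax <= f0) abort("`fmax` must exceed `f0`.")
  if (length(times) < 5L) abort("`times` needs at least 5 points.")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  if (!all(is.finite(ph_grid))) abort("`ph_grid` must be finite.")
  structure(list(
    variant = variant,
    pka_values = pka_values,
    limiting_rates = limiting_rates,
    baseline_rate = baseline_rate,
    f0 = f0, fmax = fmax, noise_sd = noise_sd,
    ph_grid = ph_grid, times = times,
    replicates = as.integer(replicates),
    seed = as.integer(seed),
    curve_family = curve_family
  ), class = "kinetics_preset")
}

#' Gel densitometry simulation designs
#'
#' Experimental designs for the synthetic gel/blot generator
#' ([make_gel_table()]). Each design row describes one lane condition:
#' modifying or crosslinking agent, cation pre-incubation, the true
#' underlying inhibition fraction, and the control (no-salt) band ratio.
#'
#' Packaged presets:
#' \describe{
#'   \item{`"figure6A"`}{Spacer-length selectivity of zinc protection against
#'     thiol crosslinking: 500 uM ZnCl2 inhibits oligomer formation by 76%
#'     for DBB (4.88 A spacer) and 56% for TMEA (10.3 A), with no
#'     significant inhibition for BMH (13.0 A) and none for the
#'     amine-reactive control DST (the published result encoded by the
#'     preset).}
#'   \item{`"figure2D"`}{Concentration-dependent zinc protection against
#'     Iac-B modification (biotin/vimentin ratio falls monotonically with
#'     ZnCl2; magnitudes other than the direction are illustrative).}
#'   \item{`"figure7"`}{Magnesium controls: no protection of Iac-B
#'     modification at <= 50 uM MgCl2, a mild decrease at 500 uM, and
#'     *enhancement* of DBB crosslinking at 500 uM MgCl2 (negative
#'     inhibition).}
#'   \item{`"nacl"`}{NaCl-polymerised protein shows increased DBB
#'     crosslinking relative to soluble protein (negative inhibition).}
#' }
#'
#' @param preset One of `"figure6A"`, `"figure2D"`, `"figure7"`, `"nacl"`,
#'   or `"custom"` (then `design` must be supplied).
#' @param design For `preset = "custom"`, a tibble with columns `variant`,
#'   `agent`, `agent_conc_um`, `pre_salt`, `salt_conc_um`, `true_inhibition`,
#'   `baseline_ratio`, `replicates`.
#' @param noise_cv Coefficient of variation of the lognormal band-intensity
#'   noise (dimensionless, >= 0).
#' @param seed Integer seed.
#'
#' @return A list of class `gel_design` with elements `design` (tibble),
#'   `noise_cv`, `seed`.
#' @export
#' @examples
#' gel_design("figure6A")$design
gel_design <- function(preset = c("figure6A", "figure2D", "figure7", "nacl",
                                  "custom"),
                       design = NULL,
                       noise_cv = 0.08,
                       seed = 1L) {
  preset <- match.arg(preset)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || is.na(noise_cv) ||
      noise_cv < 0) {
    abort("`noise_cv` must be a single non-negative number.")
  }
  row <- function(agent, salt, salt_conc, inhib, base = 0.8, conc = 25,
                  reps = 3L) {
    tibble(variant = "wt", agent = agent, agent_conc_um = conc,
           pre_salt = salt, salt_conc_um = salt_conc,
           true_inhibition = inhib, baseline_ratio = base,
           replicates = as.integer(reps))
  }
  if (preset == "figure6A") {
    design <- bind_rows(
      row("DBB",  "none",  0,  0.00), row("DBB",  "ZnCl2", 500, 0.76),
      row("TMEA", "none",  0,  0.00), row("TMEA", "ZnCl2", 500, 0.56),
      row("BMH",  "none",  0,  0.00), row("BMH",  "ZnCl2", 500, 0.00),
      row("DST",  "none",  0,  0.00), row("DST",  "ZnCl2", 500, 0.00)
    )
  } else if (preset == "figure2D") {
    zn <- c(0, 5, 10, 50, 100, 500)
    inh <- c(0, 0.15, 0.30, 0.50, 0.65, 0.80)
    design <- purrr::map2_dfr(zn, inh, function(z, i) {
      row("IacB", if (z == 0) "none" else "ZnCl2", z, i, base = 1.0,
          conc = 50)
    })
  } else if (preset == "figure7") {
    design <- bind_rows(
      row("IacB", "none",  0,   0.00, base = 1.0, conc = 50),
      row("IacB", "MgCl2", 5,   0.00, base = 1.0, conc = 50),
      row("IacB", "MgCl2", 50,  0.00, base = 1.0, conc = 50),
      row("IacB", "MgCl2", 500, 0.20, base = 1.0, conc = 50),
      row("DBB",  "none",  0,   0.00),
      row("DBB",  "MgCl2", 500, -0.40)
    )
  } else if (preset == "nacl") {
    design <- bind_rows(
      row("DBB", "none", 0, 0.00),
      row("DBB", "NaCl", 100000, -0.50)
    )
  } else {
    if (is.null(design)) abort("`design` must be supplied for preset 'custom'.")
  }
  design <- as_tibble(design)
  check_columns(design, c("variant", "agent", "agent_conc_um", "pre_salt",
                          "salt_conc_um", "true_inhibition", "baseline_ratio",
                          "replicates"), "gel design")
  if (any(design$baseline_ratio <= 0)) abort("`baseline_ratio` must be > 0.")
  if (any(design$true_inhibition > 1)) {
    abort("`true_inhibition` cannot exceed 1 (complete inhibition).")
  }
  structure(list(design = design, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "gel_design")
}

#' Toy structure arrangements
#'
#' Parameter sets for the two-chain cysteine-pair fixtures built by
#' [make_structure_fixture()]. The `"nearby"` and `"distant"` arrangements
#' reproduce the two antiparallel dimer-of-dimers geometries studied for
#' vimentin, with inter-chain Cys SG-SG separations of 4 A and 22 A
#' respectively. Ions can be pinned at a coordination distance from a
#' cysteine sulfur (default 2.5 A, the Zn-S coordination bond length) in
#' every frame, or released on a random walk far from the protein.
#'
#' @param name `"nearby"`, `"distant"` or `"custom"`.
#' @param sg_distance Inter-chain SG-SG separation in frame 1 (Angstrom).
#' @param n_frames Number of trajectory frames (>= 1).
#' @param ions A tibble (or data frame) with one row per ion: columns
#'   `element` (e.g. `"ZN"`, `"MG"`), `rule` (`"pinned"` or `"walk"`),
#'   `contact_distance` (Angstrom; used for pinned ions). `NULL` for none.
#' @param frame_jitter_sd Gaussian positional jitter added to protein atoms
#'   in frames after the first (Angstrom).
#' @param seed Integer seed.
#'
#' @return A list of class `structure_arrangement`.
#' @export
#' @examples
#' structure_arrangement("nearby")$sg_distance
structure_arrangement <- function(name = c("nearby", "distant", "custom"),
                                  sg_distance = NULL,
                                  n_frames = 1L,
                                  ions = NULL,
                                  frame_jitter_sd = 0.3,
                                  seed = 1L) {
  name <- match.arg(name)
  if (is.null(sg_distance)) {
    sg_distance <- switch(name, nearby = 4.0, distant = 22.0,
                          abort("`sg_distance` must be given for 'custom'."))
  }
  check_scalar(sg_distance, "sg_distance")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1) {
    abort("`n_frames` must be a single integer >= 1.")
  }
  if (frame_jitter_sd < 0) abort("`frame_jitter_sd` must be non-negative.")
  if (!is.null(ions)) {
    ions <- as_tibble(ions)
    check_columns(ions, c("element", "rule"), "`ions`")
    if (!all(ions$rule %in% c("pinned", "walk"))) {
      abort("ion `rule` must be 'pinned' or 'walk'.")
    }
    if (!"contact_distance" %in% names(ions)) {
      ions$contact_distance <- 2.5
    }
    ions$contact_distance[is.na(ions$contact_distance)] <- 2.5
  }
  structure(list(
    name = name, sg_distance = sg_distance,
    n_frames = as.integer(n_frames), ions = ions,
    frame_jitter_sd = frame_jitter_sd, seed = as.integer(seed)
  ), class = "structure_arrangement")
}
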