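test_that("true_kobs matches the closed-form rate law and its limits", {
  p <- kinetics_preset("wt")
  # fully protonated / deprotonated limits
  expect_equal(true_kobs(p, -50), p$baseline_rate, tolerance = 1e-10)
  expect_equal(true_kobs(p, 50),
               p$baseline_rate + sum(p$limiting_rates), tolerance = 1e-10)
  # each site contributes exactly half its limiting rate at its pK_a
  for (i in 1:2) {
    others <- oracle_rate_law(p$pka_values[i], p$baseline_rate,
                              p$pka_values[-i], p$limiting_rates[-i])
    expect_equal(true_kobs(p, p$pka_values[i]),
                 others + p$limiting_rates[i] / 2, tolerance = 1e-12)
  }
  # random pH agree with the independent oracle, and monotone in pH
  ph <- sort(runif(25, 2, 12))
  expect_equal(true_kobs(p, ph),
               oracle_rate_law(ph, p$baseline_rate, p$pka_values,
                               p$limiting_rates),
               tolerance = 1e-12)
  expect_true(all(diff(true_kobs(p, ph)) >= 0))
  expect_error(true_kobs(p, NaN), "finite")
})

test_that("kinetics generator honours zero-rate and zero-noise identities", {
  # baseline only, zero rate, zero noise: every point sits at f0
  p <- kinetics_preset("C328S", baseline_rate = 1e-12, noise_sd = 0,
                       ph_grid = c(5, 7), replicates = 2, seed = 3)
  plate <- make_kinetics_plate(p)
  samp <- dplyr::filter(plate, role == "sample")
  expect_equal(samp$fluorescence_au, rep(p$f0, nrow(samp)),
               tolerance = 1e-6)
  # background wells are flat at f0
  bg <- dplyr::filter(plate, role == "background")
  expect_equal(bg$fluorescence_au, rep(p$f0, nrow(bg)), tolerance = 1e-12)
})

test_that("noiseless single-site early-phase log-slope equals the rate law at the midpoint", {
  # single site at pK_a 7 probed at pH 7: theta = 0.5, so the true rate is
  # baseline + limiting/2 (computed by the independent oracle)
  p <- kinetics_preset("wt", pka_values = c(7, 10.5),
                       limiting_rates = c(0.02, 0), baseline_rate = 0.001,
                       noise_sd = 0, ph_grid = 7, replicates = 1, seed = 1)
  truth <- oracle_rate_law(7, 0.001, 7, 0.02)
  expect_equal(true_kobs(p, 7), truth, tolerance = 1e-12)
  plate <- make_kinetics_plate(p)
  tr <- dplyr::filter(plate, role == "sample")
  # ph_final jitter moves the realised rate slightly; evaluate at ph_final
  k_at_final <- true_kobs(p, tr$ph_final[1])
  lf <- log(tr$fluorescence_au / p$f0)
  early <- tr$time_min <= 12
  slope <- coef(lm(lf[early] ~ tr$time_min[early]))[2]
  expect_equal(unname(slope), k_at_final, tolerance = 0.02)
})

test_that("generators are deterministic under a fixed seed", {
  p <- kinetics_preset("wt", seed = 11)
  expect_identical(make_kinetics_plate(p), make_kinetics_plate(p))
  g <- gel_design("figure6A", seed = 7)
  expect_identical(make_gel_table(g), make_gel_table(g))
  a <- make_competition_curves(seed = 5)
  expect_identical(a, make_competition_curves(seed = 5))
  arr <- structure_arrangement("nearby", n_frames = 4, seed = 9,
                               frame_jitter_sd = 0.4)
  f1 <- make_structure_fixture(arr)
  f2 <- make_structure_fixture(arr)
  expect_identical(f1$coords, f2$coords)
  # different seeds change the noise
  expect_false(identical(
    make_kinetics_plate(kinetics_preset("wt", seed = 1)),
    make_kinetics_plate(kinetics_preset("wt", seed = 2))))
})

test_that("preset validation rejects inconsistent parameters", {
  expect_error(kinetics_preset("wt", pka_values = c(7.39, 4.61)),
               "ascending")
  expect_error(kinetics_preset("wt", pka_values = c(4.61, 7.39),
                               limiting_rates = 0.1), "length")
  expect_error(kinetics_preset("wt", fmax = 10, f0 = 50), "exceed")
  expect_error(kinetics_preset("wt", noise_sd = NaN), "numeric|finite")
  expect_error(kinetics_preset("wt", baseline_rate = Inf), "finite")
  expect_error(kinetics_preset("C328S", pka_values = 5), "no ionization")
  expect_error(gel_design(noise_cv = -0.1), "non-negative")
  expect_error(structure_arrangement("custom"), "sg_distance")
  expect_error(structure_arrangement("nearby", n_frames = 0), ">= 1")
})

test_that("gel generator hits its expected ratios exactly when noiseless", {
  d <- gel_design("custom", noise_cv = 0, seed = 1, design = tibble::tibble(
    variant = "wt", agent = c("DBB", "DBB", "IacB"),
    agent_conc_um = 25, pre_salt = c("none", "ZnCl2", "none"),
    salt_conc_um = c(0, 500, 0), true_inhibition = c(0, 1, 0.25),
    baseline_ratio = c(0.8, 0.8, 1.2), replicates = 2L))
  lanes <- make_gel_table(d)
  r <- lane_ratios(lanes)
  expect_equal(r$ratio[r$pre_salt == "none" & r$agent == "DBB"],
               c(0.8, 0.8))
  # complete inhibition: the quantified band vanishes
  expect_equal(r$ratio[r$pre_salt == "ZnCl2"], c(0, 0))
  expect_equal(r$ratio[r$agent == "IacB"], c(0.9, 0.9))
  expect_equal(unique(r$ratio_kind[r$agent == "IacB"]), "modification")
})

test_that("figure6A preset recovers its inhibition fractions within Monte-Carlo tolerance", {
  g <- gel_design("figure6A", seed = 42)
  pr <- quantify_protection(make_gel_table(g))
  set.seed(1)
  for (agent_i in c("DBB", "TMEA")) {
    truth <- g$design$true_inhibition[g$design$agent == agent_i &
                                        g$design$pre_salt == "ZnCl2"]
    mc <- oracle_inhibition_mc(truth, 0.8, g$noise_cv, 3)
    band <- quantile(mc, c(0.0005, 0.9995))
    est <- pr$percent_inhibition[pr$agent == agent_i]
    expect_gt(est, band[1])
    expect_lt(est, band[2])
  }
})

test_that("competition generator round-trips through the species solver", {
  truth <- binding_model(kd_protein_uM = 0.5, n_sites = 2)
  assay <- make_competition_curves(model = truth, noise_sd = 0, seed = 1)
  zt <- attr(assay, "zincon_total")
  with_p <- dplyr::filter(assay, curve_id == "with_protein")
  again <- predict_absorbance(
    solve_species(with_p$zn_total_um, truth, zincon_total = zt,
                  protein_total = attr(assay, "protein_total")), truth)
  expect_equal(with_p$a620, again, tolerance = 1e-12)
  # zn_total = 0 sits at the baseline on both curves
  expect_equal(assay$a620[assay$zn_total_um == 0],
               rep(truth$abs_baseline, 2), tolerance = 1e-12)
})

test_that("a non-competing protein leaves the two curves identical (noise off)", {
  weak <- binding_model(kd_protein_uM = 1e9, n_sites = 1)
  assay <- make_competition_curves(model = weak, noise_sd = 0, seed = 1)
  a <- dplyr::filter(assay, curve_id == "no_protein")$a620
  b <- dplyr::filter(assay, curve_id == "with_protein")$a620
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("estimator SD shrinks roughly as 1/sqrt(replicates)", {
  # spread of the DBB percent-inhibition estimate across seeds, 3 vs 12
  # replicates; lognormal noise model makes the SD scale ~ 1/sqrt(n)
  est <- function(reps, s) {
    d <- gel_design("custom", noise_cv = 0.15, seed = s,
                    design = tibble::tibble(
                      variant = "wt", agent = "DBB", agent_conc_um = 25,
                      pre_salt = c("none", "ZnCl2"),
                      salt_conc_um = c(0, 500),
                      true_inhibition = c(0, 0.76), baseline_ratio = 0.8,
                      replicates = as.integer(reps)))
    quantify_protection(make_gel_table(d))$percent_inhibition
  }
  sd3 <- sd(vapply(1:40, function(s) est(3, s), numeric(1)))
  sd12 <- sd(vapply(1:40, function(s) est(12, s), numeric(1)))
  expect_equal(sd3 / sd12, 2, tolerance = 0.5)
})
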