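lane_tbl <- function(bands, intensities, id = "L1", agent = "DBB",
                     pre_salt = "none", salt_conc = 0, replicate = 1) {
  tibble::tibble(lane_id = id, variant = "wt", agent = agent,
                 agent_conc_um = 25, pre_salt = pre_salt,
                 salt_conc_um = salt_conc, replicate = replicate,
                 band = bands, intensity_au = intensities)
}

test_that("band ratios compute and validate per lane", {
  expect_equal(modification_ratio(lane_tbl(c("biotin", "vimentin"),
                                           c(200, 100))), 2)
  expect_equal(modification_ratio(lane_tbl(c("biotin", "vimentin"),
                                           c(0, 100))), 0)
  expect_equal(oligomer_ratio(lane_tbl(c("oligomer", "monomer"),
                                       c(50, 100))), 0.5)
  expect_error(modification_ratio(lane_tbl(c("biotin", "vimentin"),
                                           c(10, 0))), "intensity is 0")
  expect_error(oligomer_ratio(lane_tbl("oligomer", 50)), "exactly one")
})

test_that("percent inhibition follows its defining identity and edge cases", {
  ctl <- dplyr::bind_rows(lapply(1:3, function(r) {
    lane_tbl(c("oligomer", "monomer"), c(80, 100), id = paste0("c", r),
             replicate = r)
  }))
  # treated identical to control: 0% inhibition
  expect_equal(percent_inhibition(ctl, ctl)$percent_inhibition, 0)
  # treated ratios all zero: 100%
  gone <- dplyr::mutate(ctl,
    intensity_au = ifelse(band == "oligomer", 0, intensity_au),
    pre_salt = "ZnCl2", salt_conc_um = 500)
  res <- percent_inhibition(gone, ctl)
  expect_equal(res$percent_inhibition, 100)
  expect_equal(res$ratio_treated, 0)
  # scale invariance: multiplying all intensities in a lane set by a
  # constant leaves the result unchanged
  up <- dplyr::mutate(gone, intensity_au = intensity_au * 37)
  ctl_up <- dplyr::mutate(ctl, intensity_au = intensity_au * 0.01)
  expect_equal(percent_inhibition(up, ctl_up)$percent_inhibition, 100)
  mixed <- dplyr::mutate(ctl, pre_salt = "ZnCl2",
    intensity_au = ifelse(band == "oligomer", intensity_au * 1.5,
                          intensity_au))
  r1 <- percent_inhibition(mixed, ctl)$percent_inhibition
  r2 <- percent_inhibition(
    dplyr::mutate(mixed, intensity_au = intensity_au * 5),
    dplyr::mutate(ctl, intensity_au = intensity_au * 5))$percent_inhibition
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, -50) # enhancement reported as negative, unclipped
})

test_that("figure6A estimates sit within the Monte-Carlo envelope of the design", {
  g <- gel_design("figure6A", seed = 3)
  pr <- quantify_protection(make_gel_table(g))
  set.seed(11)
  mc_dbb <- oracle_inhibition_mc(0.76, 0.8, g$noise_cv, 3)
  est <- pr$percent_inhibition[pr$agent == "DBB"]
  expect_gt(est, quantile(mc_dbb, 0.0005))
  expect_lt(est, quantile(mc_dbb, 0.9995))
  # spacer trend across the three thiol crosslinkers is strictly inverse
  tr <- protection_vs_spacer(dplyr::filter(pr, agent %in%
                                             c("DBB", "TMEA", "BMH")))
  expect_equal(tr$rho, -1)
  expect_equal(tr$trend, "inverse")
})

test_that("DST (amine chemistry) shows no protection across seeds", {
  est <- vapply(1:50, function(s) {
    d <- gel_design("custom", noise_cv = 0.08, seed = s,
                    design = tibble::tibble(
                      variant = "wt", agent = "DST", agent_conc_um = 25,
                      pre_salt = c("none", "ZnCl2"),
                      salt_conc_um = c(0, 500),
                      true_inhibition = 0, baseline_ratio = 0.8,
                      replicates = 3L))
    quantify_protection(make_gel_table(d))$percent_inhibition
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)))
})

test_that("magnesium preset reproduces the published directions", {
  pr <- quantify_protection(make_gel_table(gel_design("figure7", seed = 2)))
  lowmg <- dplyr::filter(pr, agent == "IacB", salt_conc_um <= 50)
  # low-micromolar magnesium does not protect the modification readout
  expect_true(all(abs(lowmg$percent_inhibition) < 15))
  # magnesium *enhances* DBB crosslinking (negative inhibition)
  dbb <- dplyr::filter(pr, agent == "DBB", salt_conc_um == 500)
  expect_lt(dbb$percent_inhibition, 0)
  # NaCl-polymerised protein crosslinks more than soluble protein
  nacl <- quantify_protection(make_gel_table(gel_design("nacl", seed = 2)))
  expect_lt(nacl$percent_inhibition, 0)
})

test_that("zinc concentration series protects monotonically on average", {
  pr <- quantify_protection(make_gel_table(gel_design("figure2D", seed = 5)))
  pr <- dplyr::arrange(pr, salt_conc_um)
  # allow small noise inversions between adjacent levels but require the
  # overall rise from the weakest to the strongest condition
  expect_gt(dplyr::last(pr$percent_inhibition),
            dplyr::first(pr$percent_inhibition))
  expect_gt(cor(pr$salt_conc_um, pr$percent_inhibition, method = "spearman"),
            0.5)
})

test_that("spacer trend handles ties and input order", {
  res <- tibble::tibble(agent = c("DBB", "TMEA", "BMH"),
                        percent_inhibition = c(76, 56, 0))
  tr <- protection_vs_spacer(res)
  expect_equal(tr$rho, -1)
  tr_shuffled <- protection_vs_spacer(res[c(3, 1, 2), ])
  expect_equal(tr$pairs, tr_shuffled$pairs)
  expect_equal(tr$rho, tr_shuffled$rho)
  flat <- tibble::tibble(agent = c("DBB", "TMEA", "BMH"),
                         percent_inhibition = c(40, 40, 40))
  expect_equal(protection_vs_spacer(flat)$trend, "flat")
  expect_error(protection_vs_spacer(res[c(1, 1, 2), ]), "duplicate")
  expect_error(protection_vs_spacer(res[1:2, ]), "at least 3")
})

test_that("compare_conditions covers degenerate and powered cases", {
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  paired0 <- compare_conditions(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(paired0$statistic, 0)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
  # power under the published DBB effect size: rejection rate >= 0.8
  reject <- vapply(1:100, function(s) {
    d <- gel_design("custom", noise_cv = 0.1, seed = s,
                    design = tibble::tibble(
                      variant = "wt", agent = "DBB", agent_conc_um = 25,
                      pre_salt = c("none", "ZnCl2"),
                      salt_conc_um = c(0, 500),
                      true_inhibition = c(0, 0.76), baseline_ratio = 0.8,
                      replicates = 3L))
    quantify_protection(make_gel_table(d))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.8)
})

test_that("gel CSV schema round-trips", {
  lanes <- make_gel_table(gel_design("figure6A", seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gel_csv(lanes, path)
  back <- read_gel_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(lanes)[names(back)],
               tolerance = 1e-12)
})
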