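#' Simulate a gel/blot densitometry table
#'
#' Generates band-intensity lanes for the protection experiments. Each
#' design row yields `replicates` lanes. The reference band (`vimentin`
#' for modification agents, `monomer` for crosslinkers and oxidants) is
#' drawn lognormal around a fixed expected intensity (1000 AU); the
#' quantified band (`biotin` or `oligomer`) is the reference intensity
#' times a lognormal ratio with expectation
#' `baseline_ratio * (1 - true_inhibition)`. Both lognormals use the
#' design's coefficient of variation, so the *observed per-lane ratio* has
#' exactly the design's expected value at any noise level.
#'
#' @param gdesign A [gel_design()].
#' @return A tibble in long format with columns `lane_id`, `variant`,
#'   `agent`, `agent_conc_um`, `pre_salt`, `salt_conc_um`, `replicate`,
#'   `band`, `intensity_au`; the design is attached as the `"design"`
#'   attribute.
#' @export
#' @examples
#' lanes <- make_gel_table(gel_design("figure6A", seed = 1))
#' dplyr::count(lanes, agent, pre_salt)
make_gel_table <- function(gdesign) {
  stopifnot(inherits(gdesign, "gel_design"))
  cv <- gdesign$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  ref_mean <- 1000
  # modification agents are read out as biotin/vimentin, everything else
  # (crosslinkers, oxidants) as oligomer/monomer
  modif_agents <- c("IacB", "15dPGJ2B")
  rlnorm_mean <- function(n, m) {
    # lognormal with expectation m and CV `cv`; degenerate at m when cv = 0
    if (m == 0) return(rep(0, n))
    if (cv == 0) return(rep(m, n))
    m * exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  withr::with_seed(gdesign$seed, {
    out <- purrr::map_dfr(seq_len(nrow(gdesign$design)), function(i) {
      d <- gdesign$design[i, ]
      is_mod <- d$agent %in% modif_agents
      num_band <- if (is_mod) "biotin" else "oligomer"
      den_band <- if (is_mod) "vimentin" else "monomer"
      target <- d$baseline_ratio * (1 - d$true_inhibition)
      purrr::map_dfr(seq_len(d$replicates), function(r) {
        ref <- rlnorm_mean(1, ref_mean)
        ratio <- rlnorm_mean(1, target)
        tibble(
          lane_id = sprintf("%s_%s%g_r%d", d$agent, d$pre_salt,
                            d$salt_conc_um, r),
          variant = d$variant, agent = d$agent,
          agent_conc_um = d$agent_conc_um, pre_salt = d$pre_salt,
          salt_conc_um = d$salt_conc_um, replicate = r,
          band = c(den_band, num_band),
          intensity_au = c(ref, ratio * ref)
        )
      })
    })
    attr(out, "design") <- gdesign
    out
  })
}
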