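# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (direct arithmetic, exhaustive
# bisection, brute-force double loops, plain Monte-Carlo) kept separate
# from the package code paths they check.

# direct evaluation of the titratable-rate law
oracle_rate_law <- function(ph, baseline, pka, rates) {
  out <- baseline
  for (i in seq_along(pka)) {
    out <- out + rates[i] / (1 + 10^(pka[i] - ph))
  }
  out
}

# exhaustive bisection on free zinc for the competitive mass balance
oracle_bisect_species <- function(zn_total, zincon_total, protein_sites,
                                  kd_zincon, kd_protein, tol = 1e-12) {
  if (zn_total == 0) {
    return(c(zn_free = 0, zn_zincon = 0, zn_protein = 0))
  }
  f <- function(z) {
    z + zincon_total * z / (kd_zincon + z) +
      protein_sites * z / (kd_protein + z) - zn_total
  }
  lo <- 0; hi <- zn_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, zn_total)) break
  }
  z <- (lo + hi) / 2
  c(zn_free = z,
    zn_zincon = zincon_total * z / (kd_zincon + z),
    zn_protein = protein_sites * z / (kd_protein + z))
}

# brute-force per-frame contact count for one ion
oracle_contact_fraction <- function(model, ion_index, cutoff) {
  prot <- which(model$atoms$record == "ATOM")
  hits <- 0
  for (f in seq_along(model$coords)) {
    mind <- Inf
    for (p in prot) {
      d <- sqrt(sum((model$coords[[f]][p, ] -
                       model$coords[[f]][ion_index, ])^2))
      mind <- min(mind, d)
    }
    if (mind <= cutoff) hits <- hits + 1
  }
  hits / length(model$coords)
}

# Monte-Carlo distribution of the percent-inhibition estimator under the
# gel generator's lognormal noise model (vectorised draws, no package code)
oracle_inhibition_mc <- function(true_inhibition, baseline_ratio, cv,
                                 replicates, n_draws = 1e4) {
  sdlog <- sqrt(log(1 + cv^2))
  draw_mean_ratio <- function(m) {
    r <- matrix(m * exp(rnorm(n_draws * replicates, -sdlog^2 / 2, sdlog)),
                nrow = n_draws)
    rowMeans(r)
  }
  mt <- draw_mean_ratio(baseline_ratio * (1 - true_inhibition))
  mc <- draw_mean_ratio(baseline_ratio)
  (1 - mt / mc) * 100
}

# random rigid-body motion: rotation matrix from QR + translation
random_rigid_motion <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_dec)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = rnorm(3, 0, 20))
}

apply_rigid <- function(model, motion) {
  model$coords <- lapply(model$coords, function(m) {
    sweep(m %*% motion$rot, 2, motion$shift, `+`)
  })
  model
}

make_trace <- function(times, values, ph_final = 7, well_id = "w1") {
  tibble::tibble(well_id = well_id, time_min = times,
                 fluorescence_au = values, ph_final = ph_final)
}
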