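#' Henderson-Hasselbalch rate model
#'
#' The titratable-rate model used throughout the pK_a analysis: a
#' pH-independent baseline plus one term per ionizable site, each
#' contributing `limiting_rate * thiolate fraction`, where the thiolate
#' fraction at a given pH is `1 / (1 + 10^(pKa - pH))`. For non-negative
#' rates the curve is monotone non-decreasing in pH, and when sites are
#' separated by more than ~2 pH units its inflexion points coincide with
#' the pK_a values.
#'
#' @param ph pH value(s); vectorised.
#' @param pka Site pK_a values. May also be a `pka_fit` object, in which
#'   case its parameters are used and the other arguments are ignored.
#' @param limiting_rates Per-site limiting rates (min^-1), same length as
#'   `pka`.
#' @param baseline Baseline rate (min^-1).
#' @return Predicted k_obs (min^-1).
#' @export
#' @examples
#' hh_rate_model(7, pka = 7, limiting_rates = 0.03, baseline = 0.002)
hh_rate_model <- function(ph, pka = numeric(0), limiting_rates = numeric(0),
                          baseline = 0) {
  if (inherits(pka, "pka_fit")) {
    fit <- pka
    pka <- fit$pka
    limiting_rates <- fit$limiting_rates
    baseline <- fit$baseline
  }
  if (length(pka) != length(limiting_rates)) {
    abort("`pka` and `limiting_rates` must have the same length.")
  }
  vapply(ph, function(p) {
    baseline + sum(limiting_rates / (1 + 10^(pka - p)))
  }, numeric(1))
}

# AICc for a Gaussian least-squares fit with k mean parameters (+1 for sigma)
aicc_from_rss <- function(rss, n, k_mean) {
  k <- k_mean + 1
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a titration curve with an n-site ionization model
#'
#' Weighted nonlinear least squares of [hh_rate_model()] against a
#' k_obs-versus-pH curve. Weights are moderated inverse-variance weights,
#' `1 / (SEM^2 + median(SEM)^2)`: with the usual three replicates per pH
#' the raw SEMs are too unstable to use directly (a lucky near-zero SEM
#' would dominate the fit), so each is tempered by the median SEM of the
#' curve. If any SEM is zero or missing the fit falls back to unweighted
#' least squares. pK_a values are
#' constrained to [2, 12] and rates to be non-negative; to avoid local
#' minima the optimiser is restarted over a pK_a grid (3 to 11 in steps of
#' 1; ordered pairs for two sites). Fitted sites are reported in ascending
#' pK_a order. A warning is attached when two fitted sites are separated
#' by less than 2 pH units, where inflexion points and pK_a values start
#' to diverge.
#'
#' `n_sites = 0` fits the constant-baseline model in closed form.
#'
#' @param curve A `titration_curve` (or any data frame with `ph_final`,
#'   `kobs_mean`, and optionally `sem`, `n` columns).
#' @param n_sites Number of ionizable sites: 0, 1 or 2.
#' @return An object of class `pka_fit`: `n_sites`, `pka`,
#'   `limiting_rates`, `baseline`, `covariance`, `r_squared`, `aicc`,
#'   `rss`, `n`, `weighted`, `separation_warning`. Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @export
#' @examples
#' ph <- seq(3, 11, 0.5)
#' curve <- tibble::tibble(ph_final = ph,
#'   kobs_mean = hh_rate_model(ph, c(5, 8), c(0.02, 0.04), 0.001),
#'   sem = 0.0005, n = 3)
#' fit_pka(curve, n_sites = 2)
fit_pka <- function(curve, n_sites) {
  check_columns(curve, c("ph_final", "kobs_mean"), "curve")
  if (!n_sites %in% 0:2) abort("`n_sites` must be 0, 1 or 2.")
  dat <- tibble(ph = curve$ph_final, y = curve$kobs_mean,
                sem = if ("sem" %in% names(curve)) curve$sem else NA_real_)
  dat <- dat[is.finite(dat$ph) & is.finite(dat$y), ]
  ndat <- nrow(dat)
  if (n_sites > 0) {
    span <- diff(range(dat$ph))
    if (ndat < 2 * n_sites + 2) {
      abort(sprintf("%d pH points are too few for a %d-site fit.",
                    ndat, n_sites))
    }
    if (n_sites == 2 && (ndat < 6 || span < 3)) {
      abort("a 2-site fit needs >= 6 distinct pH points spanning >= 3 pH units.")
    }
  }
  weighted <- all(is.finite(dat$sem)) && all(dat$sem > 0)
  w <- if (weighted) 1 / (dat$sem^2 + median(dat$sem)^2) else rep(1, ndat)

  finish <- function(pka, rates, baseline, rss, covariance, k_mean) {
    mu <- weighted.mean(dat$y, w)
    tss <- sum(w * (dat$y - mu)^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    sep_warn <- n_sites == 2 && is.finite(diff(pka)) && abs(diff(pka)) < 2
    if (sep_warn) {
      warn("fitted pK_a values are separated by < 2 pH units; inflexion points may not equal the pK_a values.")
    }
    structure(list(
      n_sites = n_sites, pka = pka, limiting_rates = rates,
      baseline = baseline, covariance = covariance,
      r_squared = r2, aicc = aicc_from_rss(rss, ndat, k_mean),
      rss = rss, n = ndat, weighted = weighted,
      separation_warning = sep_warn, data = dat
    ), class = "pka_fit")
  }

  if (n_sites == 0) {
    baseline <- weighted.mean(dat$y, w)
    rss <- sum(w * (dat$y - baseline)^2)
    covariance <- matrix(1 / sum(w), 1, 1,
                         dimnames = list("baseline", "baseline"))
    return(finish(numeric(0), numeric(0), baseline, rss, covariance,
                  k_mean = 1))
  }

  rate0 <- max(diff(range(dat$y)), 1e-6) / n_sites
  base0 <- max(min(dat$y), 0)
  grid <- if (n_sites == 1) {
    lapply(3:11, function(p) c(p))
  } else {
    pairs <- expand.grid(p1 = 3:11, p2 = 3:11)
    pairs <- pairs[pairs$p1 < pairs$p2, ]
    lapply(seq_len(nrow(pairs)), function(i) as.numeric(pairs[i, ]))
  }
  model_fn <- function(par) {
    mu <- par[1]
    for (j in seq_len(n_sites)) {
      mu <- mu + par[2 * j] / (1 + 10^(par[2 * j + 1] - dat$ph))
    }
    mu
  }
  resid_fn <- function(par) sqrt(w) * (dat$y - model_fn(par))
  lower <- c(0, rep(c(0, 2), n_sites))
  upper <- c(Inf, rep(c(Inf, 12), n_sites))
  best <- NULL
  tried <- 0L
  for (g in grid) {
    par0 <- c(base0, as.vector(rbind(rep(rate0, n_sites), g)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    tried <- tried + 1L
    if (!is.null(fit)) {
      rss <- fit$deviance # sum of squared weighted residuals
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(sprintf("no %d-site fit converged after %d multistart attempts.",
                  n_sites, tried))
  }
  par_names <- c("b", as.vector(rbind(paste0("r", seq_len(n_sites)),
                                      paste0("p", seq_len(n_sites)))))
  cf <- setNames(best$fit$par, par_names)
  if (n_sites == 1) {
    pka <- unname(cf[["p1"]]); rates <- unname(cf[["r1"]])
  } else {
    ord <- order(c(cf[["p1"]], cf[["p2"]]))
    pka <- unname(c(cf[["p1"]], cf[["p2"]])[ord])
    rates <- unname(c(cf[["r1"]], cf[["r2"]])[ord])
  }
  covariance <- tryCatch({
    sigma2 <- best$rss / max(1, ndat - length(cf))
    v <- sigma2 * solve(best$fit$hessian)
    dimnames(v) <- list(names(cf), names(cf))
    v
  }, error = function(e) {
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf)))
  })
  finish(pka, rates, unname(cf[["b"]]), best$rss, covariance,
         k_mean = 1 + 2 * n_sites)
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("%d-site titration fit (n = %d, %s)\n", x$n_sites, x$n,
              if (x$weighted) "moderated 1/SEM^2 weights" else "unweighted"))
  if (x$n_sites > 0) {
    for (i in seq_along(x$pka)) {
      cat(sprintf("  site %d: pK_a %.3f, limiting rate %.4g min^-1\n",
                  i, x$pka[i], x$limiting_rates[i]))
    }
  }
  cat(sprintf("  baseline %.4g min^-1, R^2 %.4f, AICc %.2f\n",
              x$baseline, x$r_squared, x$aicc))
  invisible(x)
}

#' @export
predict.pka_fit <- function(object, ph = NULL, ...) {
  ph <- ph %||% object$data$ph
  hh_rate_model(ph, object)
}

#' Select the number of ionization sites by AICc
#'
#' Fits the 0-, 1- and 2-site models with [fit_pka()] and returns the
#' AICc-minimising fit; models within 2 AICc units of the minimum are
#' treated as ties and broken towards fewer sites. All three AICc values
#' are recorded in the `"aicc_all"` attribute of the returned fit.
#'
#' @param curve A titration curve (see [fit_pka()]).
#' @return The selected `pka_fit`.
#' @export
#' @examples
#' plate <- make_kinetics_plate(kinetics_preset("wt", seed = 1))
#' curve <- build_titration_curve(plate)
#' select_model(curve)$n_sites # 2
select_model <- function(curve) {
  fits <- lapply(0:2, function(k) suppressWarnings(fit_pka(curve, k)))
  aicc <- vapply(fits, function(f) f$aicc, numeric(1))
  candidates <- which(aicc - min(aicc) < 2)
  chosen <- min(candidates) # fewest sites among near-ties
  out <- fits[[chosen]]
  attr(out, "aicc_all") <- setNames(aicc, paste0("sites_", 0:2))
  out
}

#' Pool pK_a estimates across independent experiments
#'
#' Averages per-experiment fits the way replicate titrations are reported:
#' each experiment is fitted on its own, then per-site means and SDs are
#' taken across experiments, sites matched by ascending pK_a order.
#'
#' @param fits A list of `pka_fit` objects sharing the same `n_sites`
#'   (>= 2 fits).
#' @return A tibble of class `pooled_pka`: columns `site`, `pka_mean`,
#'   `pka_sd`, `n_experiments`.
#' @export
#' @examples
#' curves <- lapply(1:3, function(s) {
#'   build_titration_curve(make_kinetics_plate(kinetics_preset("wt", seed = s)))
#' })
#' pool_experiments(lapply(curves, fit_pka, n_sites = 2))
pool_experiments <- function(fits) {
  if (length(fits) < 2) abort("need at least 2 experiments to pool.")
  ns <- vapply(fits, function(f) as.integer(f$n_sites), integer(1))
  if (length(unique(ns)) != 1) {
    abort("all pooled fits must share the same number of sites.")
  }
  if (ns[1] == 0) abort("cannot pool site estimates from 0-site fits.")
  pk <- do.call(rbind, lapply(fits, function(f) sort(f$pka)))
  out <- tibble(
    site = seq_len(ns[1]),
    pka_mean = colMeans(pk),
    pka_sd = apply(pk, 2, sd),
    n_experiments = length(fits)
  )
  structure(out, class = c("pooled_pka", class(out)))
}
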