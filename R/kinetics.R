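#' Fit a sigmoid to one well's fluorescence time course
#'
#' Least-squares fit of a logistic growth curve anchored at the first
#' sampling time,
#' `F(t) = top / (1 + ((top - bottom)/bottom) * exp(-rate * t))`,
#' to a single well. The bottom plateau estimates the fluorescence of the
#' initial, non-alkylated protein (`F_o`), which the downstream
#' `ln(Ft/Fo)` linearisation requires; the half-rise time is reported as
#' the derived `midpoint`. Fitting uses Levenberg-Marquardt with a small
#' multistart over initial rates and positivity bounds.
#'
#' Degenerate (flat) traces return `bottom = top = mean(F)` rather than an
#' error. If no start converges, the fit falls back to
#' `bottom = first quartile`, `top = max`, flags `converged = FALSE` and
#' warns.
#'
#' @param trace A data frame for one well with columns `time_min` and
#'   `fluorescence_au` (at least 5 points, strictly increasing times).
#' @return An object of class `sigmoid_fit`: fields `bottom`, `top`,
#'   `rate` (min^-1), `midpoint` (min), `r_squared`, `residual_sd`,
#'   `converged`, `n`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' tr <- tibble::tibble(time_min = seq(0, 90, 3),
#'                      fluorescence_au = 500 / (1 + 9 * exp(-0.05 * seq(0, 90, 3))))
#' fit_time_sigmoid(tr)
fit_time_sigmoid <- function(trace) {
  check_columns(trace, c("time_min", "fluorescence_au"), "trace")
  t <- trace$time_min
  y <- trace$fluorescence_au
  well <- if ("well_id" %in% names(trace)) trace$well_id[1] else "<trace>"
  if (length(t) < 5L) {
    abort(sprintf("well %s: need at least 5 time points, got %d.",
                  well, length(t)))
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort(sprintf("well %s: times must be strictly increasing.", well))
  }
  if (!all(is.finite(y))) {
    abort(sprintf("well %s: fluorescence must be finite.", well))
  }
  new_fit <- function(bottom, top, rate, r_squared, residual_sd, converged) {
    midpoint <- if (converged && rate > 0 && top > 2 * bottom) {
      log((top - bottom) / bottom) / rate
    } else NA_real_
    structure(list(bottom = bottom, top = top, rate = rate,
                   midpoint = midpoint, r_squared = r_squared,
                   residual_sd = residual_sd, converged = converged,
                   n = length(y), well_id = well),
              class = "sigmoid_fit")
  }
  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    return(new_fit(mean(y), mean(y), 0, NA_real_, 0, TRUE))
  }
  dat <- data.frame(t = t, y = y)
  b0 <- max(min(y), 1e-6)
  top0 <- max(y)
  # crude rate guesses spanning slow to fast rises on a 90-min scale
  rate_starts <- c(0.005, 0.02, 0.05, 0.15)
  best <- NULL
  for (r0 in rate_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ top / (1 + ((top - bottom) / bottom) * exp(-rate * t)),
        data = dat,
        start = list(bottom = b0, top = top0 * 1.05, rate = r0),
        lower = c(1e-9, 1e-9, 0),
        upper = c(Inf, 50 * max(y), 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    warn(sprintf(
      "well %s: sigmoid fit did not converge; using quartile fallback for the bottom plateau.",
      well))
    return(new_fit(unname(quantile(y, 0.25)), max(y), NA_real_,
                   NA_real_, NA_real_, FALSE))
  }
  cf <- coef(best$fit)
  bottom <- unname(cf[["bottom"]]); top <- unname(cf[["top"]])
  if (bottom > top) { tmp <- bottom; bottom <- top; top <- tmp }
  tss <- sum((y - mean(y))^2)
  residual_sd <- sqrt(best$rss / max(1, length(y) - 3))
  if (top - bottom < 2 * residual_sd) {
    # the fitted rise is indistinguishable from noise: treat as flat
    # rather than letting a noise-fitted sigmoid distort the plateaus
    return(new_fit(mean(y), mean(y), 0, NA_real_, sd(y), TRUE))
  }
  new_fit(bottom, top, unname(cf[["rate"]]),
          r_squared = 1 - best$rss / tss,
          residual_sd = residual_sd,
          converged = TRUE)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit (%s): bottom %.4g, top %.4g, rate %.4g min^-1, midpoint %.4g min, R^2 %.4g\n",
    x$well_id, x$bottom, x$top, x$rate, x$midpoint, x$r_squared))
  invisible(x)
}

#' Estimate the observed alkylation rate from one trace
#'
#' Implements the `ln(Ft/Fo)` linearisation: the observed pseudo-first-order
#' rate `k_obs` is the ordinary least-squares slope of `ln(Ft / f0)`
#' against time over the early-phase window. The window keeps the leading
#' run of points with `Ft <= f0 + window_frac * (top - f0)` (log-linearity
#' only holds before the curve bends towards its plateau); if fewer than 4
#' points qualify, the first 6 points are used instead.
#'
#' Points with `Ft <= 0` are dropped with a warning (an error if fewer
#' than 4 usable points remain). A negative fitted slope is clipped to 0
#' with a warning: near-zero rates can go slightly negative under noise,
#' and a negative pseudo-first-order rate is not physical.
#'
#' @param trace A data frame for one well with columns `time_min`,
#'   `fluorescence_au` (optionally `ph_final`, carried through).
#' @param f0 Bottom-plateau fluorescence (AU), e.g. from
#'   [fit_time_sigmoid()]; must be positive.
#' @param top Top plateau used to set the window; defaults to the maximum
#'   observed fluorescence.
#' @param window_frac Fraction of the `f0`-to-`top` rise admitted to the
#'   early-phase window (default 0.3).
#' @param fitted Optional noise-free fitted fluorescence values (same
#'   length as the trace), e.g. from [fit_time_sigmoid()]. When given,
#'   the window threshold is applied to the fitted curve instead of the
#'   noisy observations, so measurement noise cannot collapse the window;
#'   for a flat fit the whole trace is the early phase. The slope is
#'   always computed from the observed fluorescence.
#' @return A one-row tibble: `kobs` (min^-1), `stderr`, `window_start`,
#'   `window_end` (indices), `n_window`, `r_squared`, `ph_final`.
#' @export
#' @examples
#' tt <- seq(0, 90, 3)
#' tr <- tibble::tibble(time_min = tt, fluorescence_au = 50 * exp(0.01 * tt))
#' estimate_kobs(tr, f0 = 50) # slope exactly 0.01
estimate_kobs <- function(trace, f0, top = NULL, window_frac = 0.3,
                          fitted = NULL) {
  check_columns(trace, c("time_min", "fluorescence_au"), "trace")
  check_scalar(f0, "f0")
  t <- trace$time_min
  y <- trace$fluorescence_au
  well <- if ("well_id" %in% names(trace)) trace$well_id[1] else "<trace>"
  top <- top %||% max(y)
  threshold <- f0 + window_frac * (top - f0)
  wref <- fitted %||% y
  if (length(wref) != length(y)) {
    abort("`fitted` must match the trace length.")
  }
  below <- wref <= threshold + 1e-9 * max(1, abs(threshold))
  first_out <- which(!below)[1]
  win <- if (is.na(first_out)) seq_along(y) else seq_len(first_out - 1L)
  if (length(win) < 4L) win <- seq_len(min(6L, length(y)))
  if (length(win) < 4L) {
    abort(sprintf("well %s: early-phase window has fewer than 4 points.", well))
  }
  keep <- y[win] > 0
  if (any(!keep)) {
    warn(sprintf("well %s: dropped %d non-positive fluorescence point(s).",
                 well, sum(!keep)))
    if (sum(keep) < 4L) {
      abort(sprintf(
        "well %s: fewer than 4 positive points in the early-phase window.",
        well))
    }
  }
  tw <- t[win][keep]
  lw <- log(y[win][keep] / f0)
  ols <- lm(lw ~ tw)
  slope <- unname(coef(ols)[2])
  # summary.lm warns on numerically perfect fits; those are fine here
  smry <- suppressWarnings(summary(ols))
  se <- unname(smry$coefficients[2, "Std. Error"])
  r2 <- smry$r.squared
  if (!is.finite(r2)) r2 <- NA_real_
  if (slope < 0) {
    warn(sprintf("well %s: negative fitted slope (%.3g) clipped to 0.",
                 well, slope))
    slope <- 0
  }
  tibble(
    kobs = slope, stderr = se,
    window_start = win[1], window_end = win[length(win)],
    n_window = sum(keep), r_squared = r2,
    ph_final = if ("ph_final" %in% names(trace)) trace$ph_final[1] else NA_real_
  )
}

#' Build a k_obs-versus-pH titration curve from a kinetics plate
#'
#' Runs the per-well pipeline over a whole plate: every well gets a
#' sigmoid fit for its bottom plateau ([fit_time_sigmoid()]) and an
#' early-phase `ln(Ft/Fo)` slope ([estimate_kobs()]). Sample-well rates
#' are then background-corrected by subtracting the mean slope of the
#' background wells sharing the same nominal pH (slopes, not raw
#' fluorescence, are subtracted: background wells lack the protein signal
#' scale). Replicates are summarised per measured pH.
#'
#' The curve is keyed by the measured `ph_final`, not the nominal buffer
#' pH. Output is invariant to the ordering of input rows and to
#' duplication of a background well. pH groups with no usable replicate
#' are dropped with a warning; per-well clipping/drop warnings are
#' aggregated into a single message.
#'
#' @param plate A long-format kinetics table as produced by
#'   [make_kinetics_plate()] or [read_kinetics_csv()].
#' @param window_frac Early-phase window fraction passed to
#'   [estimate_kobs()].
#' @return A tibble of class `titration_curve` with columns `ph_final`,
#'   `kobs_mean` (min^-1), `sem`, `n`, sorted by pH. Per-well estimates
#'   are attached as the `"wells"` attribute; the correction method is
#'   recorded in the `"background_correction"` attribute.
#' @export
#' @examples
#' plate <- make_kinetics_plate(kinetics_preset("wt", seed = 1))
#' build_titration_curve(plate)
build_titration_curve <- function(plate, window_frac = 0.3) {
  check_columns(plate, c("well_id", "role", "ph_nominal", "ph_final",
                         "time_min", "fluorescence_au"), "plate")
  msgs <- character(0)
  plate <- distinct(plate) # a duplicated well contributes once
  per_well <- plate %>%
    group_by(.data$well_id, .data$role, .data$ph_nominal, .data$ph_final) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_min)
      res <- withCallingHandlers({
        sf <- fit_time_sigmoid(dplyr::mutate(df, well_id = key$well_id))
        f0 <- max(sf$bottom, 1e-9)
        fitted <- if (sf$converged && is.finite(sf$rate) &&
                        sf$top > sf$bottom) {
          kinetic_curve(df$time_min, f0, sf$top, sf$rate)
        } else {
          rep(f0, nrow(df))
        }
        select(
          estimate_kobs(dplyr::mutate(df, well_id = key$well_id),
                        f0 = f0, top = sf$top, window_frac = window_frac,
                        fitted = fitted),
          -"ph_final")
      }, warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      res
    }) %>%
    ungroup()
  if (length(msgs) > 0) {
    warn(sprintf("%d well-level notice(s) during rate estimation; first: %s",
                 length(msgs), msgs[1]))
  }
  bg <- per_well %>%
    filter(.data$role == "background") %>%
    distinct(.data$well_id, .keep_all = TRUE) %>%
    group_by(.data$ph_nominal) %>%
    summarise(bg_kobs = mean(.data$kobs), .groups = "drop")
  samples <- per_well %>%
    filter(.data$role == "sample") %>%
    left_join(bg, by = "ph_nominal") %>%
    mutate(kobs_corrected = .data$kobs -
             ifelse(is.na(.data$bg_kobs), 0, .data$bg_kobs))
  dropped <- setdiff(unique(plate$ph_nominal[plate$role == "sample"]),
                     unique(samples$ph_nominal))
  if (length(dropped) > 0) {
    warn(sprintf("pH value(s) with no usable replicate excluded: %s",
                 paste(dropped, collapse = ", ")))
  }
  curve <- samples %>%
    group_by(.data$ph_final) %>%
    summarise(
      kobs_mean = mean(.data$kobs_corrected),
      sem = if (dplyr::n() > 1) sd(.data$kobs_corrected) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$ph_final)
  structure(curve, class = c("titration_curve", class(curve)),
            wells = samples, background_correction = "slope subtraction")
}

#' Protein concentration from 280 nm absorbance
#'
#' Beer-Lambert conversion, `conc = A280 / (epsilon * path) * 1e6` uM,
#' with the vimentin molar absorptivity (22450 M^-1 cm^-1) as the default.
#'
#' @param a280 Absorbance at 280 nm (AU); vectorised, non-negative.
#' @param path_cm Optical path length (cm).
#' @param epsilon Molar absorptivity (M^-1 cm^-1).
#' @return Concentration(s) in uM.
#' @export
#' @examples
#' absorbance_to_concentration(0.2245) # 10 uM
absorbance_to_concentration <- function(a280, path_cm = 1,
                                        epsilon = assay_constants()$vimentin_extinction) {
  if (any(!is.finite(a280)) || any(a280 < 0)) {
    abort("`a280` must be finite and non-negative.")
  }
  check_scalar(path_cm, "path_cm")
  check_scalar(epsilon, "epsilon")
  a280 / (epsilon * path_cm) * 1e6
}
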