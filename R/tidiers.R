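#' Tidy and glance methods
#'
#' broom-style summaries for the package's fitted objects: `tidy()`
#' returns one row per parameter with standard errors where available,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (`pka_fit`, `binding_fit`, `sigmoid_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name zincys_tidiers
NULL

#' @rdname zincys_tidiers
#' @method tidy pka_fit
#' @export
tidy.pka_fit <- function(x, ...) {
  terms <- c("baseline",
             if (x$n_sites > 0) paste0("pka_", seq_len(x$n_sites)),
             if (x$n_sites > 0) paste0("limiting_rate_", seq_len(x$n_sites)))
  est <- c(x$baseline, x$pka, x$limiting_rates)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$covariance) && !anyNA(x$covariance)) {
    # covariance rows follow the fitting order b, r1, p1, (r2, p2)
    d <- sqrt(diag(x$covariance))
    nm <- names(d)
    se[1] <- d[match("b", nm)]
    if (x$n_sites >= 1) {
      se[2] <- d[match("p1", nm)]
      se[2 + x$n_sites] <- d[match("r1", nm)]
    }
    if (x$n_sites == 2) {
      se[3] <- d[match("p2", nm)]
      se[3 + x$n_sites] <- d[match("r2", nm)]
    }
  }
  tibble(term = terms, estimate = est, std_error = se)
}

#' @rdname zincys_tidiers
#' @method glance pka_fit
#' @export
glance.pka_fit <- function(x, ...) {
  tibble(n_sites = x$n_sites, r_squared = x$r_squared, aicc = x$aicc,
         rss = x$rss, n = x$n, weighted = x$weighted)
}

#' @rdname zincys_tidiers
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("kd_protein_uM", "log10_kd_protein", "n_sites", "abs_scale",
             "abs_baseline"),
    estimate = c(x$model$kd_protein_uM, x$log10_kd_protein,
                 x$model$n_sites, x$model$abs_scale, x$model$abs_baseline),
    std_error = c(NA_real_, x$se_log10_kd, NA_real_, NA_real_, NA_real_)
  )
}

#' @rdname zincys_tidiers
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd_protein_uM = x$model$kd_protein_uM, n_sites = x$model$n_sites,
         non_competing = x$non_competing, rss = x$rss, n = x$n)
}

#' @rdname zincys_tidiers
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "rate", "midpoint"),
         estimate = c(x$bottom, x$top, x$rate, x$midpoint))
}

#' @rdname zincys_tidiers
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_sd = x$residual_sd,
         converged = x$converged, n = x$n)
}
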