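#' Band-intensity ratios per lane
#'
#' The quantitative readouts of the gel and blot assays are per-lane band
#' ratios: `biotin / vimentin` for cysteine modification (streptavidin
#' signal over total protein) and `oligomer / monomer` for crosslinking.
#' Ratios are computed per lane and only then averaged across replicates,
#' matching the per-lane quantification convention of densitometry
#' figures.
#'
#' `modification_ratio()` and `oligomer_ratio()` return the scalar ratio
#' for a single lane; `lane_ratios()` computes the appropriate ratio for
#' every lane of a long-format table.
#'
#' @param lane A long-format data frame for a single lane with columns
#'   `band` and `intensity_au` containing the required band pair.
#' @return A single ratio (dimensionless).
#' @export
#' @examples
#' lane <- tibble::tibble(band = c("biotin", "vimentin"),
#'                        intensity_au = c(200, 100))
#' modification_ratio(lane) # 2
modification_ratio <- function(lane) {
  band_ratio(lane, num = "biotin", den = "vimentin")
}

#' @rdname modification_ratio
#' @export
oligomer_ratio <- function(lane) {
  band_ratio(lane, num = "oligomer", den = "monomer")
}

band_ratio <- function(lane, num, den) {
  check_columns(lane, c("band", "intensity_au"), "lane")
  id <- if ("lane_id" %in% names(lane)) lane$lane_id[1] else "<lane>"
  top <- lane$intensity_au[lane$band == num]
  bot <- lane$intensity_au[lane$band == den]
  if (length(top) != 1 || length(bot) != 1) {
    abort(sprintf("lane %s: needs exactly one `%s` and one `%s` band.",
                  id, num, den))
  }
  if (any(c(top, bot) < 0)) {
    abort(sprintf("lane %s: band intensities must be non-negative.", id))
  }
  if (bot == 0) {
    abort(sprintf("lane %s: reference band `%s` intensity is 0.", id, den))
  }
  top / bot
}

#' @param lanes A long-format lane table (e.g. from [make_gel_table()] or
#'   [read_gel_csv()]).
#' @param ratio_kind `"modification"` (biotin/vimentin), `"oligomer"`
#'   (oligomer/monomer), or `"auto"` to choose per agent (biotinylated
#'   modification probes vs crosslinkers/oxidants).
#' @rdname modification_ratio
#' @export
lane_ratios <- function(lanes, ratio_kind = c("auto", "modification",
                                              "oligomer")) {
  ratio_kind <- match.arg(ratio_kind)
  check_columns(lanes, c("lane_id", "band", "intensity_au"), "lanes")
  modif_agents <- c("IacB", "15dPGJ2B")
  meta_cols <- intersect(c("lane_id", "variant", "agent", "agent_conc_um",
                           "pre_salt", "salt_conc_um", "replicate"),
                         names(lanes))
  lanes %>%
    group_by(across(dplyr::all_of(meta_cols))) %>%
    dplyr::group_modify(function(df, key) {
      kind <- ratio_kind
      if (kind == "auto") {
        kind <- if (!is.null(key$agent) && key$agent %in% modif_agents) {
          "modification"
        } else "oligomer"
      }
      r <- if (kind == "modification") {
        modification_ratio(dplyr::mutate(df, lane_id = key$lane_id))
      } else {
        oligomer_ratio(dplyr::mutate(df, lane_id = key$lane_id))
      }
      tibble(ratio_kind = kind, ratio = r)
    }) %>%
    ungroup()
}

#' Percent inhibition of modification or crosslinking
#'
#' Quantifies cation protection: per-lane ratios are averaged within the
#' treated (salt pre-incubated) and control groups, and
#' `percent_inhibition = (1 - ratio_treated / ratio_control) * 100`.
#' Negative values mean enhancement and are deliberately not clipped
#' (magnesium enhances DBB crosslinking, for instance). Group means are
#' compared with a two-sided Student's t-test (paired or unpaired;
#' unpaired Welch by default), reported without multiple-testing
#' correction.
#'
#' @param treated,control Long-format lane tables for the two groups (same
#'   agent and readout).
#' @param ratio_kind Passed to [lane_ratios()].
#' @param paired Use a paired t-test (replicates matched by order).
#' @return A one-row tibble of class `protection_result`: `agent`, `salt`,
#'   `salt_conc_um`, `ratio_kind`, `ratio_control`, `ratio_treated`,
#'   `percent_inhibition`, `p_value`, `test`, `n_treated`, `n_control`.
#' @export
#' @examples
#' lanes <- make_gel_table(gel_design("figure6A", seed = 1))
#' dbb <- dplyr::filter(lanes, agent == "DBB")
#' percent_inhibition(dplyr::filter(dbb, pre_salt == "ZnCl2"),
#'                    dplyr::filter(dbb, pre_salt == "none"))
percent_inhibition <- function(treated, control,
                               ratio_kind = c("auto", "modification",
                                              "oligomer"),
                               paired = FALSE) {
  ratio_kind <- match.arg(ratio_kind)
  if (nrow(treated) == 0 || nrow(control) == 0) {
    abort("both the treated and control groups must be non-empty.")
  }
  rt <- lane_ratios(treated, ratio_kind)
  rc <- lane_ratios(control, ratio_kind)
  agents <- unique(c(rt$agent, rc$agent))
  if (length(agents) > 1) {
    abort(sprintf("treated and control groups mix agents: %s.",
                  paste(agents, collapse = ", ")))
  }
  if (length(unique(c(rt$ratio_kind, rc$ratio_kind))) > 1) {
    abort("treated and control groups use different ratio kinds.")
  }
  mc <- mean(rc$ratio)
  mt <- mean(rt$ratio)
  if (mc == 0) abort("control mean ratio is 0; percent inhibition undefined.")
  pi_pct <- (1 - mt / mc) * 100
  ht <- compare_conditions(rt$ratio, rc$ratio, paired = paired)
  out <- tibble(
    agent = agents,
    salt = if ("pre_salt" %in% names(rt)) rt$pre_salt[1] else NA_character_,
    salt_conc_um = if ("salt_conc_um" %in% names(rt)) rt$salt_conc_um[1]
                   else NA_real_,
    ratio_kind = rt$ratio_kind[1],
    ratio_control = mc, ratio_treated = mt,
    percent_inhibition = pi_pct,
    p_value = ht$p_value, test = ht$test,
    n_treated = nrow(rt), n_control = nrow(rc)
  )
  structure(out, class = c("protection_result", class(out)))
}

#' Protection results for every salt condition of a lane table
#'
#' Convenience wrapper running [percent_inhibition()] for each
#' (agent, salt, concentration) condition of a table against that agent's
#' no-salt control lanes.
#'
#' @param lanes A long-format lane table containing, for every agent, a
#'   `pre_salt == "none"` control condition.
#' @inheritParams percent_inhibition
#' @return A `protection_result` tibble with one row per treated
#'   condition.
#' @export
#' @examples
#' quantify_protection(make_gel_table(gel_design("figure6A", seed = 1)))
quantify_protection <- function(lanes,
                                ratio_kind = c("auto", "modification",
                                               "oligomer"),
                                paired = FALSE) {
  ratio_kind <- match.arg(ratio_kind)
  check_columns(lanes, c("agent", "pre_salt", "salt_conc_um"), "lanes")
  conds <- lanes %>%
    filter(.data$pre_salt != "none") %>%
    distinct(.data$agent, .data$pre_salt, .data$salt_conc_um)
  out <- purrr::pmap_dfr(conds, function(agent, pre_salt, salt_conc_um) {
    treated <- lanes[lanes$agent == agent & lanes$pre_salt == pre_salt &
                       lanes$salt_conc_um == salt_conc_um, ]
    control <- lanes[lanes$agent == agent & lanes$pre_salt == "none", ]
    percent_inhibition(treated, control, ratio_kind, paired = paired)
  })
  structure(out, class = unique(c("protection_result", class(out))))
}

#' Protection versus crosslinker spacer-arm length
#'
#' Relates percent inhibition to crosslinker geometry: pairs each
#' protection result with the reagent's spacer-arm length from the
#' registry and computes the Spearman rank correlation. A negative
#' correlation (`trend = "inverse"`) is the signature of short-range
#' cation protection: the shorter the spacer, the stronger the
#' inhibition. When all inhibitions are tied the correlation is undefined
#' and the trend is reported as `"flat"` without error.
#'
#' @param results A `protection_result` tibble covering >= 3 distinct
#'   crosslinkers (one row each; duplicate crosslinkers are an error).
#' @param registry A crosslinker registry (see [crosslinker_registry()]).
#' @return A list of class `spacer_trend`: `pairs` (tibble of
#'   `agent`, `spacer_arm_a`, `percent_inhibition`), `rho`, `trend`
#'   (`"inverse"`, `"direct"` or `"flat"`).
#' @export
#' @examples
#' res <- tibble::tibble(agent = c("DBB", "TMEA", "BMH"),
#'                       percent_inhibition = c(76, 56, 0))
#' protection_vs_spacer(res)$rho # -1
protection_vs_spacer <- function(results, registry = crosslinker_registry()) {
  check_columns(results, c("agent", "percent_inhibition"), "results")
  if (anyDuplicated(results$agent)) {
    abort("duplicate crosslinker entries in `results`.")
  }
  pairs <- results %>%
    left_join(registry, by = c(agent = "name")) %>%
    filter(is.finite(.data$spacer_arm_a)) %>%
    select("agent", "spacer_arm_a", "percent_inhibition") %>%
    arrange(.data$spacer_arm_a)
  if (nrow(pairs) < 3) {
    abort("need results for at least 3 crosslinkers with spacer arms.")
  }
  rho <- suppressWarnings(
    cor(pairs$spacer_arm_a, pairs$percent_inhibition, method = "spearman"))
  trend <- if (!is.finite(rho)) "flat" else if (rho < 0) "inverse" else "direct"
  structure(list(pairs = pairs,
                 rho = if (is.finite(rho)) rho else NA_real_,
                 trend = trend),
            class = "spacer_trend")
}

#' @export
print.spacer_trend <- function(x, ...) {
  cat(sprintf("Protection vs spacer arm: Spearman rho = %s, trend %s\n",
              format(x$rho, digits = 3), x$trend))
  print(x$pairs)
  invisible(x)
}

#' Two-group comparison of densitometry readouts
#'
#' Two-sided Student's t-test between two groups of per-lane ratios (or
#' any numeric summaries), following the convention that differences are
#' called significant at p < 0.05. Paired and unpaired (Welch) variants
#' are supported; the variant used is recorded in the result.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each; equal lengths
#'   and >= 2 pairs if paired).
#' @param paired Use a paired test.
#' @return A one-row tibble: `estimate` (mean difference a - b),
#'   `statistic`, `p_value`, `df`, `test`, `n_a`, `n_b`.
#' @export
#' @examples
#' compare_conditions(c(1, 2, 3), c(2, 3, 4))
compare_conditions <- function(group_a, group_b, paired = FALSE) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("need at least 2 observations per group.")
  }
  if (paired && length(group_a) != length(group_b)) {
    abort("paired comparison needs equal group sizes.")
  }
  degenerate <- if (paired) {
    sd(group_a - group_b) == 0 && mean(group_a - group_b) == 0
  } else {
    sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)
  }
  if (degenerate) {
    # identical groups leave no variance for a t statistic
    return(tibble(estimate = 0, statistic = 0, p_value = 1, df = NA_real_,
                  test = if (paired) "paired t" else "Welch t",
                  n_a = length(group_a), n_b = length(group_b)))
  }
  novar <- if (paired) sd(group_a - group_b) == 0 else
    sd(group_a) == 0 && sd(group_b) == 0
  if (novar) {
    # constant groups with different means: difference is exact
    d <- mean(group_a) - mean(group_b)
    return(tibble(estimate = d, statistic = sign(d) * Inf, p_value = 0,
                  df = NA_real_,
                  test = if (paired) "paired t" else "Welch t",
                  n_a = length(group_a), n_b = length(group_b)))
  }
  ht <- t.test(group_a, group_b, paired = paired)
  tibble(
    estimate = if (paired) unname(ht$estimate)
               else unname(ht$estimate[1] - ht$estimate[2]),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    test = if (paired) "paired t" else "Welch t",
    n_a = length(group_a), n_b = length(group_b)
  )
}
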