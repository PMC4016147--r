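#' Roost-switching and roost-use summary statistics
#'
#' Computes the tracking-effort summaries reported for telemetry studies
#' of fission-fusion colonies: the mean interval between roost switches
#' (mean length of runs of consecutive days in the same roost; runs are
#' split at tracking gaps of more than one day), roosts used per bat,
#' relocations per bat, bats per roost and uses (bat-days) per roost.
#' Because the switch interval can be averaged per bat first or pooled
#' over all runs, both aggregations are reported.
#'
#' @param relocations Data frame with `bat_id`, `date`, `roost_id`.
#' @return A `colony_summary` list: `$summary` (one-row tibble of means
#'   and SDs), `$per_bat`, `$per_roost` and `$runs` tibbles.
#' @export
roost_switching_stats <- function(relocations) {
  if (is.null(relocations) || nrow(relocations) == 0) {
    abort("empty relocation table")
  }
  runs <- relocations |>
    dplyr::arrange(.data$bat_id, .data$date) |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::mutate(
      gap = c(0, diff(as.numeric(.data$date))) > 1,
      switched = .data$roost_id != dplyr::lag(.data$roost_id, default = dplyr::first(.data$roost_id)),
      run_id = cumsum(.data$gap | .data$switched | dplyr::row_number() == 1)
    ) |>
    dplyr::group_by(.data$bat_id, .data$run_id) |>
    dplyr::summarise(roost_id = dplyr::first(.data$roost_id),
                     run_days = dplyr::n(), .groups = "drop")

  per_bat <- relocations |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::summarise(n_relocs = dplyr::n(),
                     n_roosts = dplyr::n_distinct(.data$roost_id),
                     .groups = "drop") |>
    dplyr::left_join(
      runs |> dplyr::group_by(.data$bat_id) |>
        dplyr::summarise(mean_run_days = mean(.data$run_days), .groups = "drop"),
      by = "bat_id"
    )

  per_roost <- relocations |>
    dplyr::group_by(.data$roost_id) |>
    dplyr::summarise(n_bats = dplyr::n_distinct(.data$bat_id),
                     n_uses = dplyr::n(), .groups = "drop")

  summary <- tibble::tibble(
    mean_switch_interval_days = mean(per_bat$mean_run_days),
    sd_switch_interval_days = stats::sd(per_bat$mean_run_days),
    pooled_switch_interval_days = mean(runs$run_days),
    pooled_sd_switch_interval_days = stats::sd(runs$run_days),
    mean_roosts_per_bat = mean(per_bat$n_roosts),
    sd_roosts_per_bat = stats::sd(per_bat$n_roosts),
    mean_relocs_per_bat = mean(per_bat$n_relocs),
    sd_relocs_per_bat = stats::sd(per_bat$n_relocs),
    mean_bats_per_roost = mean(per_roost$n_bats),
    sd_bats_per_roost = stats::sd(per_roost$n_bats),
    mean_uses_per_roost = mean(per_roost$n_uses),
    sd_uses_per_roost = stats::sd(per_roost$n_uses)
  )
  structure(list(summary = summary, per_bat = per_bat,
                 per_roost = per_roost, runs = runs),
            class = "colony_summary")
}

#' @export
print.colony_summary <- function(x, ...) {
  cat("<colony_summary>\n")
  print(tidyr::pivot_longer(x$summary, dplyr::everything(),
                            names_to = "statistic", values_to = "value"))
  invisible(x)
}

#' Observation-bias check: roosts used vs. relocations (Poisson GLM)
#'
#' Regresses the number of roosts used by each bat on its number of
#' relocations with a log-link Poisson GLM, to check how strongly the
#' apparent roost repertoire depends on tracking effort. Reports the
#' slope with its 95% Wald interval, the deviance explained
#' `D2 = (null deviance - residual deviance) / null deviance` and the
#' adjusted value `1 - ((n - 1) / (n - p)) * (1 - D2)`.
#'
#' @param per_bat Data frame with one row per bat and columns `n_roosts`
#'   (response) and `n_relocs` (predictor), e.g. `$per_bat` from
#'   [roost_switching_stats()].
#' @return A `roost_glm` object with `tidy()` and `glance()` methods.
#' @export
poisson_glm_roosts_vs_relocs <- function(per_bat) {
  stopifnot(all(c("n_roosts", "n_relocs") %in% names(per_bat)))
  if (nrow(per_bat) < 3) abort("need at least 3 bats for the bias regression")
  if (any(per_bat$n_roosts < 1)) abort("roost counts must be >= 1")
  fit <- stats::glm(n_roosts ~ n_relocs, family = stats::poisson(), data = per_bat)
  if (!fit$converged) abort("Poisson GLM did not converge")
  beta <- stats::coef(fit)[["n_relocs"]]
  se <- sqrt(diag(stats::vcov(fit)))[["n_relocs"]]
  D2 <- if (fit$null.deviance < 1e-12) 0 else {
    (fit$null.deviance - fit$deviance) / fit$null.deviance
  }
  n <- nrow(per_bat)
  p <- length(stats::coef(fit))
  adj_D2 <- 1 - ((n - 1) / (n - p)) * (1 - D2)
  structure(list(
    fit = fit, beta = beta, se = se,
    ci_95 = beta + c(-1, 1) * stats::qnorm(0.975) * se,
    D2 = D2, adj_D2 = adj_D2, n = n
  ), class = "roost_glm")
}

#' @export
print.roost_glm <- function(x, ...) {
  cat(sprintf("<roost_glm> beta = %.3f (95%% CI %.3f - %.3f), D2 = %.3f, adj D2 = %.3f\n",
              x$beta, x$ci_95[1], x$ci_95[2], x$D2, x$adj_D2))
  invisible(x)
}

#' Tidy the roost-effort Poisson regression
#'
#' @param x A `roost_glm`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with Wald 95% CI;
#'   `glance()`: one row with deviances, D2 and adjusted D2.
#' @method tidy roost_glm
#' @export
tidy.roost_glm <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    conf_low = co[, "Estimate"] - stats::qnorm(0.975) * co[, "Std. Error"],
    conf_high = co[, "Estimate"] + stats::qnorm(0.975) * co[, "Std. Error"]
  )
}

#' @export
#' @rdname tidy.roost_glm
#' @method glance roost_glm
glance.roost_glm <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance,
    residual_deviance = x$fit$deviance,
    D2 = x$D2,
    adj_D2 = x$adj_D2,
    n = x$n
  )
}

#' Correlation between roost use by tagged bats and emergence counts
#'
#' Pearson correlation (with two-sided t-test) between the number of
#' days a roost was used by radio-tagged bats and the maximum emergence
#' count observed there --- the check that tagged-bat roost use tracks
#' overall colony roost use.
#'
#' @param roost_days Numeric vector: days used by tagged bats, per roost.
#' @param max_counts Numeric vector: maximum emergence count, per roost.
#' @return List with `r`, `p_value`, `n`.
#' @export
emergence_correlation <- function(roost_days, max_counts) {
  stopifnot(length(roost_days) == length(max_counts))
  keep <- is.finite(roost_days) & is.finite(max_counts)
  roost_days <- roost_days[keep]
  max_counts <- max_counts[keep]
  if (length(roost_days) < 3) abort("need at least 3 roosts with both values")
  if (stats::sd(roost_days) == 0 || stats::sd(max_counts) == 0) {
    abort("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(roost_days, max_counts, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(roost_days))
}

#' Join per-roost tagged use with maximum emergence counts
#'
#' @param relocations Relocation table (`bat_id`, `date`, `roost_id`).
#' @param exit_counts Exit-count table (`roost_id`, `date`, `count`).
#' @return Tibble with `roost_id`, `days_used`, `max_count` for roosts
#'   appearing in both tables.
#' @export
roost_use_vs_emergence <- function(relocations, exit_counts) {
  use <- relocations |>
    dplyr::group_by(.data$roost_id) |>
    dplyr::summarise(days_used = dplyr::n(), .groups = "drop")
  counts <- exit_counts |>
    dplyr::group_by(.data$roost_id) |>
    dplyr::summarise(max_count = max(.data$count), .groups = "drop")
  dplyr::inner_join(use, counts, by = "roost_id")
}
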