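#' Configuration for a synthetic maternity colony
#'
#' Bundles the parameters of the synthetic telemetry generator. Defaults
#' emulate a single field season of a midwestern Indiana bat maternity
#' colony: roughly 21 radio-tagged bats, 33 available roosts of which one
#' is a heavily used "primary" roost, a mean of about 9 diurnal
#' relocations per bat, roost switching every 3-4 days, and 40-70+
#' nightly foraging fixes for bats tracked long enough to be eligible for
#' a utilization distribution.
#'
#' @param n_tagged_bats Number of radio-tagged bats (tracked individuals).
#' @param n_untagged_bats Untagged colony members; they contribute to
#'   emergence counts only.
#' @param n_roosts Number of roost trees available to the colony.
#' @param primary_concentration Non-negative scalar `kappa` controlling how
#'   strongly colony roost choice concentrates on the primary roost. The
#'   colony-level backbone over roost ranks r is proportional to
#'   `r^-kappa`: 0 gives exchangeable (uniform-backbone) preferences,
#'   `Inf` a point mass on roost 1.
#' @param pref_concentration Total concentration of the per-bat Dirichlet
#'   perturbation around the colony backbone; small values give bats
#'   individually sparse roost repertoires (a primary roost plus a few
#'   secondaries), large values make every bat follow the backbone.
#' @param daily_switch_prob Probability, each tracked day, that a bat
#'   redraws its roost from its preference vector instead of staying put;
#'   in (0, 1].
#' @param tracking_days_per_bat List with elements `mean`, `sd`, `min`,
#'   `max` describing the (rounded, clipped) normal distribution of
#'   contiguous tracking-window lengths in days.
#' @param season_days Length of the field season in days.
#' @param fixes_per_night Foraging fixes recorded per tracked night.
#' @param night_duration_min Length of the nightly tracking window in
#'   minutes (fixes are at least 3 minutes apart within it).
#' @param roost_spread_m Standard deviation (m) of roost coordinates
#'   around the colony centre.
#' @param foraging_center_spread_m Standard deviation (m) of shared
#'   foraging-patch centres around the colony centre.
#' @param n_forage_patches Number of shared foraging patches; each bat
#'   is assigned one patch, so dyads within a patch overlap strongly
#'   (fission-fusion colonies concentrate foraging in a few corridors).
#' @param forage_patch_jitter_m Standard deviation (m) of a bat's
#'   foraging centre around its patch centre.
#' @param movement_step_sd_m Per-step standard deviation (m) of the
#'   correlated random walk generating nightly fixes.
#' @param n_exit_count_nights Number of (roost, date) emergence counts to
#'   sample; includes nights when no tagged bat occupied the roost.
#' @param start_date First calendar day of the season (ISO string or Date).
#' @param seed Integer seed; all stages draw from named substreams of it.
#'
#' @return An object of class `colony_config` (a validated list).
#' @export
#' @examples
#' cfg <- colony_config(n_tagged_bats = 5, n_roosts = 8, seed = 1)
#' colony <- generate_colony(cfg)
#' colony$relocations
colony_config <- function(n_tagged_bats = 21,
                          n_untagged_bats = 90,
                          n_roosts = 33,
                          primary_concentration = 1.0,
                          pref_concentration = 1,
                          daily_switch_prob = 0.3,
                          tracking_days_per_bat = list(mean = 9.3, sd = 5, min = 2, max = 28),
                          season_days = 75,
                          fixes_per_night = 8,
                          night_duration_min = 300,
                          roost_spread_m = 1500,
                          foraging_center_spread_m = 2000,
                          n_forage_patches = 2,
                          forage_patch_jitter_m = 100,
                          movement_step_sd_m = 350,
                          n_exit_count_nights = 60,
                          start_date = "2009-06-01",
                          seed = 1L) {
  counts <- c(n_tagged_bats = n_tagged_bats, n_untagged_bats = n_untagged_bats,
              n_roosts = n_roosts, season_days = season_days,
              fixes_per_night = fixes_per_night,
              night_duration_min = night_duration_min,
              n_exit_count_nights = n_exit_count_nights)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("all counts in a colony_config must be positive and finite")
  }
  if (is.na(primary_concentration) || primary_concentration < 0) {
    abort("primary_concentration must be a non-negative scalar (Inf allowed)")
  }
  if (!is.finite(daily_switch_prob) || daily_switch_prob <= 0 || daily_switch_prob > 1) {
    abort("daily_switch_prob must lie in (0, 1]")
  }
  if (!is.finite(pref_concentration) || pref_concentration <= 0) {
    abort("pref_concentration must be positive and finite")
  }
  cfg <- list(
    n_tagged_bats = as.integer(n_tagged_bats),
    n_untagged_bats = as.integer(n_untagged_bats),
    n_roosts = as.integer(n_roosts),
    primary_concentration = primary_concentration,
    pref_concentration = pref_concentration,
    daily_switch_prob = daily_switch_prob,
    tracking_days_per_bat = tracking_days_per_bat,
    season_days = as.integer(season_days),
    fixes_per_night = as.integer(fixes_per_night),
    night_duration_min = as.integer(night_duration_min),
    roost_spread_m = roost_spread_m,
    foraging_center_spread_m = foraging_center_spread_m,
    n_forage_patches = as.integer(n_forage_patches),
    forage_patch_jitter_m = forage_patch_jitter_m,
    movement_step_sd_m = movement_step_sd_m,
    n_exit_count_nights = as.integer(n_exit_count_nights),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  structure(cfg, class = "colony_config")
}

#' @export
print.colony_config <- function(x, ...) {
  cat("<colony_config> ", x$n_tagged_bats, " tagged bats, ", x$n_roosts,
      " roosts, kappa = ", format(x$primary_concentration),
      ", switch prob = ", x$daily_switch_prob, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Per-bat roost preference probabilities
#'
#' Draws each bat's probability vector over roosts as a Dirichlet
#' perturbation of a shared colony-level backbone. The backbone over
#' roost ranks r is proportional to `r^-kappa` where `kappa` is
#' `primary_concentration`: at 0 it is uniform (preferences exchangeable
#' across roosts), and as `kappa` grows all mass concentrates on the
#' shared primary roost (roost 1). `Inf` is the degenerate point-mass
#' case.
#'
#' @param config A [colony_config()].
#' @return Numeric matrix, `n_tagged_bats` rows by `n_roosts` columns;
#'   each row is non-negative and sums to 1.
#' @export
roost_preference_matrix <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  R <- config$n_roosts
  n <- config$n_tagged_bats
  kappa <- config$primary_concentration
  if (is.nan(kappa)) abort("primary_concentration must not be NaN")
  if (is.infinite(kappa)) {
    pref <- matrix(0, n, R)
    pref[, 1] <- 1
    return(pref)
  }
  backbone <- seq_len(R)^(-kappa)
  backbone <- backbone / sum(backbone)
  alpha <- config$pref_concentration * R * backbone
  with_stage_seed(config$seed, "preferences", {
    g <- matrix(stats::rgamma(n * R, shape = rep(alpha, each = n)), n, R)
    # guard against all-zero rows when shapes are tiny
    zero <- rowSums(g) == 0
    if (any(zero)) g[zero, ] <- matrix(rep(backbone, sum(zero)), ncol = R, byrow = TRUE)
    sweep(g, 1, rowSums(g), "/")
  })
}

bat_ids <- function(n) sprintf("bat%02d", seq_len(n))
roost_ids <- function(n) sprintf("roost%02d", seq_len(n))

#' Generate synthetic maternity-colony telemetry
#'
#' Simulates one field season of radio-telemetry for a fission-fusion
#' maternity colony: diurnal roost relocations (one per tracked bat-day,
#' produced by a stay/switch process over the bat's roost preference
#' vector), nightly foraging fixes (a correlated random walk attracted to
#' a bat-specific foraging centre), emergence counts on sampled nights
#' (tagged plus untagged occupants), and bat / roost attribute tables.
#'
#' @param config A [colony_config()].
#' @return An object of class `bat_colony`: a list of tibbles
#'   `relocations` (`bat_id`, `date`, `roost_id`), `fixes` (`bat_id`,
#'   `timestamp`, `x_m`, `y_m`), `exit_counts` (`roost_id`, `date`,
#'   `count`), `bats` (`bat_id`, `age_class`, `sex`, `repro`), `roosts`
#'   (`roost_id`, `x_m`, `y_m`), plus the `config`.
#' @export
generate_colony <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  n <- config$n_tagged_bats
  R <- config$n_roosts

  roosts <- with_stage_seed(config$seed, "roosts", tibble::tibble(
    roost_id = roost_ids(R),
    x_m = stats::rnorm(R, 0, config$roost_spread_m),
    y_m = stats::rnorm(R, 0, config$roost_spread_m)
  ))

  bats <- with_stage_seed(config$seed, "bats", {
    age <- sample(c("adult", "juvenile"), n, replace = TRUE, prob = c(0.7, 0.3))
    sex <- ifelse(age == "adult", "F",
                  sample(c("F", "M"), n, replace = TRUE))
    repro <- ifelse(
      age == "adult",
      sample(c("lactating", "post-lactating", "pregnant", "unknown"),
             n, replace = TRUE, prob = c(0.4, 0.2, 0.1, 0.3)),
      "non-reproductive"
    )
    tibble::tibble(bat_id = bat_ids(n), age_class = age, sex = sex, repro = repro)
  })

  pref <- roost_preference_matrix(config)

  td <- config$tracking_days_per_bat
  tracking <- with_stage_seed(config$seed, "relocations", {
    days <- pmin(pmax(round(stats::rnorm(n, td$mean, td$sd)), td$min), td$max)
    start <- sample.int(max(config$season_days - max(days), 1L), n, replace = TRUE)
    rel <- vector("list", n)
    for (i in seq_len(n)) {
      cur <- sample.int(R, 1, prob = pref[i, ])
      seq_roost <- integer(days[i])
      for (d in seq_len(days[i])) {
        if (d > 1 && stats::runif(1) < config$daily_switch_prob) {
          cur <- sample.int(R, 1, prob = pref[i, ])
        }
        seq_roost[d] <- cur
      }
      rel[[i]] <- tibble::tibble(
        bat_id = bat_ids(n)[i],
        date = config$start_date + start[i] + seq_len(days[i]) - 1L,
        roost_id = roost_ids(R)[seq_roost]
      )
    }
    dplyr::bind_rows(rel)
  })

  if (nrow(tracking) == 0) {
    warn("configuration produced zero tracking days; returning empty tables")
  }

  fixes <- with_stage_seed(config$seed, "fixes", {
    px <- stats::rnorm(config$n_forage_patches, 0, config$foraging_center_spread_m)
    py <- stats::rnorm(config$n_forage_patches, 0, config$foraging_center_spread_m)
    patch <- sample.int(config$n_forage_patches, n, replace = TRUE)
    centers_x <- px[patch] + stats::rnorm(n, 0, config$forage_patch_jitter_m)
    centers_y <- py[patch] + stats::rnorm(n, 0, config$forage_patch_jitter_m)
    nf <- config$fixes_per_night
    out <- vector("list", 0)
    for (i in seq_len(n)) {
      nights <- unique(tracking$date[tracking$bat_id == bat_ids(n)[i]])
      for (night in as.list(nights)) {
        # timestamps: integer-minute gaps of at least 3 min inside the window
        max_gap <- max(3L, floor(config$night_duration_min / nf))
        gaps <- 2L + sample.int(max_gap - 2L, nf - 1, replace = TRUE)
        mins <- cumsum(c(sample.int(15L, 1), gaps))
        t0 <- as.POSIXct(paste(format(night[[1]]), "21:30:00"), tz = "UTC")
        xy <- matrix(0, nf, 2)
        xy[1, ] <- c(centers_x[i], centers_y[i]) + stats::rnorm(2, 0, config$movement_step_sd_m)
        for (j in seq_len(nf)[-1]) {
          pull <- 0.3 * (c(centers_x[i], centers_y[i]) - xy[j - 1, ])
          xy[j, ] <- xy[j - 1, ] + pull + stats::rnorm(2, 0, config$movement_step_sd_m)
        }
        out[[length(out) + 1]] <- tibble::tibble(
          bat_id = bat_ids(n)[i],
          timestamp = t0 + mins * 60,
          x_m = xy[, 1], y_m = xy[, 2]
        )
      }
    }
    dplyr::bind_rows(out) |> dplyr::arrange(.data$bat_id, .data$timestamp)
  })

  exit_counts <- with_stage_seed(config$seed, "exit_counts", {
    backbone <- if (is.infinite(config$primary_concentration)) {
      c(1, rep(0, R - 1))
    } else {
      b <- seq_len(R)^(-config$primary_concentration)
      b / sum(b)
    }
    dates <- config$start_date + sample.int(config$season_days, config$n_exit_count_nights,
                                            replace = TRUE) - 1L
    watched <- sample.int(R, config$n_exit_count_nights, replace = TRUE,
                          prob = 0.5 * backbone + 0.5 / R)
    tagged <- dplyr::count(tracking, .data$date, .data$roost_id, name = "n_tagged")
    counts <- integer(config$n_exit_count_nights)
    for (k in seq_len(config$n_exit_count_nights)) {
      untagged_occ <- stats::rmultinom(1, config$n_untagged_bats, backbone)[watched[k], 1]
      tg <- tagged$n_tagged[tagged$date == dates[k] &
                              tagged$roost_id == roost_ids(R)[watched[k]]]
      counts[k] <- untagged_occ + if (length(tg)) tg else 0L
    }
    tibble::tibble(roost_id = roost_ids(R)[watched], date = dates, count = counts) |>
      dplyr::distinct(.data$roost_id, .data$date, .keep_all = TRUE)
  })

  structure(
    list(relocations = tracking, fixes = fixes, exit_counts = exit_counts,
         bats = bats, roosts = roosts, config = config),
    class = "bat_colony"
  )
}

#' @export
print.bat_colony <- function(x, ...) {
  cat("<bat_colony> ", nrow(x$bats), " tagged bats, ",
      dplyr::n_distinct(x$relocations$roost_id), " roosts used, ",
      nrow(x$relocations), " relocations, ", nrow(x$fixes),
      " foraging fixes, ", nrow(x$exit_counts), " exit counts\n", sep = "")
  invisible(x)
}

#' Write the tables of a synthetic colony to CSV files
#'
#' Emits `relocations.csv`, `fixes.csv`, `exit_counts.csv`, `bats.csv` and
#' `roosts.csv` with ISO-8601 dates/timestamps and planar coordinates in
#' meters.
#'
#' @param colony A `bat_colony` from [generate_colony()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_colony_csv <- function(colony, dir) {
  stopifnot(inherits(colony, "bat_colony"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fixes <- dplyr::mutate(colony$fixes,
                         timestamp_iso = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ")) |>
    dplyr::select("bat_id", "timestamp_iso", "x_m", "y_m")
  paths <- c(
    relocations = file.path(dir, "relocations.csv"),
    fixes = file.path(dir, "fixes.csv"),
    exit_counts = file.path(dir, "exit_counts.csv"),
    bats = file.path(dir, "bats.csv"),
    roosts = file.path(dir, "roosts.csv")
  )
  readr::write_csv(colony$relocations, paths["relocations"])
  readr::write_csv(fixes, paths["fixes"])
  readr::write_csv(colony$exit_counts, paths["exit_counts"])
  readr::write_csv(colony$bats, paths["bats"])
  readr::write_csv(colony$roosts, paths["roosts"])
  invisible(paths)
}

#' Read colony telemetry tables from CSV files
#'
#' Counterpart to [write_colony_csv()]; validates the relocation table
#' (one row per bat-day).
#'
#' @param dir Directory containing the CSV files.
#' @return A `bat_colony` list (without a `config`).
#' @export
read_colony_csv <- function(dir) {
  rel <- readr::read_csv(file.path(dir, "relocations.csv"),
                         col_types = readr::cols(
                           bat_id = "c", date = readr::col_date(), roost_id = "c"))
  if (anyDuplicated(rel[c("bat_id", "date")])) {
    abort("relocations.csv has more than one roost for some bat-day")
  }
  fixes <- readr::read_csv(file.path(dir, "fixes.csv"),
                           col_types = readr::cols(
                             bat_id = "c",
                             timestamp_iso = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%SZ"),
                             x_m = "d", y_m = "d")) |>
    dplyr::rename(timestamp = "timestamp_iso")
  structure(list(
    relocations = rel,
    fixes = fixes,
    exit_counts = readr::read_csv(file.path(dir, "exit_counts.csv"),
                                  col_types = readr::cols(
                                    roost_id = "c", date = readr::col_date(), count = "i")),
    bats = readr::read_csv(file.path(dir, "bats.csv"), col_types = readr::cols(.default = "c")),
    roosts = readr::read_csv(file.path(dir, "roosts.csv"),
                             col_types = readr::cols(roost_id = "c", x_m = "d", y_m = "d")),
    config = NULL
  ), class = "bat_colony")
}
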