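#' Congruence between foraging overlap and social proximity
#'
#' Counts foraging-overlap dyads (edges of the overlap network) whose
#' endpoints are also in close social proximity: geodesic distance in
#' the social network strictly less than the colony's mean shortest
#' path length.
#'
#' @param social Single-mode social network (igraph; bat names).
#' @param overlap Foraging-overlap network (igraph; bat names must
#'   intersect the social network's).
#' @return Tibble with `n_overlap_dyads`, `n_also_close`,
#'   `colony_mean_path`.
#' @export
social_foraging_congruence <- function(social, overlap) {
  s_ids <- igraph::V(social)$name
  o_ids <- igraph::V(overlap)$name
  if (is.null(s_ids) || is.null(o_ids) || !length(intersect(s_ids, o_ids))) {
    abort("social and overlap networks share no bat identifiers")
  }
  mean_path <- as.numeric(net_mean_shortest_path(social))
  el <- igraph::as_edgelist(overlap)
  n_close <- 0L
  n_dyads <- 0L
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      if (!(el[i, 1] %in% s_ids) || !(el[i, 2] %in% s_ids)) next
      n_dyads <- n_dyads + 1L
      d <- igraph::distances(social, v = el[i, 1], to = el[i, 2])[1, 1]
      if (is.finite(d) && d < mean_path) n_close <- n_close + 1L
    }
  }
  tibble::tibble(n_overlap_dyads = n_dyads, n_also_close = n_close,
                 colony_mean_path = mean_path)
}

#' Analyse one colony-year
#'
#' Runs the full per-year analysis on a telemetry bundle: builds the
#' two-mode network and its projections, computes the metric suite,
#' compares the two-mode and social networks to Erdos-Renyi nulls,
#' simulates random and targeted roost removal on the roost projection,
#' summarises tracking effort (roost switching, the Poisson
#' observation-bias regression, the emergence-count correlation), and,
#' when at least two bats have enough foraging fixes, estimates
#' individual BRB utilization distributions, the dyadic UDOI table and
#' overlap network, colony-level roosting (roost-day weighted kernel)
#' and foraging (pooled fixed kernel) UDs, their areas and the roosting
#' centroid.
#'
#' @param colony A `bat_colony` (from [generate_colony()] or
#'   [read_colony_csv()]).
#' @param year_label Label used in report rows.
#' @param n_sims Null-model draws (default 500).
#' @param n_reps Removal replicates per proportion (default 1000).
#' @param max_removed_fraction,removal_step Removal grid (default 0 to
#'   0.70 by 0.05).
#' @param min_fixes UD eligibility threshold (default 40 fixes).
#' @param params [brb_params()] for the spatial stage.
#' @param cell Grid cell size in meters (default 30).
#' @param level Isopleth level (default 0.95).
#' @param udoi_threshold Overlap-network edge threshold (default 1).
#' @param seed Integer seed (stage substreams are derived from it).
#' @return A `colony_analysis` list; see the elements in the description.
#' @export
analyze_colony <- function(colony, year_label = "year1",
                           n_sims = 500, n_reps = 1000,
                           max_removed_fraction = 0.70, removal_step = 0.05,
                           min_fixes = 40, params = brb_params(),
                           cell = 30, level = 0.95, udoi_threshold = 1.0,
                           seed = 1L) {
  stopifnot(inherits(colony, "bat_colony"))
  bip <- build_bipartite(colony$relocations, bat_attrs = colony$bats)
  social <- project(bip, "bats")
  roost_proj <- project(bip, "roosts")

  metrics <- dplyr::bind_rows(
    network_metrics(bip, paste0("roost_", year_label)),
    network_metrics(social, paste0("social_", year_label))
  )

  nulls_two_mode <- run_null_suite(bip, n_sims = n_sims, seed = seed)
  social_metrics <- c("density", "clustering", "degree_centralization",
                      "modularity", "mean_shortest_path")
  if ("age_class" %in% igraph::vertex_attr_names(social) &&
      dplyr::n_distinct(igraph::V(social)$age_class) > 1) {
    social_metrics <- c(social_metrics, "homophily")
  }
  nulls_social <- run_null_suite(social, metrics = social_metrics,
                                 n_sims = n_sims, seed = seed + 1L)

  removal <- random_removal_curve(roost_proj,
                                  max_removed_fraction = max_removed_fraction,
                                  step = removal_step, n_reps = n_reps,
                                  seed = seed)
  targeted <- targeted_removal(roost_proj, k = 1)

  summaries <- roost_switching_stats(colony$relocations)
  glm_bias <- tryCatch(poisson_glm_roosts_vs_relocs(summaries$per_bat),
                       error = function(e) NULL)
  emergence <- if (!is.null(colony$exit_counts) && nrow(colony$exit_counts) > 0) {
    ue <- roost_use_vs_emergence(colony$relocations, colony$exit_counts)
    tryCatch(emergence_correlation(ue$days_used, ue$max_count),
             error = function(e) NULL)
  }

  spatial <- analyze_spatial(colony, min_fixes = min_fixes, params = params,
                             cell = cell, level = level,
                             udoi_threshold = udoi_threshold)
  congruence <- if (!is.null(spatial$overlap)) {
    social_foraging_congruence(social, spatial$overlap$graph)
  }

  structure(list(
    year = year_label,
    networks = list(bipartite = bip, social = social, roost_projection = roost_proj),
    metrics = metrics,
    nulls = list(roost = nulls_two_mode, social = nulls_social),
    removal = removal, targeted = targeted,
    summaries = summaries, glm_bias = glm_bias, emergence = emergence,
    spatial = spatial, congruence = congruence,
    settings = list(n_sims = n_sims, n_reps = n_reps,
                    max_removed_fraction = max_removed_fraction,
                    removal_step = removal_step, min_fixes = min_fixes,
                    brb = unclass(params), cell = cell, level = level,
                    udoi_threshold = udoi_threshold, seed = seed)
  ), class = "colony_analysis")
}

# Spatial stage: individual BRB UDs for eligible bats on a shared grid,
# dyadic overlap, and colony-level roosting/foraging UDs. Skips the
# overlap analysis (with a recorded reason) when fewer than 2 bats are
# eligible.
analyze_spatial <- function(colony, min_fixes = 40, params = brb_params(),
                            cell = 30, level = 0.95, udoi_threshold = 1.0) {
  out <- list(uds = NULL, overlap = NULL, skipped = NULL,
              colony_foraging_ud = NULL, colony_roosting_ud = NULL,
              foraging_area_ha = NA_real_, roosting_area_ha = NA_real_,
              roosting_centroid = NULL)
  fixes <- colony$fixes
  if (is.null(fixes) || nrow(fixes) == 0) {
    out$skipped <- "no foraging fixes"
    return(out)
  }
  counts <- dplyr::count(fixes, .data$bat_id)
  eligible <- counts$bat_id[counts$n >= min_fixes]

  # segment eligible tracks first so the shared grid can be buffered by
  # the largest bridge bandwidth (which grows with the diffusion D)
  tracks <- lapply(eligible, function(b) {
    segment_track(fixes[fixes$bat_id == b, , drop = FALSE], params)
  })
  names(tracks) <- eligible
  hmax <- params$hmin
  for (tr in tracks) {
    ok <- tr$segments$status == "usable"
    if (!any(ok)) next
    D <- tryCatch(as.numeric(estimate_diffusion_plugin(tr)),
                  error = function(e) NA_real_)
    if (is.finite(D)) {
      hb <- sqrt(params$hmin^2 + 2 * D * max(tr$segments$duration_min[ok]) * 0.25)
      hmax <- max(hmax, hb)
    }
  }
  spec <- grid_spec_from_points(fixes$x_m, fixes$y_m,
                                buffer = max(4 * hmax, 6 * params$hmin),
                                cell = cell)

  if (length(eligible) >= 2) {
    uds <- lapply(tracks, function(tr) brb_ud(tr, spec = spec))
    names(uds) <- eligible
    out$uds <- uds
    out$overlap <- foraging_overlap_network(uds, threshold = udoi_threshold,
                                            level = level)
    out$individual_areas <- tibble::tibble(
      bat_id = eligible,
      area_ha = vapply(uds, function(u) isopleth(u, level)$area_ha, numeric(1))
    )
  } else {
    out$skipped <- sprintf("fewer than 2 bats with >= %d fixes", min_fixes)
  }

  out$colony_foraging_ud <- weighted_kernel_ud(fixes, cell = cell)
  out$foraging_area_ha <- isopleth(out$colony_foraging_ud, level)$area_ha

  roost_use <- colony$relocations |>
    dplyr::count(.data$roost_id, name = "days_used") |>
    dplyr::inner_join(colony$roosts, by = "roost_id")
  if (nrow(roost_use) >= 2 &&
      (stats::sd(roost_use$x_m) > 0 || stats::sd(roost_use$y_m) > 0)) {
    out$colony_roosting_ud <- weighted_kernel_ud(roost_use,
                                                 weights = roost_use$days_used,
                                                 cell = cell)
    out$roosting_area_ha <- isopleth(out$colony_roosting_ud, level)$area_ha
  }
  out$roosting_centroid <- ud_centroid(roost_use, roost_use$days_used)
  out
}

#' @export
print.colony_analysis <- function(x, ...) {
  cat("<colony_analysis> ", x$year, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Run the full multi-year pipeline
#'
#' Generates (or accepts) one colony per year, analyses each with
#' [analyze_colony()], and adds the cross-year comparisons: the
#' Bhattacharyya affinity of colony roosting and foraging UDs between
#' consecutive years (recomputed on a shared grid) and the roosting
#' centroid shift in meters. A manifest records the seed and every
#' analysis setting so the report is reproducible from it alone.
#'
#' @param configs List of [colony_config()]s, or a list of `bat_colony`
#'   objects, one per year.
#' @param year_labels Character labels (default `"year1"`, ...).
#' @param seed Global seed; per-year and per-stage seeds derive from it.
#' @param out_dir Optional directory: writes per-year metric/null/removal
#'   CSVs, networks as GraphML, and the manifest JSON.
#' @param ... Passed to [analyze_colony()].
#' @return A `colony_pipeline` list: `years` (named `colony_analysis`
#'   list), `cross_year` (tibble), `manifest`.
#' @export
run_pipeline <- function(configs, year_labels = NULL, seed = 1L,
                         out_dir = NULL, ...) {
  stopifnot(length(configs) >= 1)
  year_labels <- year_labels %||% paste0("year", seq_along(configs))
  colonies <- lapply(configs, function(cf) {
    if (inherits(cf, "bat_colony")) cf else generate_colony(cf)
  })
  years <- purrr::map2(colonies, seq_along(colonies), function(col, i) {
    analyze_colony(col, year_label = year_labels[i],
                   seed = stage_seed(seed + i, "pipeline"), ...)
  })
  names(years) <- year_labels

  cross <- NULL
  if (length(years) >= 2) {
    cross <- purrr::map_dfr(seq_len(length(years) - 1), function(i) {
      a <- years[[i]]; b <- years[[i + 1]]
      cmp_ud <- function(ud1, ud2, pts1, pts2, w1, w2) {
        if (is.null(ud1) || is.null(ud2)) return(NA_real_)
        cell <- ud1$cell
        spec <- grid_spec(min(ud1$x[1], ud2$x[1]) - cell / 2,
                          max(ud1$x[length(ud1$x)], ud2$x[length(ud2$x)]) + cell / 2,
                          min(ud1$y[1], ud2$y[1]) - cell / 2,
                          max(ud1$y[length(ud1$y)], ud2$y[length(ud2$y)]) + cell / 2,
                          cell)
        u1 <- weighted_kernel_ud(pts1, weights = w1, spec = spec, h = ud1$meta$h)
        u2 <- weighted_kernel_ud(pts2, weights = w2, spec = spec, h = ud2$meta$h)
        bhattacharyya_affinity(u1, u2)
      }
      ca <- colonies[[i]]; cb <- colonies[[i + 1]]
      ra <- dplyr::count(ca$relocations, .data$roost_id, name = "days_used") |>
        dplyr::inner_join(ca$roosts, by = "roost_id")
      rb <- dplyr::count(cb$relocations, .data$roost_id, name = "days_used") |>
        dplyr::inner_join(cb$roosts, by = "roost_id")
      tibble::tibble(
        from = names(years)[i], to = names(years)[i + 1],
        ba_roosting = cmp_ud(a$spatial$colony_roosting_ud,
                             b$spatial$colony_roosting_ud,
                             ra, rb, ra$days_used, rb$days_used),
        ba_foraging = cmp_ud(a$spatial$colony_foraging_ud,
                             b$spatial$colony_foraging_ud,
                             ca$fixes, cb$fixes, NULL, NULL),
        centroid_shift_m = centroid_shift(a$spatial$roosting_centroid,
                                          b$spatial$roosting_centroid)
      )
    })
  }

  manifest <- list(
    seed = seed, year_labels = year_labels,
    settings = years[[1]]$settings,
    configs = lapply(colonies, function(col) {
      if (is.null(col$config)) NULL else unclass(col$config)
    }),
    package_version = as.character(utils::packageVersion("roostnet"))
  )
  result <- structure(list(years = years, cross_year = cross,
                           manifest = manifest),
                      class = "colony_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.colony_pipeline <- function(x, ...) {
  cat("<colony_pipeline> years: ", paste(names(x$years), collapse = ", "),
      "\n", sep = "")
  for (y in x$years) print(y$metrics)
  if (!is.null(x$cross_year)) print(x$cross_year)
  invisible(x)
}

# Write the per-year tables, networks and the manifest under out_dir.
write_pipeline_outputs <- function(pipeline, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (yl in names(pipeline$years)) {
    y <- pipeline$years[[yl]]
    d <- file.path(out_dir, yl)
    dir.create(d, showWarnings = FALSE)
    readr::write_csv(y$metrics, file.path(d, "metrics.csv"))
    readr::write_csv(dplyr::bind_rows(
      dplyr::mutate(tidy(y$nulls$roost), network = "roost"),
      dplyr::mutate(tidy(y$nulls$social), network = "social")
    ), file.path(d, "null_tests.csv"))
    readr::write_csv(tidy(y$removal), file.path(d, "removal_curve.csv"))
    readr::write_csv(y$summaries$summary, file.path(d, "summaries.csv"))
    write_network(y$networks$bipartite,
                  path_graphml = file.path(d, "bipartite.graphml"),
                  path_edges = file.path(d, "bipartite_edges.csv"))
    write_network(y$networks$social,
                  path_graphml = file.path(d, "social.graphml"))
    if (!is.null(y$spatial$overlap)) {
      readr::write_csv(y$spatial$overlap$dyads, file.path(d, "udoi_dyads.csv"))
    }
    if (!is.null(y$glm_bias) && requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(as.list(glance(y$glm_bias)),
                           file.path(d, "glm.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  if (!is.null(pipeline$cross_year)) {
    readr::write_csv(pipeline$cross_year, file.path(out_dir, "cross_year.csv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(pipeline$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out_dir)
}
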