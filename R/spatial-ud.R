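#' Define a regular analysis grid
#'
#' @param xmin,xmax,ymin,ymax Extent in meters.
#' @param cell Cell size in meters (default 30).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(xmin, xmax, ymin, ymax, cell = 30) {
  stopifnot(is.finite(cell), cell > 0, xmax > xmin, ymax > ymin)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 cell = cell), class = "grid_spec")
}

#' Grid spec covering a point set, buffered for kernel mass
#'
#' Extent is the bounding box of the points buffered by `buffer` (choose
#' at least 3x the largest bandwidth so that better than 99.9% of kernel
#' mass falls inside).
#'
#' @param x,y Point coordinates (meters).
#' @param buffer Buffer width in meters.
#' @param cell Cell size in meters.
#' @return A `grid_spec`.
#' @export
grid_spec_from_points <- function(x, y, buffer, cell = 30) {
  stopifnot(length(x) == length(y), length(x) > 0, all(is.finite(c(x, y))))
  grid_spec(min(x) - buffer, max(x) + buffer,
            min(y) - buffer, max(y) + buffer, cell)
}

grid_centers <- function(spec) {
  nx <- max(1L, ceiling((spec$xmax - spec$xmin) / spec$cell))
  ny <- max(1L, ceiling((spec$ymax - spec$ymin) / spec$cell))
  list(
    x = spec$xmin + (seq_len(nx) - 0.5) * spec$cell,
    y = spec$ymin + (seq_len(ny) - 0.5) * spec$cell
  )
}

new_ud_grid <- function(xc, yc, cell, mass, meta = list()) {
  structure(list(x = xc, y = yc, cell = cell, mass = mass, meta = meta),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat("<ud_grid> ", length(x$x), " x ", length(x$y), " cells of ",
      x$cell, " m; total mass ", format(sum(x$mass)), "\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$x) == length(b$x) && length(a$y) == length(b$y) &&
    isTRUE(all.equal(a$x, b$x, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$y, b$y, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$cell, b$cell, tolerance = 1e-9))
}

# Add w times an isotropic Gaussian density (sd in meters) centered at
# (mux, muy) to a density accumulator, evaluated at cell centers within
# 5 standard deviations.
add_gaussian <- function(dens, xc, yc, mux, muy, sd, w) {
  r <- 5 * sd
  ix <- which(xc >= mux - r & xc <= mux + r)
  iy <- which(yc >= muy - r & yc <= muy + r)
  if (length(ix) == 0 || length(iy) == 0) return(dens)
  dx <- stats::dnorm(xc[ix], mux, sd)
  dy <- stats::dnorm(yc[iy], muy, sd)
  dens[ix, iy] <- dens[ix, iy] + w * (dx %o% dy)
  dens
}

# Convert an accumulated density surface (integral ~ 1) into a
# normalized probability-mass grid, checking that the grid captured
# enough of the mass.
finish_ud <- function(dens, xc, yc, cell, meta, min_coverage = 0.999) {
  mass <- dens * cell^2
  coverage <- sum(mass)
  if (coverage < min_coverage) {
    abort(sprintf("extend grid: only %.1f%% of kernel mass fell inside the extent",
                  100 * coverage))
  }
  meta$coverage <- coverage
  new_ud_grid(xc, yc, cell, mass / coverage, meta)
}

#' Build a UD grid from a mass matrix
#'
#' Wraps a non-negative matrix as a utilization distribution on a
#' regular grid (normalised to total mass 1). Useful for analytic
#' reference distributions (uniform, Gaussian) in tests and examples.
#'
#' @param mass Non-negative matrix; rows index x, columns index y.
#' @param cell Cell size in meters.
#' @param x0,y0 Coordinates of the grid's lower-left corner.
#' @return A `ud_grid`.
#' @export
as_ud_grid <- function(mass, cell, x0 = 0, y0 = 0) {
  mass <- as.matrix(mass)
  if (any(mass < 0) || sum(mass) <= 0) {
    abort("mass must be non-negative with positive sum")
  }
  new_ud_grid(x0 + (seq_len(nrow(mass)) - 0.5) * cell,
              y0 + (seq_len(ncol(mass)) - 0.5) * cell,
              cell, mass / sum(mass), list(kind = "user"))
}

#' Parameters of the biased-random-bridge estimator
#'
#' @param Tmax Maximum duration (minutes) between successive fixes for a
#'   segment to be usable as a bridge (default 60).
#' @param Lmin Minimum distance (meters) between successive fixes for a
#'   segment to count as movement; shorter segments are treated as
#'   resting and contribute point kernels only (default 50).
#' @param hmin Minimum smoothing parameter in meters (default 88).
#' @param D Diffusion coefficient in m^2/min; `NULL` means estimate it
#'   with [estimate_diffusion_plugin()].
#' @return A `brb_params` list.
#' @export
brb_params <- function(Tmax = 60, Lmin = 50, hmin = 88, D = NULL) {
  stopifnot(Tmax > 0, Lmin > 0, hmin > 0, is.null(D) || D > 0)
  structure(list(Tmax = Tmax, Lmin = Lmin, hmin = hmin, D = D),
            class = "brb_params")
}

#' Segment a nightly track into usable, resting and unusable steps
#'
#' Successive fixes more than `Tmax` minutes apart cannot be bridged
#' (unusable); steps shorter than `Lmin` are resting (point-kernel
#' contribution only); the remainder are usable movement segments.
#'
#' @param fixes Data frame for one bat with columns `timestamp`
#'   (POSIXct), `x_m`, `y_m`; timestamps must be strictly increasing.
#' @param params A [brb_params()].
#' @return A `bat_track`: list with `fixes` and a `segments` tibble
#'   (`i0`, `i1`, `duration_min`, `length_m`, `status`).
#' @export
segment_track <- function(fixes, params = brb_params()) {
  stopifnot(all(c("timestamp", "x_m", "y_m") %in% names(fixes)))
  if (nrow(fixes) < 2) abort("a track needs at least 2 fixes")
  if (any(!is.finite(fixes$x_m)) || any(!is.finite(fixes$y_m))) {
    abort("fix coordinates must be finite")
  }
  tsec <- as.numeric(fixes$timestamp)
  if (any(diff(tsec) <= 0)) abort("timestamps must be strictly increasing")
  dur <- diff(tsec) / 60
  len <- sqrt(diff(fixes$x_m)^2 + diff(fixes$y_m)^2)
  status <- ifelse(dur > params$Tmax, "unusable",
                   ifelse(len < params$Lmin, "resting", "usable"))
  segments <- tibble::tibble(
    i0 = seq_len(nrow(fixes) - 1), i1 = seq_len(nrow(fixes) - 1) + 1L,
    duration_min = dur, length_m = len, status = status
  )
  structure(list(fixes = fixes, segments = segments, params = params),
            class = "bat_track")
}

#' @export
print.bat_track <- function(x, ...) {
  cat("<bat_track> ", nrow(x$fixes), " fixes; segments: ",
      paste(names(table(x$segments$status)), table(x$segments$status),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plug-in estimate of the bridge diffusion coefficient
#'
#' For every interior fix flanked by two usable segments, the fix is
#' left out and interpolated as a Brownian bridge between its
#' neighbours: at relative time `p` the bridge has per-coordinate
#' variance `2 D delta p (1 - p)` (delta = total duration, minutes). The
#' returned D maximises the product of these leave-one-out bivariate
#' normal likelihoods, which has the closed form
#' `D = mean(r^2 / (4 delta p (1 - p)))` over eligible triplets (`r` =
#' distance from the fix to the linear interpolation).
#'
#' @param track A `bat_track` from [segment_track()].
#' @return Diffusion coefficient D in m^2/min, with attribute
#'   `n_triplets`.
#' @export
estimate_diffusion_plugin <- function(track) {
  stopifnot(inherits(track, "bat_track"))
  seg <- track$segments
  fx <- track$fixes
  eligible <- which(seg$status[-nrow(seg)] == "usable" &
                      seg$status[-1] == "usable") + 1L
  if (length(eligible) == 0) {
    abort("cannot estimate D: no interior fix flanked by usable segments")
  }
  tsec <- as.numeric(fx$timestamp)
  contrib <- vapply(eligible, function(i) {
    delta <- (tsec[i + 1] - tsec[i - 1]) / 60
    p <- (tsec[i] - tsec[i - 1]) / (tsec[i + 1] - tsec[i - 1])
    mux <- (1 - p) * fx$x_m[i - 1] + p * fx$x_m[i + 1]
    muy <- (1 - p) * fx$y_m[i - 1] + p * fx$y_m[i + 1]
    r2 <- (fx$x_m[i] - mux)^2 + (fx$y_m[i] - muy)^2
    r2 / (4 * delta * p * (1 - p))
  }, numeric(1))
  D <- mean(contrib)
  if (!is.finite(D) || D <= 0) abort("cannot estimate D: degenerate triplets")
  structure(D, n_triplets = length(eligible))
}

#' Biased-random-bridge utilization distribution
#'
#' Each usable segment spreads probability mass along the straight line
#' between its fixes: at relative time `p` the kernel is an isotropic
#' Gaussian with variance `hmin^2 + 2 D T p (1 - p)` (T = segment
#' duration), time-integrated with a midpoint rule whose spatial step
#' never exceeds `hmin / 4`. Resting segments contribute a point kernel
#' at bandwidth `hmin` at their midpoint, weighted by their duration;
#' segments longer than `Tmax` contribute nothing. Total mass is
#' normalised to 1 (an error is raised if the grid captures less than
#' 99.9% of the mass).
#'
#' @param track A `bat_track` (or a 1-fix data frame, which yields a
#'   single resting kernel).
#' @param spec A [grid_spec()]; `NULL` buffers the track's bounding box
#'   by 3x the largest bandwidth at 30 m cells.
#' @param D Diffusion coefficient; `NULL` uses `track$params$D` or the
#'   plug-in estimate.
#' @return A `ud_grid` (probability mass per cell, summing to 1) with
#'   `meta` recording D, hmin and coverage.
#' @export
brb_ud <- function(track, spec = NULL, D = NULL) {
  if (is.data.frame(track)) {
    if (nrow(track) != 1) abort("data-frame input to brb_ud must be a single fix")
    params <- brb_params()
    fx <- track
    seg <- NULL
  } else {
    stopifnot(inherits(track, "bat_track"))
    params <- track$params
    fx <- track$fixes
    seg <- track$segments[track$segments$status != "unusable", , drop = FALSE]
    if (nrow(seg) == 0) seg <- NULL
  }
  needs_D <- !is.null(seg) && any(seg$status == "usable")
  if (needs_D) {
    D <- D %||% params$D %||% as.numeric(estimate_diffusion_plugin(track))
    stopifnot(is.finite(D), D > 0)
  }
  hmax <- params$hmin
  if (needs_D) {
    Tmaxobs <- max(seg$duration_min[seg$status == "usable"])
    hmax <- sqrt(params$hmin^2 + 2 * D * Tmaxobs * 0.25)
  }
  spec <- spec %||% grid_spec_from_points(fx$x_m, fx$y_m, buffer = 3 * hmax)
  gc <- grid_centers(spec)
  dens <- matrix(0, length(gc$x), length(gc$y))
  tsec <- as.numeric(fx$timestamp)

  if (is.null(seg)) {
    dens <- add_gaussian(dens, gc$x, gc$y, fx$x_m[1], fx$y_m[1], params$hmin, 1)
    return(finish_ud(dens, gc$x, gc$y, spec$cell,
                     list(D = NA_real_, hmin = params$hmin, kind = "brb")))
  }

  total_w <- 0
  for (s in seq_len(nrow(seg))) {
    i0 <- seg$i0[s]; i1 <- seg$i1[s]
    dur <- seg$duration_min[s]
    if (seg$status[s] == "resting") {
      # resting time sits at the fixes themselves, so an all-resting
      # track degenerates exactly to a fixed kernel on its fixes
      dens <- add_gaussian(dens, gc$x, gc$y, fx$x_m[i0], fx$y_m[i0],
                           params$hmin, dur / 2)
      dens <- add_gaussian(dens, gc$x, gc$y, fx$x_m[i1], fx$y_m[i1],
                           params$hmin, dur / 2)
      total_w <- total_w + dur
    } else {
      m <- max(15L, ceiling(seg$length_m[s] / (params$hmin / 4)))
      p <- (seq_len(m) - 0.5) / m
      w <- dur / m
      for (j in seq_len(m)) {
        mux <- (1 - p[j]) * fx$x_m[i0] + p[j] * fx$x_m[i1]
        muy <- (1 - p[j]) * fx$y_m[i0] + p[j] * fx$y_m[i1]
        sdp <- sqrt(params$hmin^2 + 2 * D * dur * p[j] * (1 - p[j]))
        dens <- add_gaussian(dens, gc$x, gc$y, mux, muy, sdp, w)
        total_w <- total_w + w
      }
    }
  }
  dens <- dens / total_w
  finish_ud(dens, gc$x, gc$y, spec$cell,
            list(D = if (needs_D) D else NA_real_, hmin = params$hmin,
                 kind = "brb"))
}

#' Weighted bivariate-normal fixed-kernel utilization distribution
#'
#' A weight-normalised mixture of isotropic bivariate normal kernels.
#' The default bandwidth is the reference (href) rule adapted to
#' weighted locations: `href = sigma_w * n_eff^(-1/6)` where `sigma_w`
#' pools the weighted x/y standard deviations and
#' `n_eff = (sum w)^2 / sum(w^2)` is the effective sample size (the
#' convention is recorded in the result's `meta`).
#'
#' @param points Data frame with `x_m`, `y_m`.
#' @param weights Non-negative weights, recycled to `nrow(points)`;
#'   rescaling all weights leaves the UD unchanged.
#' @param spec A [grid_spec()]; `NULL` buffers the points by 3x the
#'   bandwidth at 30 m cells.
#' @param h Bandwidth in meters; `NULL` uses the weighted href rule
#'   (an explicit h is required when the points have zero spread).
#' @param cell Cell size (meters) used when `spec` is `NULL`.
#' @return A `ud_grid` with `meta` recording `h`, `href_rule`, `n_eff`.
#' @export
weighted_kernel_ud <- function(points, weights = NULL, spec = NULL, h = NULL,
                               cell = 30) {
  stopifnot(all(c("x_m", "y_m") %in% names(points)), nrow(points) >= 1)
  w <- rep_len(weights %||% 1, nrow(points))
  if (any(w < 0) || sum(w) <= 0) abort("weights must be non-negative with positive sum")
  wn <- w / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  if (is.null(h)) {
    mx <- sum(wn * points$x_m); my <- sum(wn * points$y_m)
    sig <- sqrt((sum(wn * (points$x_m - mx)^2) + sum(wn * (points$y_m - my)^2)) / 2)
    h <- sig * n_eff^(-1 / 6)
    if (!is.finite(h) || h <= 0) {
      abort("href bandwidth degenerate (zero spread); supply h explicitly")
    }
  }
  spec <- spec %||% grid_spec_from_points(points$x_m, points$y_m,
                                          buffer = 3.5 * h, cell = cell)
  gc <- grid_centers(spec)
  dens <- matrix(0, length(gc$x), length(gc$y))
  for (i in seq_len(nrow(points))) {
    if (wn[i] == 0) next
    dens <- add_gaussian(dens, gc$x, gc$y, points$x_m[i], points$y_m[i], h, wn[i])
  }
  finish_ud(dens, gc$x, gc$y, spec$cell,
            list(h = h, href_rule = "weighted sd, n_eff = (sum w)^2 / sum(w^2)",
                 n_eff = n_eff, kind = "kernel"))
}

#' Write a UD grid as an ESRI ASCII raster with a JSON sidecar
#'
#' @param ud A `ud_grid`.
#' @param path Output `.asc` path; the sidecar is `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_ud_asc <- function(ud, path) {
  nx <- length(ud$x); ny <- length(ud$y)
  hdr <- c(
    paste("ncols", nx), paste("nrows", ny),
    paste("xllcorner", ud$x[1] - ud$cell / 2),
    paste("yllcorner", ud$y[1] - ud$cell / 2),
    paste("cellsize", ud$cell), "NODATA_value -9999"
  )
  # rows from top (max y) to bottom
  rows <- vapply(rev(seq_len(ny)), function(j) {
    paste(format(ud$mass[, j], digits = 8), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(ud$meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Heat-map of a utilization distribution
#'
#' @param object A `ud_grid`.
#' @param ... Unused.
#' @return A ggplot raster of probability mass.
#' @method autoplot ud_grid
#' @export
autoplot.ud_grid <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$mass <- as.vector(object$mass)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "mass") +
    ggplot2::theme_minimal()
}
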