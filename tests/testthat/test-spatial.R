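ts0 <- as.POSIXct("2009-07-01 22:00:00", tz = "UTC")

test_that("track segmentation applies the 60-minute and 50-meter rules", {
  fixes <- tibble::tibble(timestamp = ts0 + c(0, 75, 85) * 60,
                          x_m = c(0, 500, 520), y_m = c(0, 0, 0))
  tr <- segment_track(fixes)
  expect_equal(tr$segments$status, c("unusable", "resting"))
  # 10 min apart, 20 m apart -> resting
  fixes2 <- tibble::tibble(timestamp = ts0 + c(0, 10) * 60,
                           x_m = c(0, 20), y_m = c(0, 0))
  expect_equal(segment_track(fixes2)$segments$status, "resting")
  # strictly increasing timestamps enforced
  bad <- tibble::tibble(timestamp = ts0 + c(0, 10, 10) * 60,
                        x_m = 1:3, y_m = 1:3)
  expect_error(segment_track(bad), "strictly increasing")
  expect_error(segment_track(fixes2[1, ]), "at least 2")
})

test_that("plug-in D matches a 1-D grid search of the same likelihood and scales as m^2", {
  tr <- toy_track()
  D <- as.numeric(estimate_diffusion_plugin(tr))
  Dgrid <- gridsearch_D(tr)
  expect_lt(abs(D - Dgrid) / D, 1e-3)
  # doubling coordinates quadruples D
  fx2 <- tr$fixes
  fx2$x_m <- fx2$x_m * 2; fx2$y_m <- fx2$y_m * 2
  D2 <- as.numeric(estimate_diffusion_plugin(segment_track(fx2)))
  expect_equal(D2, 4 * D, tolerance = 1e-12)
  # all segments beyond Tmax -> error
  far <- tibble::tibble(timestamp = ts0 + c(0, 120, 240) * 60,
                        x_m = c(0, 400, 800), y_m = c(0, 0, 0))
  expect_error(estimate_diffusion_plugin(segment_track(far)), "cannot estimate D")
})

test_that("a single resting fix yields a normalized Gaussian kernel at the fix", {
  fix <- tibble::tibble(timestamp = ts0, x_m = 100, y_m = -50)
  ud <- brb_ud(fix, spec = grid_spec(-900, 1100, -1050, 950, cell = 20))
  expect_equal(sum(ud$mass), 1)
  peak <- which(ud$mass == max(ud$mass), arr.ind = TRUE)[1, ]
  expect_lt(abs(ud$x[peak[1]] - 100), 20)
  expect_lt(abs(ud$y[peak[2]] + 50), 20)
  # radially symmetric Gaussian: mass matches dnorm profile at the fix
  r2 <- outer((ud$x - 100)^2, (ud$y + 50)^2, `+`)
  expected <- exp(-r2 / (2 * 88^2))
  expected <- expected / sum(expected)
  expect_lt(0.5 * sum(abs(ud$mass - expected)), 1e-3)
})

test_that("BRB mass collapses toward the straight line as D -> 0", {
  fixes <- tibble::tibble(timestamp = ts0 + c(0, 30) * 60,
                          x_m = c(0, 600), y_m = c(0, 0))
  tr <- segment_track(fixes)
  spec <- grid_spec(-600, 1200, -900, 900, cell = 20)
  ud_small <- brb_ud(tr, spec = spec, D = 1e-6)
  ud_big <- brb_ud(tr, spec = spec, D = 500)
  # mass within 200 m of the y = 0 line
  band <- abs(ud_small$y) <= 200
  expect_gt(sum(ud_small$mass[, band]), 0.95)
  expect_gt(sum(ud_small$mass[, band]), sum(ud_big$mass[, band]))
})

test_that("3-fix toy-track UD matches fine-grid quadrature within 1% total variation", {
  tr <- toy_track()
  D <- 40
  spec <- grid_spec(-800, 1450, -800, 1060, cell = 20)
  ud <- brb_ud(tr, spec = spec, D = D)
  oracle <- quadrature_brb(tr, D, ud$x, ud$y, n_steps = 800)
  expect_tv_less_than(ud$mass, oracle, 0.01)
})

test_that("an all-resting track degenerates to a duration-weighted fixed kernel", {
  fixes <- tibble::tibble(timestamp = ts0 + c(0, 10, 30) * 60,
                          x_m = c(0, 30, 10), y_m = c(0, 10, 40))
  tr <- segment_track(fixes)
  expect_true(all(tr$segments$status == "resting"))
  spec <- grid_spec(-700, 700, -700, 700, cell = 20)
  ud_brb <- brb_ud(tr, spec = spec)
  # per-fix weights: half of each adjacent segment's duration
  w <- c(10 / 2, 10 / 2 + 20 / 2, 20 / 2)
  ud_k <- weighted_kernel_ud(fixes, weights = w, spec = spec, h = 88)
  expect_tv_less_than(ud_brb$mass, ud_k$mass, 1e-9)
})

test_that("weighted kernels normalise weights and honour the closed-form mixture", {
  pt <- tibble::tibble(x_m = 0, y_m = 0)
  ud1 <- weighted_kernel_ud(pt, spec = grid_spec(-500, 500, -500, 500, 25), h = 80)
  expect_equal(sum(ud1$mass), 1)
  # doubling all weights changes nothing
  pts <- tibble::tibble(x_m = c(-1500, 1500), y_m = c(0, 0))
  spec <- grid_spec(-2200, 2200, -700, 700, 25)
  a <- weighted_kernel_ud(pts, weights = c(1, 3), spec = spec, h = 100)
  b <- weighted_kernel_ud(pts, weights = c(2, 6), spec = spec, h = 100)
  expect_equal(a$mass, b$mass)
  # two far-separated points with weights (1, 3): local masses 1/4 and 3/4
  left <- a$x < 0
  expect_equal(sum(a$mass[left, ]), 0.25, tolerance = 0.01)
  expect_equal(sum(a$mass[!left, ]), 0.75, tolerance = 0.01)
  expect_error(weighted_kernel_ud(pts, weights = c(0, 0)), "positive sum")
  expect_error(weighted_kernel_ud(pt, h = NULL), "degenerate")
})

test_that("isopleths take the smallest high-density cell set and report hectares", {
  # uniform UD over a 10 x 10 grid of 1-ha cells
  uni <- as_ud_grid(matrix(1, 10, 10), cell = 100)
  iso <- isopleth(uni, 0.95)
  expect_equal(sum(iso$mask), 95)
  expect_equal(iso$area_ha, 95)
  expect_equal(isopleth(uni, 1.0)$area_ha, 100)
  expect_error(isopleth(uni, 0), "level")
  # isotropic Gaussian: area within 2% of pi sigma^2 chi2_0.95
  sigma <- 500
  g <- weighted_kernel_ud(tibble::tibble(x_m = 0, y_m = 0),
                          spec = grid_spec(-3000, 3000, -3000, 3000, 30),
                          h = sigma)
  area <- isopleth(g, 0.95)$area_ha
  expected <- pi * sigma^2 * stats::qchisq(0.95, 2) / 1e4
  expect_lt(abs(area - expected) / expected, 0.02)
})

test_that("UDOI is symmetric, zero for disjoint UDs and 1 for uniform overlap", {
  uni <- as_ud_grid(matrix(1, 10, 10), cell = 100)
  expect_equal(udoi(uni, uni), 1.0, tolerance = 1e-12)
  m1 <- matrix(0, 10, 10); m1[1:3, ] <- 1
  m2 <- matrix(0, 10, 10); m2[8:10, ] <- 1
  expect_equal(udoi(as_ud_grid(m1, 100), as_ud_grid(m2, 100)), 0)
  # symmetry on smooth UDs
  spec <- grid_spec(-2500, 3100, -2500, 2500, 30)
  ua <- weighted_kernel_ud(tibble::tibble(x_m = 0, y_m = 0), spec = spec, h = 400)
  ub <- weighted_kernel_ud(tibble::tibble(x_m = 600, y_m = 0), spec = spec, h = 400)
  expect_equal(udoi(ua, ub), udoi(ub, ua))
  expect_error(udoi(ua, uni), "common grid")
  # identical concentrated Gaussians: UDOI > 1, matching direct quadrature
  val <- udoi(ua, ua)
  expect_gt(val, 1)
  iso <- isopleth(ua, 0.95)
  da <- ua$mass; da[!iso$mask] <- 0; da <- da / sum(da) / ua$cell^2
  direct <- sum(iso$mask) * ua$cell^2 * sum(da * da) * ua$cell^2
  expect_equal(val, direct, tolerance = 1e-12)
})

test_that("Bhattacharyya affinity matches the Gaussian closed form", {
  spec <- grid_spec(-2600, 3200, -2600, 2600, 30)
  sigma <- 400
  ua <- weighted_kernel_ud(tibble::tibble(x_m = 0, y_m = 0), spec = spec, h = sigma)
  expect_equal(bhattacharyya_affinity(ua, ua), 1, tolerance = 1e-6)
  for (d in c(300, 600, 900)) {
    ub <- weighted_kernel_ud(tibble::tibble(x_m = d, y_m = 0), spec = spec, h = sigma)
    ba <- bhattacharyya_affinity(ua, ub)
    expect_equal(ba, bhattacharyya_affinity(ub, ua))
    expect_lt(abs(ba - exp(-d^2 / (8 * sigma^2))) / exp(-d^2 / (8 * sigma^2)), 0.01)
  }
  m1 <- matrix(0, 6, 6); m1[1:2, ] <- 1
  m2 <- matrix(0, 6, 6); m2[5:6, ] <- 1
  expect_equal(bhattacharyya_affinity(as_ud_grid(m1, 50), as_ud_grid(m2, 50)), 0)
})

test_that("halving the cell size moves smooth-UD statistics by less than 2%", {
  mk <- function(cell) {
    spec <- grid_spec(-2600, 3200, -2600, 2600, cell)
    list(a = weighted_kernel_ud(tibble::tibble(x_m = 0, y_m = 0), spec = spec, h = 400),
         b = weighted_kernel_ud(tibble::tibble(x_m = 500, y_m = 100), spec = spec, h = 400))
  }
  coarse <- mk(60); fine <- mk(30)
  rel <- function(x, y) abs(x - y) / y
  expect_lt(rel(bhattacharyya_affinity(coarse$a, coarse$b),
                bhattacharyya_affinity(fine$a, fine$b)), 0.02)
  expect_lt(rel(udoi(coarse$a, coarse$b), udoi(fine$a, fine$b)), 0.02)
  expect_lt(rel(isopleth(coarse$a)$area_ha, isopleth(fine$a)$area_ha), 0.02)
})

test_that("truncation renormalizes to unit mass", {
  spec <- grid_spec(-2000, 2000, -2000, 2000, 40)
  u <- weighted_kernel_ud(tibble::tibble(x_m = 0, y_m = 0), spec = spec, h = 300)
  expect_equal(sum(truncate_ud(u, 0.95)$mass), 1)
})

test_that("centroids are weighted means with exact translation equivariance", {
  pts <- tibble::tibble(x_m = c(-10, 10, 0), y_m = c(0, 0, 30))
  expect_equal(ud_centroid(pts), c(x = 0, y = 10))
  shifted <- dplyr::mutate(pts, x_m = x_m + 123, y_m = y_m - 45)
  expect_equal(ud_centroid(shifted), c(x = 123, y = -35))
  expect_equal(centroid_shift(ud_centroid(pts), ud_centroid(shifted)),
               sqrt(123^2 + 45^2))
  two <- tibble::tibble(x_m = c(0, 100), y_m = c(0, 0))
  expect_equal(ud_centroid(two, weights = c(1, 3)), c(x = 75, y = 0))
  expect_error(ud_centroid(two, weights = c(0, 0)), "positive sum")
})

test_that("the overlap network uses strict UDOI > threshold on all dyads", {
  uni <- as_ud_grid(matrix(1, 8, 8), cell = 100)
  far1 <- as_ud_grid(rbind(matrix(1, 2, 8), matrix(0, 6, 8)), cell = 100)
  far2 <- as_ud_grid(rbind(matrix(0, 6, 8), matrix(1, 2, 8)), cell = 100)
  # identical uniform UDs have UDOI exactly 1: no edge under strict >
  res <- foraging_overlap_network(list(a = uni, b = uni, c = far1, d = far2))
  expect_equal(igraph::ecount(res$graph), 0)
  expect_equal(res$fraction_over_threshold, 0)
  expect_equal(nrow(res$dyads), choose(4, 2))
  expect_error(foraging_overlap_network(list(a = uni)), "at least 2")
  # 10 bats -> 45 dyads evaluated
  uds10 <- stats::setNames(rep(list(uni), 10), paste0("bat", 1:10))
  expect_equal(nrow(foraging_overlap_network(uds10)$dyads), 45)
})

test_that("UD rasters export as ESRI ASCII with a JSON sidecar", {
  u <- as_ud_grid(matrix(1:12, 3, 4), cell = 30)
  path <- file.path(withr::local_tempdir(), "ud.asc")
  write_ud_asc(u, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ncols 3")
  expect_equal(lines[2], "nrows 4")
  expect_true(file.exists(paste0(path, ".json")))
  vals <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  expect_equal(sum(vals), 1, tolerance = 1e-6)
})
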