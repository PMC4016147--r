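test_that("switch intervals are mean run lengths, split at gaps", {
  rel <- tibble::tibble(bat_id = "b1", date = as.Date("2009-06-01") + 0:3,
                        roost_id = c("r1", "r1", "r2", "r2"))
  s <- roost_switching_stats(rel)
  expect_equal(sort(s$runs$run_days), c(2, 2))
  expect_equal(s$summary$mean_switch_interval_days, 2)

  rel2 <- tibble::tibble(bat_id = "b1", date = as.Date("2009-06-01") + 0:3,
                         roost_id = "r1")
  s2 <- roost_switching_stats(rel2)
  expect_equal(s2$summary$mean_switch_interval_days, 4)
  expect_equal(s2$per_bat$n_roosts, 1)

  # a 3-day tracking gap splits the run even without a roost switch
  rel3 <- tibble::tibble(bat_id = "b1",
                         date = as.Date("2009-06-01") + c(0, 1, 4, 5),
                         roost_id = "r1")
  s3 <- roost_switching_stats(rel3)
  expect_equal(sort(s3$runs$run_days), c(2, 2))

  expect_error(roost_switching_stats(rel[0, ]), "empty")
})

test_that("switch statistics are invariant to bat relabeling and date translation", {
  col <- generate_colony(fast_config(seed = 101))
  rel <- col$relocations
  base <- roost_switching_stats(rel)$summary
  rel2 <- dplyr::mutate(rel, bat_id = paste0("zz_", bat_id), date = date + 365)
  expect_equal(roost_switching_stats(rel2)$summary, base)
})

test_that("per-roost summaries count bats and uses", {
  s <- roost_switching_stats(small_relocations())
  expect_equal(sort(s$per_roost$n_bats), c(2, 3))
  expect_equal(sum(s$per_roost$n_uses), nrow(small_relocations()))
})

test_that("Poisson regression matches an independent Newton oracle", {
  # 8-row toy table
  toy <- tibble::tibble(n_relocs = c(2, 4, 6, 8, 10, 12, 14, 16),
                        n_roosts = c(1, 2, 2, 3, 3, 4, 5, 5))
  fit <- poisson_glm_roosts_vs_relocs(toy)
  oracle <- newton_poisson(toy$n_relocs, toy$n_roosts)
  expect_equal(fit$beta, oracle$beta[2], tolerance = 1e-4)
  expect_equal(glance(fit)$residual_deviance, oracle$deviance, tolerance = 1e-4)
  expect_equal(glance(fit)$null_deviance, oracle$null_deviance, tolerance = 1e-4)

  # 50 random small datasets, slope agreement to 1e-6
  set.seed(40)
  for (rep in 1:50) {
    n <- sample(6:12, 1)
    x <- sample(3:20, n, replace = TRUE)
    y <- pmax(1, rpois(n, exp(0.2 + 0.05 * x)))
    fit_r <- poisson_glm_roosts_vs_relocs(tibble::tibble(n_relocs = x, n_roosts = y))
    orc <- newton_poisson(x, y)
    expect_equal(fit_r$beta, orc$beta[2], tolerance = 1e-6)
  }
})

test_that("deviance explained behaves at its limits and adj D2 <= D2", {
  const <- tibble::tibble(n_relocs = c(3, 6, 9, 12), n_roosts = c(3, 3, 3, 3))
  fit <- poisson_glm_roosts_vs_relocs(const)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$D2, 0, tolerance = 1e-8)

  # exact log-linear counts saturate the fit
  exact <- tibble::tibble(n_relocs = 1:4, n_roosts = c(2, 4, 8, 16))
  fit2 <- poisson_glm_roosts_vs_relocs(exact)
  expect_equal(fit2$D2, 1, tolerance = 1e-8)

  col <- generate_colony(fast_config(seed = 111))
  fit3 <- poisson_glm_roosts_vs_relocs(roost_switching_stats(col$relocations)$per_bat)
  expect_lte(fit3$adj_D2, fit3$D2)
  expect_true(all(c("estimate", "conf_low", "conf_high") %in% names(tidy(fit3))))
  expect_error(poisson_glm_roosts_vs_relocs(const[1:2, ]), "3 bats")
})

test_that("emergence correlation matches the covariance formula and rejects degenerate input", {
  expect_equal(emergence_correlation(1:5, 2 + 3 * (1:5))$r, 1)
  expect_error(emergence_correlation(1:5, rep(4, 5)), "zero variance")
  x <- c(2, 5, 9, 13, 40)
  y <- c(10, 22, 35, 41, 97)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(emergence_correlation(x, y)$r, r_hand)
  expect_error(emergence_correlation(1:2, 1:2), "3 roosts")
})

test_that("roost use and emergence counts join on shared roosts", {
  col <- generate_colony(fast_config(seed = 121))
  ue <- roost_use_vs_emergence(col$relocations, col$exit_counts)
  expect_true(all(ue$roost_id %in% col$relocations$roost_id))
  expect_true(all(ue$roost_id %in% col$exit_counts$roost_id))
  expect_true(all(ue$days_used >= 1))
})
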