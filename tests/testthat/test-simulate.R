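test_that("with all noise off, localizations coincide with the sites", {
  m <- flat_two_layer_model(d = 30, width = 5, density = 50000,
                            length = 5000)
  sites <- sample_sites(m, "A", seed = 2)
  cfg <- noise_off_config(c("A", "B"))
  tab <- simulate_target_round(sites, cfg, 1, fov = c(30000, 30000), seed = 7)
  expect_identical(nrow(tab), nrow(sites))
  expect_equal(tab$x_nm, unname(sites[, 1]))
  expect_equal(tab$y_nm, unname(sites[, 2]))
  expect_true(all(tab$origin_flag == "true_site"))
})

test_that("blink counts follow the configured law", {
  sites <- cbind(stats::runif(200, 0, 5000), stats::runif(200, 0, 5000))
  cfg <- acquisition_config("A", mean_blinks_per_site = 5,
                            blink_count_law = "poisson", false_rate = 0,
                            sigma_loc = 2)
  totals <- vapply(1:200, function(s) {
    tab <- simulate_target_round(sites, cfg, 1, fov = c(6000, 6000), seed = s)
    sum(tab$origin_flag == "true_site")
  }, numeric(1))
  # 200 sites x mean 5 blinks: Poisson with mean 1000
  expect_gte(mean(abs(totals - 1000) <= 3 * sqrt(1000)), 0.97)
  expect_lt(abs(mean(totals) - 1000), 3 * sqrt(1000 / 200))

  cfg_g <- acquisition_config("A", mean_blinks_per_site = 5,
                              blink_count_law = "geometric", false_rate = 0)
  tot_g <- vapply(1:200, function(s) {
    sum(simulate_target_round(sites, cfg_g, 1, fov = c(6000, 6000),
                              seed = s)$origin_flag == "true_site")
  }, numeric(1))
  expect_lt(abs(mean(tot_g) - 1000), 4 * stats::sd(tot_g) / sqrt(200))
})

test_that("carryover rows match the binomial erasure model", {
  prev <- cbind(stats::runif(1000, 0, 6000), stats::runif(1000, 0, 6000))
  cfg <- acquisition_config(c("A", "B"), mean_blinks_per_site = 1,
                            blink_count_law = "fixed", false_rate = 0,
                            erasure_efficiency = 0.9)
  co <- vapply(1:300, function(s) {
    tab <- simulate_target_round(matrix(numeric(0), ncol = 2), cfg, 2,
                                 previous_round_sites = prev,
                                 fov = c(6000, 6000), seed = s)
    sum(tab$origin_flag == "carryover")
  }, numeric(1))
  # Binomial(1000, 0.1): mean 100, sd sqrt(90)
  expect_lt(abs(mean(co) - 100), 3 * sqrt(90 / 300))
  expect_gte(mean(abs(co - 100) <= 3 * sqrt(90)), 0.97)
})

test_that("a round's rigid shift displaces its localizations exactly", {
  m <- flat_two_layer_model(d = 30, width = 5, density = 50000, length = 5000)
  shifts <- rbind(c(0, 0), c(0, 0), c(40, -25))
  cfg <- noise_off_config(c("A", "B", "A2"), round_shifts = shifts)
  # reuse layer A sites under a third round label
  m3 <- golgi_model(m$geometry, list(
    target_layout("A", axial_offset = 0, site_density = 50000),
    target_layout("B", axial_offset = 30, site_density = 50000),
    target_layout("A2", axial_offset = 0, site_density = 50000)), seed = 1)
  ex <- simulate_experiment(m3, cfg, seed = 9)
  sites <- ex$ground_truth$sites$A2
  tab <- ex$tables$A2
  expect_equal(mean(tab$x_nm - sites[, 1]), 40)
  expect_equal(mean(tab$y_nm - sites[, 2]), -25)
  expect_equal(unname(ex$ground_truth$shifts["A2", ]), c(40, -25))
})

test_that("experiments are bit-identical under the same seed", {
  m <- default_golgi_model(seed = 5)
  cfg <- acquisition_config(c("GM130", "Giantin", "VPS13B"))
  e1 <- simulate_experiment(m, cfg, seed = 21)
  e2 <- simulate_experiment(m, cfg, seed = 21)
  expect_identical(e1, e2)
  e3 <- simulate_experiment(m, cfg, seed = 22)
  expect_false(identical(e1$tables$GM130, e3$tables$GM130))
})

test_that("seven non-empty tables come back for a seven-round order", {
  m <- default_golgi_model(seed = 2)
  order7 <- setdiff(names(m$layouts), "VPS13B")
  cfg <- acquisition_config(order7)
  ex <- simulate_experiment(m, cfg, seed = 2)
  expect_length(ex$tables, 7L)
  expect_true(all(vapply(ex$tables, nrow, integer(1)) > 0))
  expect_error(
    simulate_experiment(m, acquisition_config("NotATarget"), seed = 1),
    class = "proximap_config_error")
})

test_that("localization scatter grows strictly with sigma_loc", {
  sites <- cbind(rep(3000, 400), rep(3000, 400))
  vars <- vapply(c(1, 5, 10, 20), function(sg) {
    cfg <- acquisition_config("A", mean_blinks_per_site = 5,
                              blink_count_law = "fixed", sigma_loc = sg,
                              linkage_radius = 0, false_rate = 0)
    tab <- simulate_target_round(sites, cfg, 1, fov = c(6000, 6000), seed = 3)
    stats::var(tab$x_nm)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("origin flags partition synthetic rows and rates are honored", {
  m <- default_golgi_model(seed = 8)
  cfg <- acquisition_config(names(m$layouts))
  ex <- simulate_experiment(m, cfg, seed = 8)
  tab <- ex$tables[[2]]
  expect_true(all(tab$origin_flag %in%
                    c("true_site", "false_positive", "carryover")))
  # expected false localizations per round: false_rate x FOV area
  n_false <- vapply(ex$tables, function(t) sum(t$origin_flag == "false_positive"),
                    numeric(1))
  expect_lt(abs(mean(n_false) - 25 * 36), 0.5 * 25 * 36)
})
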