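test_that("density rendering bins on half-open intervals and conserves counts", {
  tab <- make_table(12, 7)
  g <- render_density(tab, bin_size = 5, extent = c(0, 0, 50, 50))
  expect_identical(g$counts[3, 2], 1L)      # floor(12/5)=2, floor(7/5)=1 (0-based)
  expect_identical(sum(g$counts), 1L)
  expect_identical(g$n_dropped, 0L)

  tab2 <- uniform_table(500, 1000)
  g2 <- render_density(tab2, bin_size = 10, extent = c(0, 0, 1000, 1000))
  expect_identical(sum(g2$counts), 500L)

  g3 <- render_density(make_table(numeric(0), numeric(0)), bin_size = 10,
                       extent = c(0, 0, 100, 100))
  expect_true(all(g3$counts == 0L))
  expect_error(render_density(tab, bin_size = 0),
               class = "proximap_config_error")
  # out-of-extent localizations are dropped and reported
  g4 <- render_density(make_table(c(5, 500), c(5, 5)), bin_size = 10,
                       extent = c(0, 0, 100, 100))
  expect_identical(g4$n_dropped, 1L)
  expect_identical(sum(g4$counts), 1L)
})

test_that("shift estimation honors its sign convention", {
  set.seed(42)
  tab <- uniform_table(3000, 2000)
  ext <- c(0, 0, 2560, 2560)
  ref <- render_density(tab, 10, ext)
  expect_equal(estimate_shift(ref, ref, max_shift = 300)$dx, 0)
  expect_equal(estimate_shift(ref, ref, max_shift = 300)$dy, 0)

  # moving = reference translated by exactly +3 bins in x
  mov <- render_density(translate_tab(tab, 30, 0), 10, ext)
  est <- estimate_shift(ref, mov, max_shift = 300)
  expect_equal(est$dx, -30, tolerance = 1e-6)
  expect_equal(est$dy, 0, tolerance = 1e-6)

  flat <- render_density(make_table(numeric(0), numeric(0)), 10, ext)
  expect_error(estimate_shift(ref, flat, 300), class = "proximap_data_error")
  small <- render_density(tab, 20, ext)
  expect_error(estimate_shift(ref, small, 300),
               class = "proximap_config_error")
})

test_that("sub-bin refinement recovers a non-integer shift within 2.5 nm", {
  m <- default_golgi_model(seed = 31)
  cfg <- acquisition_config("GM130")
  ex <- simulate_experiment(m, cfg, seed = 31)
  tab <- ex$tables$GM130
  expect_gt(nrow(tab), 1e3)
  ext <- c(-600, -600, 6600, 6600)
  ref <- render_density(tab, 5, ext)
  mov <- render_density(translate_tab(tab, 37, -22), 5, ext)
  est <- estimate_shift(ref, mov, max_shift = 200)
  expect_lt(abs(est$dx - (-37)), 2.5)
  expect_lt(abs(est$dy - 22), 2.5)
})

test_that("translation equivariance holds for integer-bin translations", {
  set.seed(7)
  # keep the table away from the extent edges so every tested translation is
  # exact (no localizations clipped)
  tab <- translate_tab(uniform_table(2000, 1200), 400, 400)
  ext <- c(0, 0, 2000, 2000)
  ref <- render_density(tab, 10, ext)
  for (t in list(c(50, 0), c(-120, 80), c(0, -200))) {
    mov <- render_density(translate_tab(tab, t[1], t[2]), 10, ext)
    est <- estimate_shift(ref, mov, max_shift = 400)
    expect_equal(c(est$dx, est$dy), -t, tolerance = 1e-6)
  }
})

test_that("round alignment recovers injected shifts and is idempotent", {
  m <- default_golgi_model(seed = 17)
  ids <- names(m$layouts)
  set.seed(17)
  shifts <- matrix(stats::runif(2 * length(ids), -100, 100), ncol = 2)
  shifts[1, ] <- 0
  cfg <- acquisition_config(ids, round_shifts = shifts)
  ex <- simulate_experiment(m, cfg, seed = 17)
  al <- align_rounds(ex$tables, bin_size = 10, max_shift = 500)
  est <- as.data.frame(al$registration)
  expect_identical(est$dx_nm[1], 0)         # reference estimate exactly zero
  resid <- cbind(est$dx_nm + shifts[, 1], est$dy_nm + shifts[, 2])
  expect_true(all(abs(resid) <= 5))         # bin_size / 2 per axis
  # inputs untouched
  expect_identical(ex$tables[[2]]$x_nm,
                   simulate_experiment(m, cfg, seed = 17)$tables[[2]]$x_nm)
  # idempotence: re-aligning the aligned dataset finds only sub-bin shifts
  al2 <- align_rounds(al$aligned, bin_size = 10, max_shift = 500)
  est2 <- as.data.frame(al2$registration)
  expect_true(all(abs(c(est2$dx_nm, est2$dy_nm)) <= 5))
  expect_error(align_rounds(ex$tables, reference = "Nope"),
               class = "proximap_lookup_error")
})

test_that("zero injected shifts give near-zero estimates", {
  m <- default_golgi_model(seed = 23)
  cfg <- acquisition_config(names(m$layouts))
  ex <- simulate_experiment(m, cfg, seed = 23)
  al <- align_rounds(ex$tables, bin_size = 10)
  est <- as.data.frame(al$registration)
  expect_true(all(abs(c(est$dx_nm, est$dy_nm)) <= 5))
})

test_that("a common rigid translation leaves NN distances unchanged", {
  m <- default_golgi_model(seed = 3)
  cfg <- acquisition_config(c("GM130", "TGN46", "VPS13B"))
  ex <- simulate_experiment(m, cfg, seed = 3)
  pm1 <- proximity_map(ex$tables, min_pair_count = 10)
  moved <- lapply(ex$tables, translate_tab, 123.4, -56.7)
  pm2 <- proximity_map(moved, min_pair_count = 10)
  expect_equal(pm1$median_matrix, pm2$median_matrix, tolerance = 1e-9)
})
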