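test_that("directed NN distances match hand-computable cases", {
  a <- make_table(0, 0, "A")
  b <- make_table(30, 40, "B")
  expect_equal(nn_distances(a, b)$distances, 50)       # 3-4-5 triangle
  far <- make_table(600, 0, "B")
  ds <- nn_distances(a, far, cutoff = 500)
  expect_identical(ds$n_kept, 0L)
  expect_length(ds$distances, 0)
  # identical tables: everything at distance zero
  set.seed(1)
  u <- uniform_table(50, 1000)
  expect_true(all(nn_distances(u, u)$distances == 0))
  # empty target is not an error
  expect_identical(
    nn_distances(u, make_table(numeric(0), numeric(0)))$n_kept, 0L)
  expect_error(nn_distances(a, b, cutoff = -5),
               class = "proximap_config_error")
})

test_that("kd-tree search agrees exactly with exhaustive search", {
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(1:300, 1); n2 <- sample(1:300, 1)
    cutoff <- sample(c(50, 200, 500, 2000), 1)
    s <- cbind(stats::runif(n1, 0, 2000), stats::runif(n1, 0, 2000))
    t <- cbind(stats::runif(n2, 0, 2000), stats::runif(n2, 0, 2000))
    got <- nn_distances(make_table(s[, 1], s[, 2]),
                        make_table(t[, 1], t[, 2]), cutoff)$distances
    want <- brute_nn(s, t, cutoff)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("cutoff is strict and monotone in the retained multiset", {
  src <- make_table(0, 0, "A")
  tgt <- make_table(100, 0, "B")
  # distance exactly at the cutoff is excluded (strictly closer than)
  expect_identical(nn_distances(src, tgt, cutoff = 100)$n_kept, 0L)
  expect_identical(nn_distances(src, tgt, cutoff = 100.001)$n_kept, 1L)
  set.seed(3)
  u1 <- uniform_table(400, 4000, "A")
  u2 <- uniform_table(80, 4000, "B")
  d_small <- nn_distances(u1, u2, cutoff = 150)$distances
  d_big <- nn_distances(u1, u2, cutoff = 500)$distances
  expect_true(all(d_small %in% d_big))
  expect_lte(stats::median(d_small), stats::median(d_big))
})

test_that("adding target points never increases any NN distance", {
  set.seed(8)
  src <- uniform_table(200, 2000, "A")
  tgt <- uniform_table(100, 2000, "B")
  extra <- uniform_table(100, 2000, "B")
  d1 <- RANN::nn2(cbind(tgt$x_nm, tgt$y_nm), cbind(src$x_nm, src$y_nm), 1)$nn.dists[, 1]
  both <- localization_table(c(tgt$x_nm, extra$x_nm), c(tgt$y_nm, extra$y_nm),
                             channel = "B")
  d2 <- RANN::nn2(cbind(both$x_nm, both$y_nm), cbind(src$x_nm, src$y_nm), 1)$nn.dists[, 1]
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("median matrix reproduces a known two-layer separation", {
  m <- flat_two_layer_model(d = 30, width = 0.1, density = 5e5, length = 20000)
  ex <- simulate_experiment(m, noise_off_config(c("A", "B")), seed = 6)
  pm <- proximity_map(ex$tables)
  expect_equal(pm$median_matrix["A", "B"], 30, tolerance = 0.01 * 30)
  expect_equal(pm$median_matrix["B", "A"], 30, tolerance = 0.01 * 30)
  expect_equal(pm$median_matrix["A", "A"], 0)
})

test_that("entries too far or too sparse are reported missing", {
  a <- make_table(stats::runif(200, 0, 500), stats::runif(200, 0, 500), "A")
  b <- make_table(stats::runif(200, 1200, 1500), stats::runif(200, 0, 500), "B")
  pm <- proximity_map(list(A = a, B = b), cutoff = 500)
  expect_true(is.na(pm$median_matrix["A", "B"]))
  # below min_pair_count
  c3 <- make_table(c(0, 10, 20), c(0, 0, 0), "C")
  d3 <- make_table(c(5, 15, 25), c(0, 0, 0), "D")
  pm2 <- proximity_map(list(C = c3, D = d3), min_pair_count = 50)
  expect_true(is.na(pm2$median_matrix["C", "D"]))
  expect_identical(pm2$n_matrix["C", "D"], 3L)
  expect_error(proximity_map(list(A = a)), class = "proximap_config_error")
})

test_that("directed medians differ on an asymmetric-density fixture", {
  set.seed(12)
  dense <- uniform_table(2000, 2000, "dense")
  sparse <- uniform_table(30, 2000, "sparse")
  pm <- proximity_map(list(dense = dense, sparse = sparse),
                      min_pair_count = 10)
  expect_gt(pm$median_matrix["dense", "sparse"],
            5 * pm$median_matrix["sparse", "dense"])
})

test_that("symmetrization pools both directions", {
  set.seed(5)
  a <- uniform_table(300, 1000, "A")
  b <- uniform_table(60, 1000, "B")
  pm_dir <- proximity_map(list(A = a, B = b), min_pair_count = 10)
  pm_sym <- proximity_map(list(A = a, B = b), min_pair_count = 10,
                          symmetrize = TRUE)
  pooled <- c(pm_dir$samples[["A->B"]]$distances,
              pm_dir$samples[["B->A"]]$distances)
  expect_equal(pm_sym$median_matrix["A", "B"], stats::median(pooled))
  expect_identical(pm_sym$median_matrix["A", "B"],
                   pm_sym$median_matrix["B", "A"])
})

test_that("long-format export conserves rows and round-trips the medians", {
  m <- default_golgi_model(seed = 13)
  cfg <- acquisition_config(c("GM130", "Giantin", "VPS13B"))
  ex <- simulate_experiment(m, cfg, seed = 13)
  pm <- proximity_map(ex$tables, min_pair_count = 10)
  long <- as.data.frame(pm)
  expect_identical(nrow(long), sum(vapply(pm$samples, `[[`, integer(1), "n_kept")))
  med_back <- tapply(long$distance_nm,
                     list(long$source_channel, long$target_channel),
                     stats::median)
  for (i in pm$channels) for (j in pm$channels) {
    if (!is.na(pm$median_matrix[i, j])) {
      expect_identical(unname(med_back[i, j]), pm$median_matrix[i, j])
    }
  }
  empty <- proximity_map(list(A = make_table(0, 0, "A"),
                              B = make_table(2000, 0, "B")),
                         cutoff = 500, min_pair_count = 1)
  long0 <- as.data.frame(empty)
  # only the self-pairs survive; cross pairs are empty
  expect_true(all(long0$source_channel == long0$target_channel))
})

test_that("rank_partners orders ascending with alphabetical ties", {
  ch <- c("Q", "A", "B", "Z")
  mm <- matrix(NA_real_, 4, 4, dimnames = list(ch, ch))
  diag(mm) <- 0
  mm["Q", c("A", "B", "Z")] <- c(20, 10, 20)
  pm <- structure(list(channels = ch, median_matrix = mm),
                  class = "proximity_map")
  rk <- rank_partners(pm, "Q")
  expect_identical(rk$target_id, c("B", "A", "Z"))
  expect_identical(rk$median_nm, c(10, 20, 20))
  pm$median_matrix["Q", c("A", "B", "Z")] <- NA
  expect_identical(nrow(rank_partners(pm, "Q")), 0L)
  expect_error(rank_partners(pm, "Nope"), class = "proximap_lookup_error")
})

test_that("source-restricted maps fill only the requested rows", {
  m <- default_golgi_model(seed = 19)
  cfg <- acquisition_config(c("GM130", "Giantin", "VPS13B"))
  ex <- simulate_experiment(m, cfg, seed = 19)
  pm <- proximity_map(ex$tables, sources = "VPS13B", min_pair_count = 10)
  expect_true(all(is.na(pm$median_matrix["GM130", ])))
  expect_false(anyNA(pm$median_matrix["VPS13B", ]))
  full <- proximity_map(ex$tables, min_pair_count = 10)
  expect_equal(pm$median_matrix["VPS13B", ], full$median_matrix["VPS13B", ])
})
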