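make_stats <- function(n, center, mean_dist, sd, n_total = sum(n),
                       global = sum(n * mean_dist) / n_total) {
  structure(
    list(
      table = data.frame(
        cluster = seq_along(n), n = n, center = center,
        mean_dist = mean_dist, sd = sd, split_dim = 1L
      ),
      centers = matrix(center, ncol = 1),
      global_mean_dist = global, n = n_total
    ),
    class = "cluster_stats"
  )
}

test_that("cluster statistics follow the distance-dispersion definitions", {
  # symmetric pair: mean distance 1, population sd 1
  st <- cluster_stats(c(4, 6), matrix(5), c(1L, 1L))
  expect_identical(st$table$mean_dist, 1)
  expect_identical(st$table$sd, 1)

  # all samples on the center: zero dispersion
  st <- cluster_stats(c(7, 7, 7), matrix(7), c(1L, 1L, 1L))
  expect_identical(st$table$mean_dist, 0)
  expect_identical(st$table$sd, 0)

  # global mean distance is the count-weighted mean: (10*1 + 30*2)/40
  x <- c(
    rep(5, 10) + rep(c(-1, 1), 5), # 10 pts at distance 1 from center 5
    rep(50, 30) + rep(c(-2, 2), 15) # 30 pts at distance 2 from center 50
  )
  st <- cluster_stats(x, rbind(5, 50), rep(c(1L, 2L), c(10, 30)))
  expect_equal(st$global_mean_dist, 1.75, tolerance = 1e-12)
  expect_equal(sum(st$table$n), 40L)

  expect_error(
    cluster_stats(c(1, 2), rbind(1, 50), c(1L, 1L)),
    "cluster 2 is empty"
  )
})

test_that("split fires only under all three strict conditions", {
  cfg <- isodata_config(theta_n = 20, theta_S = 5, theta_c = 2)

  # qualifying cluster: center 10, sigma 4 under a looser threshold
  cfg_loose <- isodata_config(theta_n = 1, theta_S = 3)
  ev <- try_split(make_stats(
    n = c(50, 50), center = c(10, 40), mean_dist = c(4, 0.1), sd = c(4, 0.1)
  ), cfg_loose)
  expect_length(ev, 1)
  expect_identical(ev[[1]]$cluster, 1L)
  expect_identical(as.numeric(ev[[1]]$new_centers), c(10 - 0.5 * 4, 10 + 0.5 * 4))
  expect_identical(as.numeric(ev[[1]]$new_centers), c(8, 12))

  # theta_n = 20 demands more than 2*(20+1) = 42 members
  base <- list(center = c(10, 40), mean_dist = c(6, 0.1), sd = c(6, 0.1))
  expect_length(try_split(make_stats(n = c(42, 400), center = base$center,
    mean_dist = base$mean_dist, sd = base$sd
  ), cfg), 0)
  expect_length(try_split(make_stats(n = c(43, 400), center = base$center,
    mean_dist = base$mean_dist, sd = base$sd
  ), cfg), 1)

  # boundary: sigma equal to theta_S does not split
  expect_length(try_split(make_stats(n = c(100, 100), center = c(10, 40),
    mean_dist = c(5, 0.1), sd = c(5, 0.1)
  ), cfg), 0)

  # mean distance must strictly exceed the global mean
  expect_length(try_split(make_stats(n = c(100, 100), center = c(10, 40),
    mean_dist = c(6, 6), sd = c(7, 0.1)
  ), cfg), 0)
})

test_that("merge uses the count-weighted mean, strict threshold, greedy pairs", {
  cfg <- isodata_config(theta_c = 2)
  ev <- try_merge(rbind(5, 6), c(10L, 30L), cfg)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$new_center, (10 * 5 + 30 * 6) / 40, tolerance = 1e-12)
  expect_equal(ev[[1]]$new_center, 5.75)

  # equal counts merge at the midpoint
  ev <- try_merge(rbind(5, 6.5), c(20L, 20L), cfg)
  expect_equal(ev[[1]]$new_center, 5.75, tolerance = 1e-12)

  # distance exactly theta_c: no merge
  expect_length(try_merge(rbind(5, 7), c(10L, 10L), cfg), 0)

  # three mutually close centers: closest pair first, one merge per cluster
  ev <- try_merge(rbind(0, 1, 1.8), c(10L, 10L, 10L), cfg)
  expect_length(ev, 1)
  expect_identical(sort(ev[[1]]$clusters), c(2L, 3L))
})

test_that("hard assignment is nearest-center with low-index ties", {
  expect_identical(hard_assign(c(70, 81), rbind(63, 80)), c(1L, 2L))
  # exactly midway: lower cluster index wins
  expect_identical(hard_assign(c(71.5, 60), rbind(63, 80)), c(1L, 1L))

  x <- withr::with_seed(31, runif(50, 30, 90))
  centers <- c(40, 60, 85)
  expect_identical(hard_assign(x, centers), brute_nearest(x, centers))
})

test_that("three tight layers are recovered without any split or merge", {
  x <- gauss_layers(c(60, 66, 80), sd = 0.3, n_per = 150, seed = 41)
  m <- run_fuzzy_isodata(x, isodata_config())
  expect_identical(nrow(m$centers), 3L)
  expect_true(all(abs(cluster_centers(m) - c(60, 66, 80)) < 0.5))
  expect_length(m$events, 0)
  expect_identical(m$labels, hard_assign(x, m$centers))
})

test_that("two-layer data started at three clusters collapses to two", {
  x <- gauss_layers(c(63, 80), sd = 0.4, n_per = 150, seed = 42)
  m <- run_fuzzy_isodata(x, isodata_config(c_init = 3))
  expect_identical(nrow(m$centers), 2L)
  expect_true(all(abs(cluster_centers(m) - c(63, 80)) < 0.5))
})

test_that("a wide bimodal cluster is split into its two modes", {
  # one over-dispersed bimodal layer plus a tight far layer, c_init = 2
  x <- c(
    gauss_layers(c(55, 68), sd = 1, n_per = 60, seed = 43),
    gauss_layers(85, sd = 0.3, n_per = 100, seed = 44)
  )
  m <- run_fuzzy_isodata(x, isodata_config(c_init = 2))
  expect_identical(nrow(m$centers), 3L)
  expect_true(any(vapply(m$events, `[[`, character(1), "type") == "split"))
  expect_true(all(abs(cluster_centers(m) - c(55, 68, 85)) < 1))
})

test_that("the driver is deterministic and idempotent at its fixed point", {
  x <- gauss_layers(c(60, 66, 80), sd = 0.5, n_per = 80, seed = 45)
  m1 <- run_fuzzy_isodata(x, isodata_config())
  m2 <- run_fuzzy_isodata(x, isodata_config())
  expect_identical(cluster_centers(m1), cluster_centers(m2))
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$events, m2$events)

  # restarting from the converged centers changes nothing
  m3 <- run_fuzzy_isodata(x, isodata_config(), init_centers = m1$centers)
  expect_length(m3$events, 0)
  expect_equal(cluster_centers(m3), cluster_centers(m1), tolerance = 1e-8)
  expect_identical(m3$labels, m1$labels)
})

test_that("model invariants hold across seeded replicates", {
  for (seed in c(7, 19)) {
    x <- gauss_layers(c(58, 70, 80), sd = 0.6, n_per = 60, seed = seed)
    m <- run_fuzzy_isodata(x)
    expect_gte(nrow(m$centers), 2L)
    expect_true(all(tabulate(m$labels, nrow(m$centers)) >= 1))
    expect_true(!is.unsorted(cluster_centers(m)))
    expect_true(all(abs(colSums(m$partition) - 1) <= 1e-9))
  }
})

test_that("too few samples for the initial cluster count is an input error", {
  expect_error(run_fuzzy_isodata(c(60, 70, 80)), "more than c_init")
})
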