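test_that("crisp partitions give per-cluster arithmetic-mean centers", {
  x <- c(60, 62, 64, 80, 81)
  U <- rbind(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1))
  V <- update_centers(x, U, q = 2)
  expect_identical(as.numeric(V), c(62, 80.5))

  # a cluster holding a single sample sits exactly on it
  U1 <- rbind(c(1, 0), c(0, 1))
  expect_identical(as.numeric(update_centers(c(55.5, 70), U1, 2)), c(55.5, 70))
})

test_that("center update matches the weighted-mean formula elementwise", {
  x <- c(1, 2, 3, 4)
  U <- rbind(c(0.9, 0.7, 0.2, 0.1), c(0.1, 0.3, 0.8, 0.9))
  for (q in c(1.5, 2, 3)) {
    expect_equal(
      unname(update_centers(x, U, q)), brute_centers(x, U, q),
      tolerance = 1e-14
    )
  }
})

test_that("a cluster whose membership weights vanish raises a named error", {
  # row sums are positive so the partition is valid, but u^q underflows to 0
  U <- rbind(
    c(1e-200, 1e-200, 1e-200),
    c(0.3, 0.6, 0.5),
    c(0.7, 0.4, 0.5)
  )
  expect_error(update_centers(c(1, 2, 3), U, q = 2), "degenerate cluster 1")
})

test_that("membership updates follow the inverse-squared-distance rule", {
  # equidistant from both centers: symmetric membership
  U <- update_memberships(c(70, 60), rbind(60, 80), 2)
  expect_equal(U[, 1], c(0.5, 0.5))

  # coincident with one of three centers: crisp by the singularity convention
  U <- update_memberships(c(60, 61, 75), rbind(60, 70, 80), 2)
  expect_identical(U[, 1], c(1, 0, 0))

  # coincident with two duplicated centers: uniform over the ties
  U <- update_memberships(c(60, 61, 75), rbind(60, 60, 80), 2)
  expect_identical(U[, 1], c(0.5, 0.5, 0))

  # hand-evaluated value: sample 61, centers {60, 80}, q = 2
  U <- update_memberships(c(61, 70), rbind(60, 80), 2)
  expect_equal(U[1, 1], 361 / 362, tolerance = 1e-15)
  expect_equal(U[2, 1], 1 / 362, tolerance = 1e-15)
})

test_that("membership columns always sum to one", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, runif(50, 30, 90))
    V <- withr::with_seed(seed + 100, matrix(runif(3, 30, 90), ncol = 1))
    U <- update_memberships(x, V, 2)
    expect_true(all(abs(colSums(U) - 1) <= 1e-9))
    expect_true(all(U >= 0 & U <= 1))
  }
})

test_that("objective equals the weighted sum of squared distances", {
  # every sample on its own center, crisp: zero
  expect_identical(
    fcm_objective(c(60, 80), rbind(60, 80), diag(2), 2), 0
  )
  # single pair straddling one center: 1^2 + 1^2
  x <- c(0.5, 2.5)
  U <- rbind(c(1, 1), c(0, 0) + 1e-12)
  U <- sweep(U, 2, colSums(U), "/")
  expect_equal(fcm_objective(x, rbind(1.5, 100), U, 2), 2, tolerance = 1e-6)

  x <- withr::with_seed(11, runif(20, 30, 90))
  U <- random_partition(3, 20, 12)
  V <- withr::with_seed(13, matrix(runif(3, 30, 90), ncol = 1))
  expect_equal(
    fcm_objective(x, V, U, 2), brute_objective(x, V, U, 2),
    tolerance = 1e-12
  )
})

test_that("one full iteration matches independent scalar evaluation", {
  for (seed in 1:4) {
    n <- sample(c(6, 8, 10), 1)
    x <- withr::with_seed(seed, runif(n, 35, 90))
    U0 <- random_partition(3, n, seed + 50)
    for (q in c(2, 2.5)) {
      V <- update_centers(x, U0, q)
      expect_equal(unname(V), brute_centers(x, U0, q), tolerance = 1e-12)
      U1 <- update_memberships(x, V, q)
      expect_equal(unname(unclass(U1)), brute_memberships(x, V, q),
        tolerance = 1e-12
      )
    }
  }
})

test_that("well-separated crisp data is a fixed point reached immediately", {
  x <- c(rep(60, 5), rep(80, 5))
  U0 <- rbind(
    c(rep(1, 5), rep(0, 5)),
    c(rep(0, 5), rep(1, 5))
  )
  st <- fcm_converge(x, U0, epsilon = 1e-4)
  expect_true(st$converged)
  expect_lte(st$iteration, 2)
  expect_identical(as.numeric(st$centers), c(60, 80))
})

test_that("fuzzy c-means recovers three Gaussian layers", {
  x <- gauss_layers(c(60, 66, 80), sd = 0.5, n_per = 100, seed = 21)
  st <- fcm_converge(x, initial_partition(x, 3), epsilon = 1e-4)
  expect_true(st$converged)
  expect_true(all(abs(sort(st$centers[, 1]) - c(60, 66, 80)) < 0.5))
})

test_that("objective is non-increasing along every seeded run", {
  for (seed in c(3, 17, 99)) {
    x <- withr::with_seed(seed, runif(120, 35, 90))
    st <- fcm_converge(
      x, initial_partition(x, 3, method = "random", seed = seed)
    )
    expect_true(all(diff(st$objective_trace) <= 1e-9))
    expect_lte(st$objective, st$objective_trace[1])
  }
})

test_that("hitting the iteration cap warns and flags the state", {
  x <- gauss_layers(c(60, 66, 80), sd = 1, n_per = 40, seed = 4)
  expect_warning(
    st <- fcm_converge(x, initial_partition(x, 3), epsilon = 1e-12,
      max_iter = 2
    ),
    "did not converge"
  )
  expect_false(st$converged)
  expect_identical(st$iteration, 2L)
})

test_that("permuting samples permutes memberships and fixes centers", {
  x <- withr::with_seed(8, runif(40, 35, 90))
  V <- rbind(45, 65, 85)
  U <- update_memberships(x, V, 2)
  perm <- withr::with_seed(9, sample(40))
  Up <- update_memberships(x[perm], V, 2)
  expect_equal(unclass(Up), unclass(U)[, perm], tolerance = 1e-15)
  expect_equal(
    update_centers(x[perm], Up, 2), update_centers(x, U, 2),
    tolerance = 1e-12
  )
})

test_that("partition validation enforces the membership constraints", {
  expect_error(fuzzy_partition(rbind(c(0.6, 0.2), c(0.5, 0.8))), "sum to 1")
  expect_error(fuzzy_partition(rbind(c(1.2, 0), c(-0.2, 1))), "\\[0, 1\\]")
  expect_error(fuzzy_partition(rbind(c(1, 1), c(0, 0))), "strictly in")
})
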