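test_that("next_center follows the stage-update rule", {
  expect_equal(next_center(c(0, 0, 0), c(2, 0, 0), i = 1, n_stages = 21),
               c(0.1, 0, 0))                       # remaining gap / 20
  # fixed point: a mean already at the destination stays there
  expect_equal(next_center(c(2, 0, 0), c(2, 0, 0), i = 5, n_stages = 21),
               c(2, 0, 0))
  # final update lands on the destination bitwise
  dest <- c(1.234567890123, -2.5, 0.1)
  expect_identical(next_center(c(9, 9, 9), dest, i = 20, n_stages = 21), dest)
  expect_error(next_center(c(0, 0, 0), c(1, 0, 0), i = 0, n_stages = 21),
               "outside")
  expect_error(next_center(c(0, 0, 0), c(1, 0, 0), i = 21, n_stages = 21),
               "outside")
})

test_that("schedule endpoint exactness holds on random instances", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    dest <- matrix(rnorm(9, sd = 5), 3, 3)
    centers <- matrix(rnorm(9, sd = 5), 3, 3)
    for (i in seq_len(n - 1)) {
      means <- centers + matrix(rnorm(9, sd = 0.5), 3, 3)  # arbitrary means
      centers <- next_center(means, dest, i, n)
    }
    expect_identical(centers, dest)
  }
})

test_that("contraction identity when means track centers", {
  set.seed(42)
  n <- 21
  dest <- rnorm(3)
  for (i in 1:(n - 1)) {
    m <- rnorm(3, sd = 3)    # mean == current center
    cn <- next_center(m, dest, i, n)
    lhs <- sqrt(sum((cn - dest)^2))
    rhs <- sqrt(sum((m - dest)^2)) * (n - i - 1) / (n - i)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("restraint energy and force match the harmonic form and its gradient", {
  hr <- harmonic_restraint("X", c(1, 2, 3), 500)
  at0 <- restraint_energy_force(c(1, 2, 3), hr)
  expect_equal(at0$U, 0)
  expect_equal(at0$F, c(0, 0, 0))
  # k = 500, |r - r0| = 0.1 => U = 500 * 0.01 / 2 = 2.5 kcal/mol
  expect_equal(restraint_energy_force(c(1.1, 2, 3), hr)$U, 2.5)
  set.seed(43)
  r <- rnorm(3)
  h <- 1e-5
  num <- vapply(1:3, function(j) {
    rp <- r; rm <- r
    rp[j] <- rp[j] + h; rm[j] <- rm[j] - h
    -(restraint_energy_force(rp, hr)$U - restraint_energy_force(rm, hr)$U) / (2 * h)
  }, 0)
  expect_lt(max(abs(restraint_energy_force(r, hr)$F - num)), 1e-4)
  expect_error(harmonic_restraint("X", c(0, 0, 0), -1), "k")
})

test_that("stage work increment equals the brute-force energy difference", {
  expect_equal(stage_work_increment(matrix(1, 2, 3), matrix(1, 2, 3),
                                    matrix(1, 2, 3), 500), 0)
  # single atom sitting at the old center: W = k d^2 / 2
  r <- matrix(c(0, 0, 0), 1, 3)
  new <- matrix(c(0.3, 0, 0), 1, 3)
  expect_equal(stage_work_increment(r, r, new, 500), 500 * 0.09 / 2)
  set.seed(44)
  coords <- matrix(rnorm(15), 5, 3)
  old <- matrix(rnorm(15), 5, 3)
  new <- matrix(rnorm(15), 5, 3)
  k <- 500
  brute <- sum(vapply(1:5, function(i) {
    restraint_energy_force(coords[i, ], harmonic_restraint("a", new[i, ], k))$U -
      restraint_energy_force(coords[i, ], harmonic_restraint("a", old[i, ], k))$U
  }, 0))
  expect_equal(stage_work_increment(coords, old, new, k), brute,
               tolerance = 1e-10)
  # additivity under splitting the atom set
  w_all <- stage_work_increment(coords, old, new, k)
  w_split <- stage_work_increment(coords[1:2, ], old[1:2, ], new[1:2, ], k) +
    stage_work_increment(coords[3:5, ], old[3:5, ], new[3:5, ], k)
  expect_equal(w_all, w_split, tolerance = 1e-10)
  expect_error(stage_work_increment(coords, old[1:3, ], new, k), "mismatch")
})

test_that("schedule construction validates its invariants", {
  dest <- matrix(0, 2, 3)
  expect_error(steering_schedule(c("a", "b"), dest, n_stages = 1,
                                 stage_length = 10), "n_stages")
  expect_error(steering_schedule(c("a", "b"), dest, k_pull = 0,
                                 stage_length = 10), "force constants")
  expect_error(steering_schedule(c("a", "b"), dest, stage_length = 10,
                                 avg_window = 0), "avg_window")
  s <- steering_schedule(c("a", "b"), dest, stage_length = 10)
  expect_equal(s$n_stages, 21L)
  expect_equal(s$k_pull, 500)
  expect_equal(s$k_core, 80)
})

test_that("zero-temperature steering lands on the destination with uniform shifts", {
  # gradient descent on the restraint alone: means track centers, so the
  # center path is linear and each shift is d / (N - 1)
  for (d in c(2.1, 2.9)) {
    pos0 <- matrix(0, 1, 3, dimnames = list("P", NULL))
    backend <- make_descent_backend(pos0, dt = 1e-4)
    sched <- steering_schedule("P", matrix(c(d, 0, 0), 1, 3),
                               n_stages = 21, k_pull = 500,
                               stage_length = 400)
    run <- run_steering(backend, sched, seed = 1)
    expect_identical(run$centers[21, 1, ], c(d, 0, 0))
    expect_lt(max(abs(run$final_coords["P", ] - c(d, 0, 0))), 1e-3)
    shifts <- sqrt(rowSums(apply(run$centers[, 1, ], 2, diff)^2))
    # printed protocol scale: ~0.1-0.15 A per step for a 2-3 A pull
    expect_true(all(shifts > 0.09 & shifts < 0.16))
    expect_equal(mean(shifts), d / 20, tolerance = 1e-3)
    # means coincide with centers once relaxed
    expect_lt(max(abs(run$means[10, 1, ] - run$centers[10, 1, ])), 1e-3)
  }
})

test_that("steering trace bookkeeping is consistent", {
  pos0 <- matrix(0, 1, 3, dimnames = list("P", NULL))
  backend <- make_descent_backend(pos0, dt = 1e-4)
  sched <- steering_schedule("P", matrix(c(1, 0, 0), 1, 3), n_stages = 5,
                             k_pull = 500, stage_length = 200)
  run <- run_steering(backend, sched, seed = 1)
  expect_equal(run$work, sum(run$work_increments))
  expect_equal(nrow(run$trace), 5L)
  expect_equal(run$trace$center_x[run$trace$stage == 5], 1)
  expect_error(run_steering(backend,
                            steering_schedule("Q", matrix(0, 1, 3),
                                              stage_length = 5), seed = 1),
               "does not know")
})

test_that("backend failures propagate with stage context", {
  bad <- list(
    initialize = function(seed) NULL,
    coordinates = function() matrix(0, 1, 3, dimnames = list("P", NULL)),
    step = function(restraints) stop("boom")
  )
  sched <- steering_schedule("P", matrix(c(1, 0, 0), 1, 3), n_stages = 3,
                             stage_length = 2)
  expect_error(run_steering(bad, sched, seed = 1), "stage 1.*boom")
})
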