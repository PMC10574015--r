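test_that("constant trajectory gives zero rmsf; alternating +/-delta gives delta", {
  b <- bundle_fixture()
  traj <- make_jitter_trajectory(b, sigma = 0, n_frames = 5, seed = 1)
  expect_true(all(rmsf_profile(traj)$rmsf == 0))

  # one atom hopping +/- delta along x about its mean
  co <- traj$coords[1:4, , , drop = FALSE]
  delta <- 0.7
  co[c(1, 3), 1, 1] <- co[c(1, 3), 1, 1] + delta
  co[c(2, 4), 1, 1] <- co[c(2, 4), 1, 1] - delta
  t2 <- ca_trajectory(co, traj$labels)
  pr <- rmsf_profile(t2)
  expect_equal(pr$rmsf[1], delta, tolerance = 1e-10)
  expect_true(all(pr$rmsf[-1] == 0))
})

test_that("gaussian jitter recovers sqrt(3)*sigma and the planted profile", {
  b <- bundle_fixture()
  n_ca <- sum(b$atom$elety == "CA")
  sig <- rep(0.5, n_ca)
  sig[1:20] <- 0.1
  traj <- make_jitter_trajectory(b, sigma = sig, n_frames = 1000, seed = 5)
  pr <- rmsf_profile(traj)
  # parameter recovery: rmsf/sqrt(3) ~ sigma within 3 standard errors
  # (se of the rmsf estimate is ~ rmsf/sqrt(2T) per atom)
  se <- sqrt(3) * sig / sqrt(2 * 1000)
  expect_true(all(abs(pr$rmsf - sqrt(3) * sig) < 3 * se + 0.01))
})

test_that("rmsf is invariant under frame permutation", {
  b <- bundle_fixture()
  traj <- make_jitter_trajectory(b, sigma = 0.4, n_frames = 50, seed = 9)
  perm <- sample(50)
  t2 <- ca_trajectory(traj$coords[perm, , , drop = FALSE], traj$labels)
  expect_equal(rmsf_profile(t2)$rmsf, rmsf_profile(traj)$rmsf,
               tolerance = 1e-12)
})

test_that("alignment removes rigid-body motion and is idempotent", {
  set.seed(31)
  b <- bundle_fixture()
  ref <- coords(b)
  t_ <- 12
  co <- array(NA_real_, c(t_, nrow(ref), 3))
  for (i in seq_len(t_)) co[i, , ] <- rigid_motion(ref)
  labels <- data.frame(chain = b$atom$chain, resno = b$atom$resno,
                       elety = b$atom$elety, stringsAsFactors = FALSE)
  traj <- ca_trajectory(co, labels)
  al <- align_trajectory(traj)
  for (i in 2:t_) {
    expect_lt(rmsd(al$coords[i, , ], al$coords[1, , ]), 1e-6)
  }
  expect_true(all(rmsf_profile(al)$rmsf < 1e-6))
  al2 <- align_trajectory(al)
  expect_equal(al2$coords, al$coords, tolerance = 1e-8)

  # identical frames stay put
  same <- ca_trajectory(array(rep(ref, each = 3), c(3, nrow(ref), 3)),
                        labels)
  same$coords[1, , ] <- ref; same$coords[2, , ] <- ref; same$coords[3, , ] <- ref
  expect_equal(align_trajectory(same)$coords, same$coords, tolerance = 1e-8)
})

test_that("alignment can fit on a selection only", {
  b <- bundle_fixture()
  traj <- make_jitter_trajectory(b, sigma = 0.3, n_frames = 20, seed = 2)
  al <- align_trajectory(traj, default_selections()$basement)
  expect_equal(dim(al$coords), dim(traj$coords))
})

test_that("stiff-core detection: uniform profile yields nothing, a plateau is found exactly", {
  prof <- data.frame(chain = "A", resno = 1:100, elety = "CA",
                     rmsf = rep(1, 100), stringsAsFactors = FALSE)
  class(prof) <- c("rmsf_profile", "data.frame")
  expect_equal(nrow(detect_stiff_core(prof)$ranges), 0L)

  prof$rmsf <- 1.5
  prof$rmsf[41:50] <- 0.3
  got <- detect_stiff_core(prof, quantile = 0.25, min_run = 5)
  expect_equal(got$ranges,
               data.frame(chain = "A", start = 41L, end = 50L,
                          stringsAsFactors = FALSE))
  # a run shorter than min_run is suppressed
  prof$rmsf <- 1.5
  prof$rmsf[41:43] <- 0.3
  expect_equal(nrow(detect_stiff_core(prof, min_run = 4)$ranges), 0L)
})

test_that("stiff-core detection recovers generator ground truth on the basement", {
  b <- bundle_fixture()
  ca <- b$atom[b$atom$elety == "CA", ]
  base <- default_selections()$basement
  in_base <- rep(FALSE, nrow(ca))
  for (i in seq_len(nrow(base$ranges))) {
    in_base <- in_base | (ca$resno >= base$ranges$start[i] &
                          ca$resno <= base$ranges$end[i])
  }
  # quantile ~ the planted core fraction (27 of 219 residues) keeps the
  # threshold in the gap between the low and background rmsf clusters
  sig <- ifelse(in_base, 0.1, 0.5)
  traj <- make_jitter_trajectory(b, sigma = sig, n_frames = 400, seed = 17)
  got <- detect_stiff_core(rmsf_profile(traj), quantile = 0.13, min_run = 4)
  expect_equal(got$ranges[order(got$ranges$start), ]$start, base$ranges$start)
  expect_equal(got$ranges[order(got$ranges$start), ]$end, base$ranges$end)
})

test_that("trajectory table and multi-MODEL PDB round trips preserve coordinates", {
  b <- bundle_fixture()
  traj <- make_jitter_trajectory(b, sigma = 0.2, n_frames = 4, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_trajectory_table(traj, f)
  t2 <- read_trajectory_table(f)
  expect_equal(t2$coords, traj$coords, tolerance = 1e-6)
  expect_equal(t2$labels$resno, traj$labels$resno)

  fp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, fp)
  t3 <- read_trajectory_pdb(fp)
  expect_equal(dim(t3$coords), dim(traj$coords))
  expect_lt(max(abs(t3$coords - traj$coords)), 0.001 + 1e-9)
  expect_equal(t3$labels$resno, traj$labels$resno)
})

test_that("degenerate trajectories are refused", {
  b <- bundle_fixture()
  expect_error(make_jitter_trajectory(b, sigma = 0.1, n_frames = 1, seed = 1),
               "n_frames")
  traj <- make_jitter_trajectory(b, sigma = 0.1, n_frames = 3, seed = 1)
  expect_error(ca_trajectory(traj$coords[1, , , drop = FALSE], traj$labels),
               "2 frames")
})
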