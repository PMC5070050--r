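test_that("identical point sets give the identity transform", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.2, 0.9))
  xf <- estimate_rigid_transform(src, src)
  expect_lt(max(abs(xf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(xf$translation)), 1e-9)
})

test_that("a constructed rotation and translation is recovered to 1e-9", {
  theta <- pi / 2
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  t <- c(1, 2, 3)
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 1))
  dst <- sweep(src %*% t(R), 2, t, "+")
  xf <- estimate_rigid_transform(src, dst)
  expect_lt(max(abs(xf$rotation - R)), 1e-9)
  expect_lt(max(abs(xf$translation - t)), 1e-9)

  # property: arbitrary random motions are also recovered exactly
  set.seed(21)
  for (rep in 1:5) {
    Rr <- random_rotation(); tr <- rnorm(3)
    src_r <- matrix(rnorm(24), 8, 3)
    dst_r <- sweep(src_r %*% t(Rr), 2, tr, "+")
    xfr <- estimate_rigid_transform(src_r, dst_r)
    expect_lt(max(abs(xfr$rotation - Rr)), 1e-9)
    expect_lt(max(abs(xfr$translation - tr)), 1e-9)
  }
})

test_that("estimation agrees with a brute-force rotation grid on a 3-point toy", {
  # planar toy: the optimal rotation reduces to one angle about z
  theta_true <- 0.7
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  src <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, -1, 0))
  dst <- sweep(src %*% t(Rz(theta_true)), 2, c(0.2, -0.1, 0.05), "+")
  grid <- seq(0, 2 * pi, by = 1e-4)
  rss <- vapply(grid, function(a) {
    R <- Rz(a)
    tt <- colMeans(dst) - as.numeric(R %*% colMeans(src))
    sum((sweep(src %*% t(R), 2, tt, "+") - dst)^2)
  }, numeric(1))
  best <- grid[which.min(rss)]
  xf <- estimate_rigid_transform(src, dst)
  est_angle <- atan2(xf$rotation[2, 1], xf$rotation[1, 1])
  expect_equal(est_angle, best, tolerance = 1e-3)
  expect_equal(est_angle, theta_true, tolerance = 1e-9)
})

test_that("noisy correspondences fit within 3 sigma RMSD", {
  set.seed(42)
  sigma <- 1e-3
  R <- random_rotation(); t <- c(0.3, -0.2, 0.5)
  src <- matrix(runif(60, -1, 1), 20, 3)
  dst <- sweep(src %*% t(R), 2, t, "+") + matrix(rnorm(60, sd = sigma), 20, 3)
  xf <- estimate_rigid_transform(src, dst)
  fit <- sweep(src %*% t(xf$rotation), 2, xf$translation, "+")
  rmsd <- sqrt(mean(rowSums((fit - dst)^2)))
  expect_lte(rmsd, 3 * sigma)
})

test_that("degenerate geometry is refused", {
  line <- cbind(0:4, 0, 0)
  expect_error(estimate_rigid_transform(line, line), "collinear")
  expect_error(estimate_rigid_transform(line[1:2, ], line[1:2, ]),
               "at least 3")
})

test_that("applying a transform is rigid and invertible", {
  sim <- simulate_dyad(dyad_sim_config(duration = 3, seed = 2))
  st <- sim$recording$infant
  pair_dist <- function(s) {
    ok <- s$joints$head$valid & s$joints$hand_left$valid
    row_norms_test(s$joints$head$positions[ok, ] -
                     s$joints$hand_left$positions[ok, ])
  }
  # identity leaves the stream unchanged
  same <- apply_transform(st, rigid_transform())
  expect_equal(same$joints$head$positions, st$joints$head$positions)

  # pure translation preserves inter-joint distances exactly
  shift <- apply_transform(st, rigid_transform(diag(3), c(1, -2, 0.5)))
  expect_lt(max(abs(pair_dist(shift) - pair_dist(st))), 1e-12)

  # a general motion composed with its inverse is the identity
  set.seed(8)
  xf <- rigid_transform(random_rotation(), rnorm(3))
  back <- apply_transform(apply_transform(st, xf), invert_transform(xf))
  ok <- st$joints$head$valid
  expect_lt(max(abs(back$joints$head$positions[ok, ] -
                      st$joints$head$positions[ok, ])), 1e-9)
  expect_lt(max(abs(pair_dist(apply_transform(st, xf)) - pair_dist(st))), 1e-9)
  # orientations are rotated, not translated: still unit
  expect_equal(row_norms_test(back$head_orientation[st$orientation_valid, ]),
               rep(1, sum(st$orientation_valid)), tolerance = 1e-9)
})

test_that("a shifted impulse yields the exact offset and identical signals lag zero", {
  a <- numeric(60); a[21] <- 1          # impulse at t = 2.0 s at 10 Hz
  b <- numeric(60); b[26] <- 1          # impulse at t = 2.5 s
  ta <- estimate_temporal_offset(a, b, rate = 10, max_lag = 2)
  expect_identical(ta$offset, 0.5)
  expect_equal(ta$confidence, 1, tolerance = 1e-12)

  set.seed(3)
  s <- abs(rnorm(200))
  ta0 <- estimate_temporal_offset(s, s, rate = 10, max_lag = 2)
  expect_identical(ta0$offset, 0)
  expect_equal(ta0$confidence, 1, tolerance = 1e-12)
})

test_that("a sub-sample shift of band-limited noise is recovered to half a sample", {
  set.seed(14)
  fine_rate <- 1000; rate <- 100
  x <- stats::filter(rnorm(12 * fine_rate), rep(1 / 25, 25), sides = 2)
  x[is.na(x)] <- 0
  shift_fine <- 123                      # 0.123 s at the fine rate
  dec <- seq(1, 10 * fine_rate, by = fine_rate / rate)
  a <- x[dec + fine_rate]
  b <- x[dec + fine_rate - shift_fine]
  ta <- estimate_temporal_offset(a, b, rate = rate, max_lag = 1)
  expect_lte(abs(ta$offset - 0.123), 0.5 / rate)
})

test_that("flat signals are rejected", {
  expect_error(estimate_temporal_offset(rep(1, 100), rnorm(100), 10, 2),
               "flat")
})

test_that("aligning an already-aligned dyad reproduces it", {
  sim <- simulate_dyad(dyad_sim_config(duration = 5, dropout_prob = 0, seed = 9))
  rec <- sim$recording
  re <- align_dyad(rec$mother, rec$infant, rate = rec$rate)
  expect_equal(re$mother$timestamps, rec$mother$timestamps, tolerance = 1e-9)
  expect_lt(max(abs(re$infant$joints$head$positions -
                      rec$infant$joints$head$positions)), 1e-9)
})

test_that("a dyad split across frames and clocks realigns to within 1 mm", {
  sim <- simulate_dyad(dyad_sim_config(duration = 20, dropout_prob = 0,
                                       seed = 31))
  rec <- sim$recording
  set.seed(6)
  xf <- rigid_transform(random_rotation(), c(0.4, -0.3, 0.2))
  raw <- desync_dyad(rec, xf, offset = 0.5)   # 15 frames at 30 Hz
  xf_hat <- estimate_rigid_transform(raw$calibration$src, raw$calibration$dst)
  ta_hat <- estimate_temporal_offset(raw$sync_mother$samples,
                                     raw$sync_infant$samples,
                                     raw$sync_mother$rate, max_lag = 2)
  expect_lt(abs(ta_hat$offset - 0.5), 1e-3)
  re <- align_dyad(raw$mother, raw$infant, xf_hat, ta_hat, rate = rec$rate)
  idx <- match(round(re$mother$timestamps, 6), round(rec$mother$timestamps, 6))
  expect_false(anyNA(idx))
  err <- row_norms_test(re$infant$joints$head$positions -
                          rec$infant$joints$head$positions[idx, ])
  expect_lt(max(err), 1e-3)
})

test_that("an offset beyond the session length cannot be aligned", {
  sim <- simulate_dyad(dyad_sim_config(duration = 4, seed = 1))
  rec <- sim$recording
  expect_error(align_dyad(rec$mother, rec$infant, ta = 100, rate = 30),
               "overlap")
})
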