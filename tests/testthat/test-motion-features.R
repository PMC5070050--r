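test_that("quantity of movement matches hand-computed speeds", {
  t <- (0:9) / 10
  # one joint advancing 0.1 m per frame at 10 Hz -> 1.0 m/s
  head <- cbind(seq(0, 0.9, by = 0.1), 0, 0)
  st <- toy_stream(list(head = head), t)
  q <- quantity_of_movement(st, "head")
  expect_equal(q$qom[-1], rep(1, 9))
  expect_false(q$valid[1])

  # two joints moving 0.05 and 0.10 m per frame -> 0.5 + 1.0 = 1.5 m/s
  st2 <- toy_stream(list(head = cbind(seq(0, 0.45, by = 0.05), 0, 0),
                         hand_left = cbind(0, seq(0, 0.9, by = 0.1), 0)), t)
  q2 <- quantity_of_movement(st2, c("head", "hand_left"))
  expect_equal(q2$qom[-1], rep(1.5, 9))

  # stationary skeleton -> identically zero
  q0 <- quantity_of_movement(toy_stream(list(head = matrix(0.3, 10, 3)), t))
  expect_equal(q0$qom[-1], rep(0, 9))

  expect_error(quantity_of_movement(st, c("head", "hand_right")), "hand_right")
})

test_that("frames adjacent to tracking losses have no quantity of movement", {
  t <- (0:5) / 10
  st <- toy_stream(list(head = cbind(seq(0, 0.5, by = 0.1), 0, 0)), t)
  st$joints$head$valid[3] <- FALSE
  q <- quantity_of_movement(st, "head")
  expect_equal(q$valid, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(q$qom[!q$valid])))
})

test_that("activity detection thresholds and duration-filters the state", {
  a <- detect_activity(c(0, 0, 1, 1, 0, 1, 0, 0, 0, 0), threshold = 0.1,
                       min_duration = 0, rate = 1)
  expect_equal(mean(a$moving), 0.3)

  # a single-frame spike dies under a 0.2 s minimum at 30 Hz
  spike <- numeric(30); spike[15] <- 1
  a2 <- detect_activity(spike, threshold = 0.1, min_duration = 0.2, rate = 30)
  expect_true(all(!a2$moving))

  # alternation faster than the minimum collapses to sustained movement
  # (closing fills interior gaps only, so end the trace on a moving frame)
  alt <- rep(c(1, 0), 30)[1:59]
  a3 <- detect_activity(alt, threshold = 0.1, min_duration = 0.2, rate = 30)
  expect_true(all(a3$moving))

  expect_error(detect_activity(alt, threshold = 0, rate = 30), "threshold")
})

test_that("activity ratio counts moving frames among valid ones", {
  expect_equal(activity_ratio(toy_activity(c(1, 1, 1, 1))), 1)
  expect_equal(activity_ratio(toy_activity(c(0, 0, 0, 0))), 0)
  expect_equal(activity_ratio(toy_activity(c(1, 1, 0, 0, 1))), 0.6)
  act <- toy_activity(c(1, 0, 1), valid = c(FALSE, FALSE, FALSE))
  expect_error(activity_ratio(act), "valid")
})

test_that("inter-head distance matches per-frame norms", {
  d <- heads_distance(static_dyad(mother_at = c(0, 0, 0),
                                  infant_at = c(1, 0, 0)))
  expect_equal(unique(d), 1)

  # identical translation of both heads changes nothing
  d2 <- heads_distance(static_dyad(mother_at = c(5, 5, 5),
                                   infant_at = c(6, 5, 5)))
  expect_equal(d2, d)

  # random trajectories against a brute-force per-frame norm
  set.seed(77)
  t <- (0:49) / 10
  hm <- matrix(rnorm(150), 50, 3); hi <- matrix(rnorm(150), 50, 3)
  dy <- dyad_recording(toy_stream(list(head = hm), t, partner = "mother"),
                       toy_stream(list(head = hi), t, partner = "infant"), 10)
  brute <- vapply(1:50, function(k) sqrt(sum((hm[k, ] - hi[k, ])^2)),
                  numeric(1))
  expect_equal(heads_distance(dy), brute, tolerance = 1e-12)
})

test_that("heads-distance contributions identify the mover and split symmetric motion", {
  t <- (0:9) / 10
  # mother recedes along the inter-head axis; infant static -> (1, 0)
  hm <- cbind(0, seq(1, 1.9, by = 0.1), 0)
  hi <- matrix(rep(c(0, 0, 0), each = 10), 10, 3)
  dy <- dyad_recording(toy_stream(list(head = hm), t, partner = "mother"),
                       toy_stream(list(head = hi), t, partner = "infant"), 10)
  ctr <- heads_distance_contributions(dy)
  expect_equal(ctr$mother_share, 1)
  expect_equal(ctr$infant_share, 0)

  # mirror-symmetric equal motion -> (0.5, 0.5)
  hm2 <- cbind(0, seq(1, 1.9, by = 0.1), 0)
  hi2 <- cbind(0, -seq(1, 1.9, by = 0.1), 0)
  dy2 <- dyad_recording(toy_stream(list(head = hm2), t, partner = "mother"),
                        toy_stream(list(head = hi2), t, partner = "infant"), 10)
  ctr2 <- heads_distance_contributions(dy2)
  expect_equal(ctr2$mother_share, 0.5)
  expect_equal(ctr2$infant_share, 0.5)

  # both static -> (0.5, 0.5) by convention
  ctr3 <- heads_distance_contributions(static_dyad())
  expect_equal(ctr3$mother_share, 0.5)
})

test_that("per-frame contributions sum to the distance change to first order", {
  set.seed(12)
  t <- (0:199) / 10
  step <- 1e-3
  hm <- sweep(apply(matrix(rnorm(600, sd = step), 200, 3), 2, cumsum),
              2, c(0, 1, 0), "+")
  hi <- apply(matrix(rnorm(600, sd = step), 200, 3), 2, cumsum)
  dy <- dyad_recording(toy_stream(list(head = hm), t, partner = "mother"),
                       toy_stream(list(head = hi), t, partner = "infant"), 10)
  ctr <- heads_distance_contributions(dy)
  dd <- diff(heads_distance(dy))
  resid <- (ctr$c_mother + ctr$c_infant)[-1] - dd
  expect_lt(max(abs(resid)), 50 * step^2)   # O(step^2) decomposition error
})

test_that("face-to-face counting respects the mutual-gaze cone", {
  expect_equal(face_to_face_ratio(static_dyad()), 1)

  # mother looking away -> never face to face
  t <- seq(0, 1, by = 0.1)
  m <- static_stream(c(0, -0.5, 0.5), t, "mother", facing = c(0, -1, 0))
  i <- static_stream(c(0, 0.5, 0.5), t, "infant", facing = c(0, -1, 0))
  expect_equal(face_to_face_ratio(dyad_recording(m, i, 10)), 0)

  # 20 degrees off with a 30 degree threshold still counts
  a <- 20 * pi / 180
  m2 <- static_stream(c(0, -0.5, 0.5), t, "mother",
                      facing = c(sin(a), cos(a), 0))
  i2 <- static_stream(c(0, 0.5, 0.5), t, "infant", facing = c(0, -1, 0))
  expect_equal(face_to_face_ratio(dyad_recording(m2, i2, 10), 30), 1)
  expect_equal(face_to_face_ratio(dyad_recording(m2, i2, 10), 15), 0)
})

test_that("task orientation ratio counts frames gazing at the task point", {
  t <- seq(0, 1, by = 0.1)
  at_task <- static_stream(c(0, -0.5, 0.5), t, "mother",
                           facing = c(0, 0.5, -0.5))
  expect_equal(task_orientation_ratio(at_task, c(0, 0, 0)), 1)
  away <- static_stream(c(0, -0.5, 0.5), t, "mother", facing = c(0, -1, 0))
  expect_equal(task_orientation_ratio(away, c(0, 0, 0)), 0)

  # half the frames on task, half away -> 0.5
  T <- length(t)
  ori <- rbind(matrix(rep(c(0, 1, 0), each = 6), 6, 3),
               matrix(rep(c(0, -1, 0), each = 5), 5, 3))
  st <- toy_stream(list(head = matrix(rep(c(0, -0.5, 0), each = T), T, 3)),
                   t, orientation = ori)
  expect_equal(task_orientation_ratio(st, c(0, 0.5, 0)), 6 / 11)
})

test_that("synchrony ratio counts answered leader onsets inside the window", {
  rate <- 10; T <- 120
  mk <- function(onsets) {
    mv <- logical(T)
    for (o in onsets) mv[(o * rate + 1):(o * rate + 5)] <- TRUE
    toy_activity(mv, rate = rate)
  }
  infant <- mk(c(1, 5)); parent <- mk(c(1.5, 9))
  expect_equal(synchrony_ratio(infant, parent, window = 2), 0.5)
  # responder without onsets -> 0; leader without onsets -> undefined
  expect_equal(synchrony_ratio(infant, toy_activity(logical(T), rate = rate),
                               window = 2), 0)
  expect_true(is.na(synchrony_ratio(toy_activity(logical(T), rate = rate),
                                    parent, window = 2)))
  expect_error(synchrony_ratio(infant, toy_activity(logical(10)), 2),
               "length")
})

test_that("uncoupled Poisson responders match the analytic null rate", {
  set.seed(40)
  rate <- 10; dur <- 300; window <- 1; lam_l <- 0.08; lam_r <- 0.2
  res <- replicate(40, {
    mk <- function(lam) {
      onsets <- cumsum(rexp(dur * lam * 3, lam))
      onsets <- onsets[onsets < dur - 1]
      mv <- logical(dur * rate)
      idx <- round(onsets * rate) + 1
      for (o in idx) mv[o:(o + 2)] <- TRUE
      toy_activity(mv, rate = rate)
    }
    leader <- mk(lam_l); resp <- mk(lam_r)
    # the analytic null uses the realized responder onset rate (bout
    # collisions make it slightly lower than the generating rate)
    n_on <- sum(diff(resp$moving) == 1) + resp$moving[1]
    c(synchrony_ratio(leader, resp, window = window), n_on / dur)
  })
  lam_hat <- mean(res[2, ])
  expect_lt(abs(mean(res[1, ], na.rm = TRUE) - (1 - exp(-lam_hat * window))),
            0.03)
})

test_that("overlap and pause ratios partition joint time with discordance", {
  a <- toy_activity(c(1, 1, 0, 0, 1)); b <- toy_activity(c(1, 0, 0, 1, 1))
  expect_equal(overlap_ratio(a, b), 0.4)
  expect_equal(pause_ratio(a, b), 0.2)
  # disjoint activity overlaps nowhere; ceaseless activity never pauses
  expect_equal(overlap_ratio(toy_activity(c(1, 0)), toy_activity(c(0, 1))), 0)
  expect_equal(pause_ratio(toy_activity(c(1, 1)), toy_activity(c(1, 1))), 0)
  # identical series: overlap equals the activity ratio
  set.seed(2)
  r <- toy_activity(runif(200) < 0.3)
  expect_equal(overlap_ratio(r, r), activity_ratio(r))
  # partition: overlap + pause + discordant = 1 on random series
  for (k in 1:10) {
    x <- toy_activity(runif(50) < 0.5); y <- toy_activity(runif(50) < 0.5)
    disc <- mean(xor(x$moving, y$moving))
    expect_equal(overlap_ratio(x, y) + pause_ratio(x, y) + disc, 1)
  }
})

test_that("a fully static dyad yields the degenerate feature vector", {
  dy <- static_dyad(duration = 5, rate = 10)
  fv <- extract_feature_vector(dy)
  expect_identical(names(fv), feature_names())
  expect_equal(unname(fv["mother_qom_mean"]), 0)
  expect_equal(unname(fv["infant_qom_mean"]), 0)
  expect_equal(unname(fv["mother_activity_ratio"]), 0)
  expect_equal(unname(fv["overlap_ratio"]), 0)
  expect_equal(unname(fv["pause_ratio"]), 1)
  expect_equal(unname(fv["mother_heads_contribution"]), 0.5)
  expect_true(is.na(fv["sync_parent_to_infant"]))
})

test_that("features are invariant under a common rigid motion and time shift", {
  sim <- simulate_dyad(dyad_sim_config(duration = 20, seed = 17))
  rec <- sim$recording
  cfg <- extraction_config()
  fv <- extract_feature_vector(rec, cfg)
  set.seed(4)
  xf <- rigid_transform(random_rotation(), rnorm(3))
  shifted <- dyad_recording(apply_transform(rec$mother, xf),
                            apply_transform(rec$infant, xf), rec$rate)
  shifted$mother$timestamps <- shifted$mother$timestamps + 100
  shifted$infant$timestamps <- shifted$infant$timestamps + 100
  # the task point moves with the frame
  cfg2 <- extraction_config(task_point = as.numeric(
    xf$rotation %*% cfg$task_point + xf$translation))
  fv2 <- extract_feature_vector(shifted, cfg2)
  expect_equal(as.numeric(fv2), as.numeric(fv), tolerance = 1e-9)
})

test_that("ratio features always lie in the unit interval", {
  for (s in c(5, 23)) {
    fv <- extract_feature_vector(
      simulate_dyad(dyad_sim_config(duration = 30, seed = s))$recording)
    ratios <- fv[c("mother_activity_ratio", "infant_activity_ratio",
                   "mother_heads_contribution", "infant_heads_contribution",
                   "face_to_face_ratio", "mother_task_ratio",
                   "infant_task_ratio", "sync_parent_to_infant",
                   "sync_infant_to_parent", "overlap_ratio", "pause_ratio")]
    ratios <- ratios[!is.na(ratios)]
    expect_true(all(ratios >= 0 & ratios <= 1))
    expect_lte(fv["overlap_ratio"] + fv["pause_ratio"], 1)
    expect_equal(unname(fv["mother_heads_contribution"] +
                          fv["infant_heads_contribution"]), 1)
  }
})
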