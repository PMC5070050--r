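#' Configuration for the synthetic dyad generator
#'
#' Describes one simulated 4-minute tabletop play session. Each partner's
#' moving/still state follows a continuous-time two-state Markov chain
#' (discretized at the frame rate) with stationary moving probability
#' `on_rate / (on_rate + off_rate)`; while moving, the head and both hands
#' follow smoothed random walks at the speed scale, while still they only
#' show tracker jitter. Each infant movement onset triggers a mother response
#' onset with probability `p_resp` after a lag drawn uniformly from
#' `(0, response_window]`. Head orientations alternate between the partner,
#' the task location and elsewhere according to the gaze probabilities, with
#' bout-like persistence. Frames are dropped (skeleton untracked) with the
#' dropout probability, independently per partner.
#'
#' @param duration session length in seconds (default 240, a 4-minute play
#'   session).
#' @param rate frame rate in Hz (default 30, sensor native).
#' @param mother_on_rate,mother_off_rate,infant_on_rate,infant_off_rate
#'   Markov switching rates in 1/s (still-to-moving and moving-to-still).
#' @param speed_scale per-hand speed while moving, m/s (the head moves at
#'   0.3x this scale; summed head+hands quantity of movement is therefore
#'   about `2.3 * speed_scale`).
#' @param p_resp probability that an infant movement onset triggers a mother
#'   response onset.
#' @param response_window response-lag upper bound in seconds (lags are
#'   uniform on `(0, response_window]`).
#' @param mother_face_prob,infant_face_prob stationary probability of gazing
#'   at the partner.
#' @param mother_task_prob,infant_task_prob stationary probability of gazing
#'   at the task location.
#' @param dropout_prob per-frame skeleton dropout probability.
#' @param noise_sd tracker jitter standard deviation per axis, metres.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(duration = 240, rate = 30,
                            mother_on_rate = 1 / 3, mother_off_rate = 0.5,
                            infant_on_rate = 0.5, infant_off_rate = 0.6,
                            speed_scale = 0.2,
                            p_resp = 0.3, response_window = 3,
                            mother_face_prob = 0.5, infant_face_prob = 0.4,
                            mother_task_prob = 0.35, infant_task_prob = 0.45,
                            dropout_prob = 0.02, noise_sd = 2e-4,
                            seed = NULL) {
  cfg <- list(duration = duration, rate = rate,
              mother_on_rate = mother_on_rate,
              mother_off_rate = mother_off_rate,
              infant_on_rate = infant_on_rate,
              infant_off_rate = infant_off_rate,
              speed_scale = speed_scale, p_resp = p_resp,
              response_window = response_window,
              mother_face_prob = mother_face_prob,
              infant_face_prob = infant_face_prob,
              mother_task_prob = mother_task_prob,
              infant_task_prob = infant_task_prob,
              dropout_prob = dropout_prob, noise_sd = noise_sd, seed = seed)
  probs <- c(p_resp, mother_face_prob, infant_face_prob, mother_task_prob,
             infant_task_prob, dropout_prob)
  stopifnot(duration > 0, rate > 0, duration * rate >= 2,
            mother_on_rate > 0, mother_off_rate > 0,
            infant_on_rate > 0, infant_off_rate > 0,
            speed_scale >= 0, response_window > 0, noise_sd >= 0,
            all(probs >= 0 & probs <= 1),
            mother_face_prob + mother_task_prob <= 1,
              infant_face_prob + infant_task_prob <= 1)
  structure(cfg, class = "dyad_sim_config")
}

#' Group presets emulating low-risk and high-risk dyads
#'
#' Parameter presets whose contrast mirrors the direction of the reported
#' group differences: high-risk (neglect) dyads have a markedly more active,
#' more response-prone mother, fewer joint pauses and less face-to-face and
#' task-directed gaze than low-risk (control) dyads.
#'
#' @param ... overrides passed on to [dyad_sim_config()].
#' @return A [dyad_sim_config()].
#' @export
config_low_risk <- function(...) {
  defaults <- list(mother_on_rate = 0.25, mother_off_rate = 0.6,
                   infant_on_rate = 0.5, infant_off_rate = 0.6,
                   p_resp = 0.2,
                   mother_face_prob = 0.6, infant_face_prob = 0.5,
                   mother_task_prob = 0.35, infant_task_prob = 0.45)
  do.call(dyad_sim_config, modifyList(defaults, list(...)))
}

#' @rdname config_low_risk
#' @export
config_high_risk <- function(...) {
  defaults <- list(mother_on_rate = 0.9, mother_off_rate = 0.35,
                   infant_on_rate = 0.5, infant_off_rate = 0.6,
                   p_resp = 0.8,
                   mother_face_prob = 0.3, infant_face_prob = 0.25,
                   mother_task_prob = 0.15, infant_task_prob = 0.3)
  do.call(dyad_sim_config, modifyList(defaults, list(...)))
}

# resting skeleton geometry (metres): table centre at the origin, partners
# seated across it, z up
scene_geometry <- function() {
  list(task_point = c(0, 0, 0),
       mother = list(head = c(0, -0.40, 0.50),
                     hand_left = c(-0.15, -0.25, 0.08),
                     hand_right = c(0.15, -0.25, 0.08)),
       infant = list(head = c(0, 0.40, 0.35),
                     hand_left = c(0.12, 0.25, 0.06),
                     hand_right = c(-0.12, 0.25, 0.06)))
}

# discrete two-state Markov chain; returns logical vector of length T
sim_markov_state <- function(T, on_rate, off_rate, rate) {
  p_on <- min(1, on_rate / rate)
  p_off <- min(1, off_rate / rate)
  p_stat <- on_rate / (on_rate + off_rate)
  state <- logical(T)
  state[1L] <- runif(1) < p_stat
  u <- runif(T)
  for (i in 2:T)
    state[i] <- if (state[i - 1L]) u[i] >= p_off else u[i] < p_on
  state
}

rising_edges <- function(state) which(state[-1L] & !state[-length(state)]) + 1L

# smoothed random walk for one joint: while moving, constant speed with an
# AR(1)-smoothed heading that is steered back toward the base position as the
# joint leaves its reach radius (so speed never stalls and the joint stays
# near the table); while still, frozen apart from tracker jitter
sim_joint_path <- function(T, base, moving, speed, rate, noise_sd,
                           radius = 0.15, rho = 0.9) {
  v <- vapply(1:3, function(a)
    as.numeric(filter(rnorm(T), rho, method = "recursive")), numeric(T))
  dir <- normalize_rows(v)
  bad <- !is.finite(dir[, 1L])
  if (any(bad)) dir[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
  jitter <- matrix(rnorm(3L * T, sd = noise_sd), T, 3L)
  step_len <- speed / rate
  pos <- matrix(0, T, 3L)
  pos[1L, ] <- base + jitter[1L, ]
  for (i in 2:T) {
    p <- pos[i - 1L, ] + jitter[i, ]
    if (moving[i] && step_len > 0) {
      to_base <- base - pos[i - 1L, ]
      d2 <- sum(to_base * to_base)
      h <- dir[i, ] + to_base * (d2 / radius^2) / sqrt(d2 + 1e-12)
      h <- h / sqrt(sum(h * h))
      p <- p + h * step_len
    }
    pos[i, ] <- p
  }
  pos
}

# persistent gaze-state chain: 1 = partner, 2 = task, 3 = elsewhere
sim_gaze_states <- function(T, face_prob, task_prob, switch_prob = 0.02) {
  probs <- c(face_prob, task_prob, max(0, 1 - face_prob - task_prob))
  draw <- function(n) sample.int(3L, n, replace = TRUE, prob = probs)
  state <- integer(T)
  state[1L] <- draw(1L)
  switches <- runif(T) < switch_prob
  for (i in 2:T) state[i] <- if (switches[i]) draw(1L) else state[i - 1L]
  state
}

# unit vector at least `min_deg` away from every row-direction in `avoid`
random_away_direction <- function(avoid, min_deg = 45) {
  repeat {
    d <- rnorm(3L)
    d <- d / sqrt(sum(d * d))
    ang <- apply(avoid, 1L, function(a) sum(a * d))
    if (all(ang < cos(min_deg * pi / 180))) return(d)
  }
}

#' Simulate one dyadic play session with known ground truth
#'
#' Generates a spatio-temporally aligned [dyad_recording()] (common frame,
#' uniform 30 Hz grid by default) plus the ground truth that produced it, for
#' parameter-recovery testing: true per-frame moving states, true onset
#' times, realized mother response events, and the stationary activity
#' probabilities. Fully reproducible from `config$seed`.
#'
#' @param config a [dyad_sim_config()].
#' @return list with `recording` (a [dyad_recording()]) and `truth` (list:
#'   `mother_moving`, `infant_moving`, `mother_onsets`, `infant_onsets`,
#'   `responses` data.frame, `p_active_mother`, `p_active_infant`,
#'   `gaze_mother`, `gaze_infant`, `config`).
#' @export
simulate_dyad <- function(config = dyad_sim_config()) {
  stopifnot(inherits(config, "dyad_sim_config"))
  with_seed(config$seed, {
    rate <- config$rate
    T <- as.integer(round(config$duration * rate)) + 1L
    t <- (seq_len(T) - 1L) / rate
    geom <- scene_geometry()

    infant_state <- sim_markov_state(T, config$infant_on_rate,
                                     config$infant_off_rate, rate)
    mother_state <- sim_markov_state(T, config$mother_on_rate,
                                     config$mother_off_rate, rate)
    # superimpose the response hazard: infant onsets recruit mother onsets
    infant_onset_idx <- rising_edges(infant_state)
    n_on <- length(infant_onset_idx)
    responses <- data.frame(onset_time = t[infant_onset_idx],
                            responded = logical(n_on),
                            lag = rep(NA_real_, n_on))
    if (nrow(responses)) {
      fire <- runif(nrow(responses)) < config$p_resp
      gap <- as.integer(ceiling(0.25 * rate)) + 2L   # still gap so the
      for (r in which(fire)) {                       # response is a real onset
        lag <- runif(1, 0, config$response_window)
        j <- infant_onset_idx[r] + as.integer(ceiling(lag * rate))
        if (j + 1L > T) next
        bout <- 1L + stats::rgeom(1L, min(1, config$mother_off_rate / rate))
        if (mother_state[j - 1L])
          mother_state[max(1L, j - gap):(j - 1L)] <- FALSE
        mother_state[j:min(T, j + max(bout, gap) - 1L)] <- TRUE
        responses$responded[r] <- TRUE
        responses$lag[r] <- lag
      }
    }

    make_stream <- function(partner, state, other_base_head) {
      b <- geom[[partner]]
      speed <- config$speed_scale
      paths <- list(
        head = sim_joint_path(T, b$head, state, 0.3 * speed, rate,
                              config$noise_sd),
        hand_left = sim_joint_path(T, b$hand_left, state, speed, rate,
                                   config$noise_sd),
        hand_right = sim_joint_path(T, b$hand_right, state, speed, rate,
                                    config$noise_sd))
      fp <- config[[paste0(partner, "_face_prob")]]
      tp <- config[[paste0(partner, "_task_prob")]]
      gaze <- sim_gaze_states(T, fp, tp)
      head <- paths$head
      to_partner <- normalize_rows(sweep(-head, 2L, other_base_head, "+"))
      to_task <- normalize_rows(sweep(-head, 2L, geom$task_point, "+"))
      ho <- to_partner
      ho[gaze == 2L, ] <- to_task[gaze == 2L, , drop = FALSE]
      away_rows <- which(gaze == 3L)
      if (length(away_rows)) {
        # one fixed direction per away bout
        bout_id <- cumsum(c(1L, diff(away_rows) > 1L))
        for (bk in unique(bout_id)) {
          rows <- away_rows[bout_id == bk]
          avoid <- rbind(to_partner[rows[1L], ], to_task[rows[1L], ])
          ho[rows, ] <- matrix(random_away_direction(avoid), length(rows), 3L,
                               byrow = TRUE)
        }
      }
      ho <- normalize_rows(ho + matrix(rnorm(3L * T, sd = 0.01), T, 3L))
      dropout <- runif(T) < config$dropout_prob
      valid <- !dropout
      joints <- lapply(paths, function(p) {
        p[dropout, ] <- NA_real_
        joint_track(p, valid)
      })
      ho[dropout, ] <- NA_real_
      list(stream = skeleton_stream(partner = partner, timestamps = t,
                                    joints = joints, head_orientation = ho,
                                    orientation_valid = valid,
                                    frame_id = "common"),
           gaze = gaze)
    }

    m <- make_stream("mother", mother_state, geom$infant$head)
    i <- make_stream("infant", infant_state, geom$mother$head)
    rec <- dyad_recording(m$stream, i$stream, rate)
    truth <- list(
      mother_moving = mother_state, infant_moving = infant_state,
      mother_onsets = t[rising_edges(mother_state)],
      infant_onsets = t[infant_onset_idx],
      responses = responses,
      p_active_mother = config$mother_on_rate /
        (config$mother_on_rate + config$mother_off_rate),
      p_active_infant = config$infant_on_rate /
        (config$infant_on_rate + config$infant_off_rate),
      gaze_mother = m$gaze, gaze_infant = i$gaze,
      config = config)
    list(recording = rec, truth = truth)
  })
}

#' Split an aligned recording into two misaligned sensor views
#'
#' The inverse of the calibration stage, for end-to-end testing: expresses
#' the infant stream in its own sensor frame (inverse rigid transform),
#' delays its clock by `offset` seconds, and emits a pair of synchronization
#' envelopes containing a shared clap event, plus the point correspondences a
#' chessboard calibration would supply.
#'
#' @param dyad a [dyad_recording()] in the common frame.
#' @param xf [rigid_transform()] from the infant sensor frame to the common
#'   frame (the infant stream is de-registered with its inverse).
#' @param offset infant clock delay in seconds.
#' @param n_points number of calibration correspondences to emit.
#' @param sync_rate synchronization-envelope rate in Hz.
#' @param clap_time common-clock time of the clap event (s).
#' @return list with `mother`, `infant` (raw [skeleton_stream()]s),
#'   `calibration` (`src`/`dst` matrices, infant-sensor to common),
#'   `sync_mother`, `sync_infant` (lists with `samples`, `rate`).
#' @export
desync_dyad <- function(dyad, xf, offset, n_points = 12, sync_rate = 120,
                        clap_time = 1.5) {
  stopifnot(inherits(dyad, "dyad_recording"), inherits(xf, "rigid_transform"))
  inv <- invert_transform(xf)
  infant_raw <- apply_transform(dyad$infant, inv, frame_id = "kinect_infant")
  infant_raw$timestamps <- infant_raw$timestamps + offset
  mother_raw <- dyad$mother
  mother_raw$frame_id <- "kinect_mother"
  # chessboard-like planar grid of correspondences over the table
  gx <- seq(-0.3, 0.3, length.out = ceiling(n_points / 3))
  pts_common <- as.matrix(expand.grid(x = gx, y = c(-0.1, 0, 0.1), z = 0.1))
  pts_common <- pts_common[seq_len(n_points), , drop = FALSE]
  src <- sweep(pts_common %*% t(inv$rotation), 2L, inv$translation, "+")
  dur <- dyad$duration
  env <- function(t0) {
    ts <- seq(0, dur + abs(offset) + 1, by = 1 / sync_rate)
    exp(-((ts - t0) / 0.03)^2)
  }
  list(mother = mother_raw, infant = infant_raw,
       calibration = list(src = src, dst = pts_common),
       sync_mother = list(samples = env(clap_time), rate = sync_rate),
       sync_infant = list(samples = env(clap_time + offset), rate = sync_rate))
}

#' Sign links between generator parameters and CIB-like composites
#'
#' The default link specification used by [simulate_cohort()] to generate
#' composite scores as monotone functions of the true session parameters.
#' Each composite is driven by one primary generator parameter with the sign
#' matching the direction of the reported feature-composite correlations
#' (e.g. maternal sensitivity decreases with mother activity, reciprocity
#' increases with response coupling, avoidance decreases with face-to-face
#' gaze).
#'
#' @return data.frame with columns `composite`, `parameter`, `sign`.
#' @export
default_cib_link <- function() {
  data.frame(
    composite = c("maternal_sensitivity", "mother_intrusiveness",
                  "mother_limit_setting", "dyadic_reciprocity",
                  "negative_dyadic_status", "infant_avoidance",
                  "infant_engagement", "infant_compliance"),
    parameter = c("mother_activity", "mother_activity", "joint_pause",
                  "p_resp", "joint_pause", "face_to_face", "joint_pause",
                  "infant_task"),
    sign = c(-1, 1, 1, 1, -1, -1, 1, 1),
    stringsAsFactors = FALSE)
}

jitter_rate <- function(r, sd) r * exp(rnorm(1L, 0, sd))
jitter_prob <- function(p, sd) {
  if (p <= 0 || p >= 1) return(p)
  stats::plogis(stats::qlogis(p) + rnorm(1L, 0, 2 * sd))
}

#' Simulate a two-group cohort with linked CIB-like composites
#'
#' Emits `2 * n_per_group` sessions. Each session's parameters are drawn
#' around its group's configuration (log-normal jitter on switching rates,
#' logit-normal on probabilities), the dyad is simulated, and the eight
#' composite scores are generated as clamped-to-`[1, 5]` monotone functions
#' of the session's true parameters plus noise, with the signs given by the
#' link specification.
#'
#' @param n_per_group sessions per group.
#' @param config_control,config_risk group-level [dyad_sim_config()]s
#'   (defaults: [config_low_risk()] / [config_high_risk()]).
#' @param link link specification as in [default_cib_link()].
#' @param seed integer seed for the whole cohort.
#' @param param_jitter between-session parameter spread (sd on the log /
#'   half-logit scale).
#' @param cib_noise rating-noise sd added to each composite.
#' @return list with `recordings` (list of [dyad_recording()]s), `truths`,
#'   `cib` (data.frame `session_id` + 8 composites), `labels`
#'   (`low_risk` / `high_risk`), `session_ids`, `true_params` (data.frame of
#'   per-session generator parameters).
#' @export
simulate_cohort <- function(n_per_group,
                            config_control = config_low_risk(),
                            config_risk = config_high_risk(),
                            link = default_cib_link(),
                            seed = 1, param_jitter = 0.15, cib_noise = 0.25) {
  stopifnot(inherits(config_control, "dyad_sim_config"),
            inherits(config_risk, "dyad_sim_config"))
  n <- 2L * n_per_group
  with_seed(seed, {
    labels <- rep(c("low_risk", "high_risk"), each = n_per_group)
    session_ids <- sprintf("dyad_%02d", seq_len(n))
    session_seeds <- sample.int(.Machine$integer.max - 1L, n)
    recordings <- vector("list", n)
    truths <- vector("list", n)
    tp <- vector("list", n)
    for (s in seq_len(n)) {
      base <- if (labels[s] == "low_risk") config_control else config_risk
      cfg <- base
      for (f in c("mother_on_rate", "mother_off_rate",
                  "infant_on_rate", "infant_off_rate"))
        cfg[[f]] <- jitter_rate(base[[f]], param_jitter)
      for (f in c("p_resp", "mother_face_prob", "infant_face_prob",
                  "mother_task_prob", "infant_task_prob"))
        cfg[[f]] <- jitter_prob(base[[f]], param_jitter)
      # keep the gaze simplex constraint after jittering
      tot_m <- cfg$mother_face_prob + cfg$mother_task_prob
      if (tot_m > 1) { cfg$mother_face_prob <- cfg$mother_face_prob / tot_m
                       cfg$mother_task_prob <- cfg$mother_task_prob / tot_m }
      tot_i <- cfg$infant_face_prob + cfg$infant_task_prob
      if (tot_i > 1) { cfg$infant_face_prob <- cfg$infant_face_prob / tot_i
                       cfg$infant_task_prob <- cfg$infant_task_prob / tot_i }
      cfg$seed <- session_seeds[s]
      sim <- simulate_dyad(cfg)
      recordings[[s]] <- sim$recording
      truths[[s]] <- sim$truth
      pm <- sim$truth$p_active_mother
      pi_ <- sim$truth$p_active_infant
      tp[[s]] <- data.frame(
        session_id = session_ids[s],
        mother_activity = pm, infant_activity = pi_,
        p_resp = cfg$p_resp,
        face_to_face = cfg$mother_face_prob * cfg$infant_face_prob,
        joint_pause = (1 - pm) * (1 - pi_),
        infant_task = cfg$infant_task_prob,
        stringsAsFactors = FALSE)
    }
    true_params <- do.call(rbind, tp)
    cib <- data.frame(session_id = session_ids, stringsAsFactors = FALSE)
    for (cname in cib_composite_names()) {
      rows <- link[link$composite == cname, , drop = FALSE]
      raw <- rep(0, n)
      for (r in seq_len(nrow(rows))) {
        v <- true_params[[rows$parameter[r]]]
        if (is.null(v))
          stop("simulate_cohort: unknown link parameter \"",
               rows$parameter[r], "\"")
        sv <- sd(v)
        raw <- raw + rows$sign[r] *
          (if (sv > 0) (v - mean(v)) / sv else rep(0, n))
      }
      spread <- sd(raw)
      z <- if (is.na(spread) || spread == 0) raw else raw / spread
      cib[[cname]] <- pmin(5, pmax(1, 3 + 0.9 * z + rnorm(n, 0, cib_noise)))
    }
    list(recordings = recordings, truths = truths, cib = cib,
         labels = labels, session_ids = session_ids,
         true_params = true_params)
  })
}
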