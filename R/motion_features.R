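#' Quantity of movement (summed joint speed)
#'
#' Per-frame quantity of movement: the sum over the requested joints of the
#' Euclidean displacement between consecutive frames divided by the frame
#' interval, in m/s. A frame's value is defined only when every requested
#' joint is tracked at both that frame and the previous one; the first frame
#' and frames adjacent to dropouts are invalid.
#'
#' @param stream a [skeleton_stream()].
#' @param joints joint names to sum over; default is head plus both hands
#'   when present, otherwise every available joint.
#' @return Object of class `qom_series`: list with `timestamps`, `qom`
#'   (NA where invalid) and `valid`.
#' @export
quantity_of_movement <- function(stream, joints = NULL) {
  stopifnot(inherits(stream, "skeleton_stream"))
  joints <- joints %||% default_feature_joints(stream)
  missing_j <- setdiff(joints, names(stream$joints))
  if (length(missing_j))
    stop("quantity_of_movement: joint(s) not in stream: ",
         paste(missing_j, collapse = ", "))
  t <- stream$timestamps
  T <- length(t)
  dt <- diff(t)
  qom <- rep(0, T)
  valid <- rep(TRUE, T)
  valid[1L] <- FALSE
  for (jn in joints) {
    jt <- stream$joints[[jn]]
    if (sum(jt$valid) < 2L)
      stop("quantity_of_movement: joint \"", jn, "\" has fewer than 2 valid frames")
    disp <- row_norms(diff(jt$positions))
    pair_ok <- jt$valid[-T] & jt$valid[-1L]
    speed <- disp / dt
    speed[!pair_ok] <- NA_real_
    qom[-1L] <- qom[-1L] + speed
    valid[-1L] <- valid[-1L] & pair_ok
  }
  qom[!valid] <- NA_real_
  structure(list(timestamps = t, qom = qom, valid = valid),
            class = "qom_series")
}

# head + both hands when present, else all joints
default_feature_joints <- function(stream) {
  preferred <- intersect(c("head", "hand_left", "hand_right"),
                         names(stream$joints))
  if (length(preferred) >= 2L) preferred else names(stream$joints)
}

#' Binary moving / not-moving state from a quantity-of-movement series
#'
#' Thresholds the quantity of movement, then regularizes the binary state in
#' time by a morphological closing (interior still gaps shorter than
#' `min_duration`, including brief tracking dropouts inside a bout, are merged
#' into the surrounding movement) followed by an opening (movement bursts
#' shorter than `min_duration` are discarded), so every bout of the
#' regularized `state` lasts at least `min_duration`. The reported `moving`
#' mask is `state` restricted to validly tracked frames, so `moving` never
#' labels an untracked frame.
#'
#' @param qom a [quantity_of_movement()] result (or a plain numeric vector, in
#'   which case `rate` must be given).
#' @param threshold movement threshold in m/s.
#' @param min_duration shortest admissible state duration in seconds.
#' @param rate sampling rate in Hz; inferred from timestamps when `qom` is a
#'   `qom_series`.
#' @return Object of class `activity_series`: list with `timestamps`, `qom`,
#'   `valid`, `moving` (state AND valid), `state` (regularized state before
#'   validity masking), `threshold`, `min_duration`, `rate`.
#' @export
detect_activity <- function(qom, threshold = 0.05, min_duration = 0.25,
                            rate = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("detect_activity: threshold must be > 0")
  if (inherits(qom, "qom_series")) {
    t <- qom$timestamps
    rate <- rate %||% (1 / stats::median(diff(t)))
    v <- qom$qom
    valid <- qom$valid
  } else {
    if (is.null(rate)) stop("detect_activity: `rate` required for a bare vector")
    v <- as.numeric(qom)
    t <- (seq_along(v) - 1L) / rate
    valid <- !is.na(v)
  }
  raw <- !is.na(v) & v > threshold & valid
  m <- max(1L, as.integer(ceiling(min_duration * rate - 1e-9)))
  # `state` is the regularized movement state: closing bridges short still
  # gaps (including brief tracking dropouts inside a bout), opening discards
  # sub-minimum bursts, so every state bout lasts >= min_duration. The
  # reported `moving` mask additionally excludes untracked frames.
  state <- open_runs(close_runs(raw, m), m)
  structure(list(timestamps = t, qom = v, valid = valid,
                 moving = state & valid, state = state,
                 threshold = threshold, min_duration = min_duration,
                 rate = rate),
            class = "activity_series")
}

# fill FALSE runs shorter than m frames that sit between TRUE runs
close_runs <- function(x, m) {
  r <- rle(x)
  n <- length(r$lengths)
  if (n >= 3L) {
    interior <- which(!r$values & seq_len(n) > 1L & seq_len(n) < n &
                        r$lengths < m)
    r$values[interior] <- TRUE
  }
  inverse.rle(r)
}

# drop TRUE runs shorter than m frames (anywhere, including edges)
open_runs <- function(x, m) {
  r <- rle(x)
  r$values[r$values & r$lengths < m] <- FALSE
  inverse.rle(r)
}

#' Motion activity ratio
#'
#' Fraction of the partner's validly tracked session time spent in the moving
#' state.
#'
#' @param act an [detect_activity()] result.
#' @return Fraction in `[0, 1]`.
#' @export
activity_ratio <- function(act) {
  stopifnot(inherits(act, "activity_series"))
  nv <- sum(act$valid)
  if (nv == 0L) stop("activity_ratio: no valid frames")
  sum(act$moving & act$valid) / nv
}

joint_head_validity <- function(dyad) {
  dyad$mother$joints[["head"]]$valid & dyad$infant$joints[["head"]]$valid
}

#' Inter-head distance series
#'
#' Frame-wise Euclidean distance between the two partners' heads, NA where
#' either head is untracked.
#'
#' @param dyad a [dyad_recording()].
#' @return Numeric vector (metres) the length of the recording.
#' @export
heads_distance <- function(dyad) {
  stopifnot(inherits(dyad, "dyad_recording"))
  jv <- joint_head_validity(dyad)
  if (!any(jv)) stop("heads_distance: no jointly valid head frames")
  d <- row_norms(dyad$mother$joints[["head"]]$positions -
                   dyad$infant$joints[["head"]]$positions)
  d[!jv] <- NA_real_
  d
}

#' Per-partner contribution to inter-head distance change
#'
#' Decomposes each frame-to-frame change of the inter-head distance along the
#' previous frame's inter-head axis: with `u` the unit vector from infant head
#' to mother head at frame `i-1`, the mother's contribution is
#' `(delta mother head) . u` and the infant's is `-(delta infant head) . u`
#' (so each partner's contribution is positive when they increase the
#' distance). Shares are the absolute contributions summed over the session,
#' normalized to 1; approach and withdrawal count symmetrically. If neither
#' head moved, shares are (0.5, 0.5) by convention.
#'
#' @param dyad a [dyad_recording()].
#' @return list with `mother_share`, `infant_share` (summing to 1) and the
#'   per-frame contribution series `c_mother`, `c_infant` (NA on frames
#'   without two consecutive jointly valid head fixes).
#' @export
heads_distance_contributions <- function(dyad) {
  stopifnot(inherits(dyad, "dyad_recording"))
  jv <- joint_head_validity(dyad)
  T <- length(jv)
  if (sum(jv) < 2L)
    stop("heads_distance_contributions: need >= 2 jointly valid frames")
  hm <- dyad$mother$joints[["head"]]$positions
  hi <- dyad$infant$joints[["head"]]$positions
  pair_ok <- jv[-T] & jv[-1L]
  axis <- hm[-T, , drop = FALSE] - hi[-T, , drop = FALSE]
  u <- normalize_rows(axis)
  cm <- rowSums((hm[-1L, , drop = FALSE] - hm[-T, , drop = FALSE]) * u)
  ci <- -rowSums((hi[-1L, , drop = FALSE] - hi[-T, , drop = FALSE]) * u)
  cm[!pair_ok] <- NA_real_
  ci[!pair_ok] <- NA_real_
  sm <- sum(abs(cm), na.rm = TRUE)
  si <- sum(abs(ci), na.rm = TRUE)
  if (sm + si <= 1e-12) {
    shares <- c(0.5, 0.5)               # both heads static
  } else {
    shares <- c(sm, si) / (sm + si)
  }
  list(mother_share = shares[1L], infant_share = shares[2L],
       c_mother = c(NA_real_, cm), c_infant = c(NA_real_, ci))
}

angle_within <- function(dirs, targets, threshold_deg) {
  # TRUE where the angle between each row of `dirs` and `targets` is within
  # the threshold; NA where undefined (zero-length target vector)
  nt <- row_norms(targets)
  nd <- row_norms(dirs)
  cosang <- rowSums(dirs * targets) / (nd * nt)
  out <- cosang >= cos(threshold_deg * pi / 180) - 1e-12
  out[!is.finite(cosang) | nt <= 1e-12] <- NA
  out
}

#' Fraction of time spent face to face
#'
#' A frame counts as face-to-face when each partner's head orientation points
#' at the other partner's head within `angle_threshold` degrees, for both
#' partners simultaneously. The ratio is over frames where both head
#' positions and both orientations are valid.
#'
#' @param dyad a [dyad_recording()].
#' @param angle_threshold half-angle of the gaze cone in degrees.
#' @return Fraction in `[0, 1]`.
#' @export
face_to_face_ratio <- function(dyad, angle_threshold = 30) {
  stopifnot(inherits(dyad, "dyad_recording"))
  jv <- joint_head_validity(dyad) &
    dyad$mother$orientation_valid & dyad$infant$orientation_valid
  if (!any(jv)) stop("face_to_face_ratio: no jointly valid oriented frames")
  hm <- dyad$mother$joints[["head"]]$positions
  hi <- dyad$infant$joints[["head"]]$positions
  m_at_i <- angle_within(dyad$mother$head_orientation, hi - hm, angle_threshold)
  i_at_m <- angle_within(dyad$infant$head_orientation, hm - hi, angle_threshold)
  ok <- jv & !is.na(m_at_i) & !is.na(i_at_m)
  if (!any(ok)) stop("face_to_face_ratio: no frames with defined gaze angles")
  sum(m_at_i[ok] & i_at_m[ok]) / sum(ok)
}

#' Fraction of time oriented to the task
#'
#' A frame counts when the partner's head orientation points at the task
#' location (e.g. the table centre holding the toy set) within
#' `angle_threshold` degrees. Frames where the head coincides with the task
#' point are skipped as undefined.
#'
#' @param stream a [skeleton_stream()].
#' @param task_point 3-vector, task location in the stream's frame (metres).
#' @param angle_threshold half-angle of the gaze cone in degrees.
#' @return Fraction in `[0, 1]`.
#' @export
task_orientation_ratio <- function(stream, task_point,
                                   angle_threshold = 30) {
  stopifnot(inherits(stream, "skeleton_stream"), length(task_point) == 3L)
  head <- stream$joints[["head"]]
  jv <- head$valid & stream$orientation_valid
  if (!any(jv)) stop("task_orientation_ratio: no valid oriented frames")
  to_task <- sweep(-head$positions, 2L, as.numeric(task_point), "+")
  at_task <- angle_within(stream$head_orientation, to_task, angle_threshold)
  ok <- jv & !is.na(at_task)
  if (!any(ok)) stop("task_orientation_ratio: no frames with defined gaze angle")
  sum(at_task[ok]) / sum(ok)
}

activity_onsets <- function(act) {
  # onsets are rises of the regularized state, so a bout briefly interrupted
  # by a tracking dropout does not restart; a rise needs a preceding still
  # frame, so the first frame of a session never counts
  s <- act$state %||% act$moving
  which(s[-1L] & !s[-length(s)]) + 1L
}

#' Directed onset-based synchrony ratio
#'
#' Fraction of the leader's movement onsets that are answered by a responder
#' movement onset within the window `(0, window]` seconds. An onset is a
#' still-to-moving transition of the regularized activity state. Returns `NA`
#' (undefined) when the leader never onsets, and 0 when the responder never
#' does.
#'
#' @param leader,responder [detect_activity()] results on shared timestamps.
#' @param window response window in seconds.
#' @return Fraction in `[0, 1]`, or `NA` if the leader has no onsets.
#' @export
synchrony_ratio <- function(leader, responder, window = 3) {
  stopifnot(inherits(leader, "activity_series"),
            inherits(responder, "activity_series"))
  if (length(leader$moving) != length(responder$moving))
    stop("synchrony_ratio: series have mismatched lengths")
  t <- leader$timestamps
  on_l <- t[activity_onsets(leader)]
  on_r <- t[activity_onsets(responder)]
  if (!length(on_l)) return(NA_real_)
  eps <- 1e-9
  answered <- vapply(on_l, function(tl)
    any(on_r > tl + eps & on_r <= tl + window + eps), logical(1L))
  mean(answered)
}

#' Overlap ratio: both partners moving simultaneously
#'
#' @param a,b [detect_activity()] results on shared timestamps.
#' @return Fraction of jointly valid frames where both are moving.
#' @export
overlap_ratio <- function(a, b) {
  stopifnot(inherits(a, "activity_series"), inherits(b, "activity_series"))
  if (length(a$moving) != length(b$moving))
    stop("overlap_ratio: series have mismatched lengths")
  jv <- a$valid & b$valid
  if (!any(jv)) stop("overlap_ratio: no jointly valid frames")
  sum(a$moving[jv] & b$moving[jv]) / sum(jv)
}

#' Pause ratio: both partners still simultaneously
#'
#' @param a,b [detect_activity()] results on shared timestamps.
#' @return Fraction of jointly valid frames where neither is moving.
#' @export
pause_ratio <- function(a, b) {
  stopifnot(inherits(a, "activity_series"), inherits(b, "activity_series"))
  if (length(a$moving) != length(b$moving))
    stop("pause_ratio: series have mismatched lengths")
  jv <- a$valid & b$valid
  if (!any(jv)) stop("pause_ratio: no jointly valid frames")
  sum(!a$moving[jv] & !b$moving[jv]) / sum(jv)
}
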