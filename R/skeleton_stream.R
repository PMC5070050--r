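#' Per-joint 3D position track
#'
#' A `joint_track` holds the 3D trajectory of one tracked skeleton point over
#' the frames of a stream, together with a per-frame validity mask (skeleton
#' trackers routinely drop frames; invalid frames are flagged, never removed).
#'
#' @param positions numeric T x 3 matrix of positions in metres.
#' @param valid logical vector of length T; default marks rows with all-finite
#'   coordinates as valid.
#' @return An object of class `joint_track`: list with `positions` and `valid`.
#' @export
joint_track <- function(positions, valid = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("joint_track: `positions` must have 3 columns (x, y, z)")
  storage.mode(positions) <- "double"
  if (is.null(valid)) valid <- apply(is.finite(positions), 1L, all)
  valid <- as.logical(valid)
  if (length(valid) != nrow(positions))
    stop("joint_track: `valid` length must equal nrow(positions)")
  valid[is.na(valid)] <- FALSE
  if (any(valid & !apply(is.finite(positions), 1L, all)))
    stop("joint_track: non-finite position marked valid")
  structure(list(positions = positions, valid = valid), class = "joint_track")
}

#' One partner's skeleton stream
#'
#' A time-stamped sequence of tracked 3D joints plus a head-orientation
#' (face-forward) unit vector per frame, expressed in a named coordinate frame.
#' The `"head"` joint is mandatory; any further joint set is accepted.
#'
#' @param partner partner label, typically `"mother"` or `"infant"`.
#' @param timestamps strictly increasing vector of session times in seconds.
#' @param joints named list of [joint_track()] objects; must contain `"head"`.
#' @param head_orientation T x 3 matrix of unit face-forward vectors (may be
#'   `NULL` when orientation was not tracked).
#' @param orientation_valid logical mask for the orientation rows; defaults to
#'   rows that are finite with norm within 1e-6 of 1.
#' @param frame_id label of the coordinate frame (a sensor name, or `"common"`
#'   once co-registered).
#' @return An object of class `skeleton_stream`.
#' @export
skeleton_stream <- function(partner, timestamps, joints,
                            head_orientation = NULL,
                            orientation_valid = NULL,
                            frame_id = "sensor") {
  stopifnot(is.character(partner), length(partner) == 1L)
  timestamps <- as.numeric(timestamps)
  T <- length(timestamps)
  if (T < 1L) stop("skeleton_stream: empty timestamp vector")
  if (any(!is.finite(timestamps)))
    stop("skeleton_stream: non-finite timestamps")
  if (T > 1L && any(diff(timestamps) <= 0))
    stop("skeleton_stream: timestamps must be strictly increasing")
  if (is.null(names(joints)) || any(names(joints) == ""))
    stop("skeleton_stream: `joints` must be a named list")
  if (!"head" %in% names(joints))
    stop("skeleton_stream: a \"head\" joint is required")
  for (nm in names(joints)) {
    jt <- joints[[nm]]
    if (!inherits(jt, "joint_track")) jt <- joint_track(jt)
    if (nrow(jt$positions) != T)
      stop(sprintf("skeleton_stream: joint \"%s\" has %d frames, expected %d",
                   nm, nrow(jt$positions), T))
    joints[[nm]] <- jt
  }
  if (is.null(head_orientation)) {
    head_orientation <- matrix(NA_real_, T, 3L)
    orientation_valid <- rep(FALSE, T)
  } else {
    head_orientation <- as.matrix(head_orientation)
    storage.mode(head_orientation) <- "double"
    if (nrow(head_orientation) != T || ncol(head_orientation) != 3L)
      stop("skeleton_stream: head_orientation must be a T x 3 matrix")
    nrm <- row_norms(head_orientation)
    if (is.null(orientation_valid))
      orientation_valid <- is.finite(nrm) & abs(nrm - 1) <= 1e-6
    orientation_valid <- as.logical(orientation_valid)
    orientation_valid[is.na(orientation_valid)] <- FALSE
    if (any(orientation_valid & (!is.finite(nrm) | abs(nrm - 1) > 1e-6)))
      stop("skeleton_stream: head_orientation rows marked valid must be unit vectors (tol 1e-6)")
  }
  structure(list(partner = partner,
                 timestamps = timestamps,
                 joints = joints,
                 head_orientation = head_orientation,
                 orientation_valid = orientation_valid,
                 frame_id = frame_id),
            class = "skeleton_stream")
}

#' @export
print.skeleton_stream <- function(x, ...) {
  dur <- diff(range(x$timestamps))
  cat(sprintf("<skeleton_stream> partner=%s frame=%s: %d frames over %.2f s\n",
              x$partner, x$frame_id, length(x$timestamps), dur))
  cat("  joints:", paste(names(x$joints), collapse = ", "), "\n")
  cat(sprintf("  orientation valid: %d/%d frames\n",
              sum(x$orientation_valid), length(x$orientation_valid)))
  invisible(x)
}

n_frames <- function(stream) length(stream$timestamps)

#' A spatio-temporally aligned dyad recording
#'
#' Both partners' streams on identical timestamps in a shared coordinate
#' frame, at a common sampling rate.
#'
#' @param mother,infant [skeleton_stream()] objects sharing timestamps and
#'   frame id.
#' @param rate common sampling rate in Hz.
#' @return An object of class `dyad_recording` with fields `mother`, `infant`,
#'   `rate` and `duration` (seconds, `(T-1)/rate`).
#' @export
dyad_recording <- function(mother, infant, rate) {
  stopifnot(inherits(mother, "skeleton_stream"),
            inherits(infant, "skeleton_stream"))
  if (length(mother$timestamps) != length(infant$timestamps) ||
      max(abs(mother$timestamps - infant$timestamps)) > 1e-9)
    stop("dyad_recording: streams must share identical timestamps")
  if (!identical(mother$frame_id, infant$frame_id))
    stop("dyad_recording: streams must share one coordinate frame (got \"",
         mother$frame_id, "\" and \"", infant$frame_id, "\")")
  if (!is.numeric(rate) || rate <= 0) stop("dyad_recording: rate must be > 0")
  structure(list(mother = mother, infant = infant, rate = rate,
                 duration = (length(mother$timestamps) - 1L) / rate),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %d frames @ %g Hz (%.1f s), frame=%s\n",
              length(x$mother$timestamps), x$rate, x$duration,
              x$mother$frame_id))
  invisible(x)
}
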