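#' Feature-extraction parameters
#'
#' Bundles every tunable of the feature extractor with its default. Defaults
#' are scaled to tabletop play: the activity threshold is 0.05 m/s on summed
#' head+hand speed, state changes shorter than 0.25 s are treated as tracker
#' flicker, a movement response within 3 s counts as an answer to an onset,
#' and gaze cones are 30 degrees wide. The task location is a single 3D point
#' (the table centre) in the common frame.
#'
#' @param activity_threshold moving/still threshold on quantity of movement
#'   (m/s).
#' @param min_duration shortest admissible moving/still bout (s).
#' @param sync_window response window for the synchrony ratios (s).
#' @param face_angle,task_angle gaze-cone half-angles (degrees).
#' @param joints joint names for quantity of movement, or `NULL` for the
#'   per-stream default (head + hands when present).
#' @param task_point 3-vector task location in metres (common frame).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(activity_threshold = 0.05,
                              min_duration = 0.25,
                              sync_window = 3,
                              face_angle = 30,
                              task_angle = 30,
                              joints = NULL,
                              task_point = c(0, 0, 0)) {
  stopifnot(activity_threshold > 0, min_duration >= 0, sync_window > 0,
            face_angle > 0, task_angle > 0, length(task_point) == 3L)
  structure(list(activity_threshold = activity_threshold,
                 min_duration = min_duration,
                 sync_window = sync_window,
                 face_angle = face_angle,
                 task_angle = task_angle,
                 joints = joints,
                 task_point = as.numeric(task_point)),
            class = "extraction_config")
}

#' Extract the canonical 17-feature session vector
#'
#' Runs every individual and dyadic feature operation on an aligned recording
#' and assembles the canonical vector (see [feature_names()] for the roster
#' and order): quantity-of-movement mean/sd and activity ratio per partner,
#' inter-head distance mean/sd and per-partner contribution shares, the
#' face-to-face ratio, per-partner task-orientation ratios, the two directed
#' synchrony ratios (`sync_parent_to_infant` is the parent's response to
#' infant onsets), and the overlap and pause ratios. Deterministic given its
#' inputs.
#'
#' @param dyad a [dyad_recording()].
#' @param config an [extraction_config()].
#' @param session_id,group optional identifiers attached as attributes (used
#'   by [write_feature_table()]).
#' @return Named numeric vector of class `motion_feature_set`, length 17.
#' @export
extract_feature_vector <- function(dyad, config = extraction_config(),
                                   session_id = NULL, group = NULL) {
  stopifnot(inherits(dyad, "dyad_recording"),
            inherits(config, "extraction_config"))
  with_feature <- function(feature, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("extract_feature_vector [%s]: %s", feature,
                   conditionMessage(e)), call. = FALSE))
  }
  qom_m <- with_feature("mother_qom",
                        quantity_of_movement(dyad$mother, config$joints))
  qom_i <- with_feature("infant_qom",
                        quantity_of_movement(dyad$infant, config$joints))
  act_m <- detect_activity(qom_m, config$activity_threshold,
                           config$min_duration, rate = dyad$rate)
  act_i <- detect_activity(qom_i, config$activity_threshold,
                           config$min_duration, rate = dyad$rate)
  d <- with_feature("heads_distance", heads_distance(dyad))
  contrib <- with_feature("heads_contribution",
                          heads_distance_contributions(dyad))
  out <- c(
    mother_qom_mean = mean(qom_m$qom, na.rm = TRUE),
    mother_qom_sd = sd(qom_m$qom[qom_m$valid]),
    infant_qom_mean = mean(qom_i$qom, na.rm = TRUE),
    infant_qom_sd = sd(qom_i$qom[qom_i$valid]),
    mother_activity_ratio = with_feature("mother_activity_ratio",
                                         activity_ratio(act_m)),
    infant_activity_ratio = with_feature("infant_activity_ratio",
                                         activity_ratio(act_i)),
    heads_distance_mean = mean(d, na.rm = TRUE),
    heads_distance_sd = sd(d[!is.na(d)]),
    mother_heads_contribution = contrib$mother_share,
    infant_heads_contribution = contrib$infant_share,
    face_to_face_ratio = with_feature("face_to_face_ratio",
                                      face_to_face_ratio(dyad, config$face_angle)),
    mother_task_ratio = with_feature("mother_task_ratio",
                                     task_orientation_ratio(dyad$mother,
                                                            config$task_point,
                                                            config$task_angle)),
    infant_task_ratio = with_feature("infant_task_ratio",
                                     task_orientation_ratio(dyad$infant,
                                                            config$task_point,
                                                            config$task_angle)),
    sync_parent_to_infant = synchrony_ratio(act_i, act_m, config$sync_window),
    sync_infant_to_parent = synchrony_ratio(act_m, act_i, config$sync_window),
    overlap_ratio = with_feature("overlap_ratio", overlap_ratio(act_m, act_i)),
    pause_ratio = with_feature("pause_ratio", pause_ratio(act_m, act_i)))
  stopifnot(identical(names(out), feature_names()))
  structure(out, class = "motion_feature_set",
            session_id = session_id, group = group)
}

#' @export
print.motion_feature_set <- function(x, ...) {
  id <- attr(x, "session_id")
  cat("<motion_feature_set>", if (!is.null(id)) paste0("session ", id), "\n")
  print(round(setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}
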