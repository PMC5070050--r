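# builders for small hand-constructed streams and recordings

# single- or multi-joint stream from a named list of T x 3 matrices
toy_stream <- function(positions, timestamps, partner = "mother",
                       orientation = NULL, frame_id = "common",
                       valid = NULL) {
  joints <- lapply(positions, function(p) {
    p <- as.matrix(p)
    joint_track(p, valid %||% rep(TRUE, nrow(p)))
  })
  skeleton_stream(partner = partner, timestamps = timestamps, joints = joints,
                  head_orientation = orientation, frame_id = frame_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-position stream; orientation along `facing`
static_stream <- function(head_at, timestamps, partner, facing = c(0, 1, 0)) {
  T <- length(timestamps)
  ori <- matrix(rep(facing / sqrt(sum(facing^2)), each = T), T, 3L)
  toy_stream(list(head = matrix(rep(head_at, each = T), T, 3L)),
             timestamps, partner = partner, orientation = ori)
}

# dyad with both heads static, facing each other
static_dyad <- function(duration = 2, rate = 10,
                        mother_at = c(0, -0.5, 0.5), infant_at = c(0, 0.5, 0.5)) {
  t <- seq(0, duration, by = 1 / rate)
  m <- static_stream(mother_at, t, "mother", facing = infant_at - mother_at)
  i <- static_stream(infant_at, t, "infant", facing = mother_at - infant_at)
  dyad_recording(m, i, rate)
}

# activity_series from an explicit moving vector (bypasses thresholding)
toy_activity <- function(moving, rate = 1, valid = NULL, timestamps = NULL) {
  moving <- as.logical(moving)
  valid <- valid %||% rep(TRUE, length(moving))
  structure(list(timestamps = timestamps %||% ((seq_along(moving) - 1) / rate),
                 qom = as.numeric(moving), valid = valid,
                 moving = moving & valid, state = moving,
                 threshold = 0.5, min_duration = 0, rate = rate),
            class = "activity_series")
}

normalize_rows_test <- function(m) m / sqrt(rowSums(m^2))
row_norms_test <- function(m) sqrt(rowSums(m^2))

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
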