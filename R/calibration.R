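#' Rigid transform between sensor frames
#'
#' A proper rigid motion `p -> R p + t` (rotation plus translation, no scale,
#' no reflection) mapping one sensor's coordinates into another's.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector in metres.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rigid_transform: rotation is not orthonormal (tol 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation must have det +1 (reflections excluded)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f) m\n",
              ang, x$translation[1L], x$translation[2L], x$translation[3L]))
  invisible(x)
}

#' Invert a rigid transform
#' @param xf a [rigid_transform()].
#' @return The inverse transform (`R^T`, `-R^T t`).
#' @export
invert_transform <- function(xf) {
  stopifnot(inherits(xf, "rigid_transform"))
  Rt <- t(xf$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% xf$translation))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return `p -> a(b(p))` as a single [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid transform from point correspondences
#'
#' Estimates the rotation and translation minimizing
#' `sum ||R src_i + t - dst_i||^2` by the SVD-based closed form
#' (Kabsch/Umeyama without scale). Reflections are excluded, so the estimate
#' is always a proper rigid motion. In the sensor-calibration workflow the
#' correspondences are chessboard corners seen simultaneously by both sensors.
#'
#' @param src,dst N x 3 matrices of corresponding points (N >= 3,
#'   non-collinear).
#' @return A [rigid_transform()] mapping `src` coordinates onto `dst`.
#' @export
estimate_rigid_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 3L || ncol(dst) != 3L)
    stop("estimate_rigid_transform: point sets must be N x 3")
  if (nrow(src) != nrow(dst))
    stop("estimate_rigid_transform: src and dst must have equal row counts")
  n <- nrow(src)
  if (n < 3L)
    stop("estimate_rigid_transform: need at least 3 correspondences, got ", n)
  if (any(!is.finite(src)) || any(!is.finite(dst)))
    stop("estimate_rigid_transform: non-finite coordinates")
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2L, cs); Y <- sweep(dst, 2L, cd)
  # collinear (or coincident) source points leave the rotation about the line
  # unconstrained
  sv_src <- svd(X, nu = 0L, nv = 0L)$d
  scale <- max(sv_src[1L], 1e-12)
  if (sv_src[2L] / scale < 1e-8)
    stop("estimate_rigid_transform: degenerate geometry (points are collinear)")
  H <- crossprod(X, Y)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cd - as.numeric(R %*% cs)
  rigid_transform(R, t)
}

#' Apply a rigid transform to a skeleton stream
#'
#' Maps every joint position `p -> R p + t` and every head-orientation vector
#' `o -> R o` (directions are rotation-only). Validity masks are untouched and
#' the stream's frame id becomes `"common"`.
#'
#' @param stream a [skeleton_stream()].
#' @param xf a [rigid_transform()].
#' @param frame_id frame label of the result.
#' @return The transformed [skeleton_stream()].
#' @export
apply_transform <- function(stream, xf, frame_id = "common") {
  stopifnot(inherits(stream, "skeleton_stream"), inherits(xf, "rigid_transform"))
  Rt <- t(xf$rotation)
  joints <- lapply(stream$joints, function(jt) {
    pos <- jt$positions %*% Rt
    pos <- sweep(pos, 2L, xf$translation, "+")
    pos[!jt$valid, ] <- NA_real_
    joint_track(pos, jt$valid)
  })
  ho <- stream$head_orientation %*% Rt
  ho[!stream$orientation_valid, ] <- NA_real_
  skeleton_stream(partner = stream$partner, timestamps = stream$timestamps,
                  joints = joints, head_orientation = ho,
                  orientation_valid = stream$orientation_valid,
                  frame_id = frame_id)
}

#' Temporal offset between two synchronization signals
#'
#' Finds the lag maximizing the normalized cross-correlation between the two
#' signals over lags in `[-max_lag, +max_lag]`, then refines the peak to
#' sub-sample precision by parabolic interpolation through the three
#' correlations around it. In the recording workflow the signals are the two
#' sensors' microphone (or motion) energy envelopes, both containing the
#' shared hand-clap event; signals should be non-negative envelopes or
#' zero-mean (no demeaning is applied).
#'
#' A positive `offset` means signal `b` lags signal `a`: an event at time `t`
#' in `a` appears at `t + offset` in `b`.
#'
#' @param sig_a,sig_b numeric sample vectors at a common `rate`.
#' @param rate sampling rate in Hz.
#' @param max_lag search half-width in seconds.
#' @param refine use parabolic sub-sample refinement (default TRUE).
#' @return list of class `temporal_alignment` with `offset` (seconds) and
#'   `confidence` (peak correlation in `[-1, 1]`).
#' @export
estimate_temporal_offset <- function(sig_a, sig_b, rate, max_lag = 5,
                                     refine = TRUE) {
  sig_a <- as.numeric(sig_a); sig_b <- as.numeric(sig_b)
  if (any(!is.finite(sig_a)) || any(!is.finite(sig_b)))
    stop("estimate_temporal_offset: signals must be finite")
  if (var(sig_a) == 0 || var(sig_b) == 0)
    stop("estimate_temporal_offset: flat signal, no synchronization energy")
  L <- as.integer(round(max_lag * rate))
  if (min(length(sig_a), length(sig_b)) <= 2L * L)
    stop("estimate_temporal_offset: signals shorter than 2*max_lag*rate samples")
  lags <- (-L):L
  # matched-filter normalized cross-correlation: signals are energy envelopes
  # (or zero-mean), so no demeaning; norms taken over the overlapping segment
  # keep |cc| <= 1 by Cauchy-Schwarz
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- seq_len(length(sig_a) - l)
      ib <- ia + l
    } else {
      ib <- seq_len(length(sig_b) + l)
      ia <- ib - l
    }
    ib <- ib[ib <= length(sig_b)]; ia <- ia[seq_along(ib)]
    a <- sig_a[ia]; b <- sig_b[ib]
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0) return(-Inf)
    sum(a * b) / (na * nb)
  }, numeric(1L))
  k <- which.max(cc)
  peak_lag <- lags[k]
  peak_val <- cc[k]
  offset <- peak_lag / rate
  if (refine && k > 1L && k < length(lags) &&
      is.finite(cc[k - 1L]) && is.finite(cc[k + 1L])) {
    y0 <- cc[k - 1L]; y1 <- cc[k]; y2 <- cc[k + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom < -1e-12) {                  # genuine local maximum
      delta <- 0.5 * (y0 - y2) / denom
      delta <- max(-0.5, min(0.5, delta))
      offset <- (peak_lag + delta) / rate
    }
  }
  structure(list(offset = offset,
                 confidence = max(-1, min(1, peak_val))),
            class = "temporal_alignment")
}

#' @export
print.temporal_alignment <- function(x, ...) {
  cat(sprintf("<temporal_alignment> offset %.4f s (confidence %.3f)\n",
              x$offset, x$confidence))
  invisible(x)
}

#' Build an aligned dyad recording from two raw sensor streams
#'
#' Applies the sensor-to-common rigid transform to the infant stream, removes
#' the estimated clock offset, and resamples both streams onto one uniform
#' timestamp grid over the overlapping window.
#'
#' The temporal alignment is interpreted with the mother's sensor as reference
#' signal `a`: infant timestamps are mapped into the common clock as
#' `t - offset`.
#'
#' @param mother,infant raw [skeleton_stream()] objects in their own frames.
#' @param xf [rigid_transform()] from the infant sensor frame to the mother
#'   (common) frame; identity if the streams are already co-registered.
#' @param ta [estimate_temporal_offset()] result (or a number of seconds);
#'   zero if clocks are already shared.
#' @param rate target common rate in Hz.
#' @param max_gap interpolation gap limit passed to [resample_stream()].
#' @return A [dyad_recording()].
#' @export
align_dyad <- function(mother, infant, xf = rigid_transform(), ta = 0,
                       rate = 30, max_gap = 0.33) {
  stopifnot(inherits(mother, "skeleton_stream"),
            inherits(infant, "skeleton_stream"))
  offset <- if (inherits(ta, "temporal_alignment")) ta$offset else as.numeric(ta)
  infant <- apply_transform(infant, xf, frame_id = "common")
  infant$timestamps <- infant$timestamps - offset
  mother$frame_id <- "common"
  t0 <- max(mother$timestamps[1L], infant$timestamps[1L])
  t1 <- min(mother$timestamps[length(mother$timestamps)],
            infant$timestamps[length(infant$timestamps)])
  if (t1 - t0 < 1)
    stop(sprintf(paste0("align_dyad: temporal overlap after offset removal is ",
                        "%.2f s (< 1 s); streams do not overlap"), t1 - t0))
  grid <- t0 + seq(0L, floor((t1 - t0) * rate + 1e-9)) / rate
  m <- resample_stream(mother, rate, max_gap = max_gap, timestamps = grid)
  i <- resample_stream(infant, rate, max_gap = max_gap, timestamps = grid)
  dyad_recording(m, i, rate)
}
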