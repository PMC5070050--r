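#' Read a skeleton stream from disk
#'
#' Two on-disk dialects are supported. The reference dialect is a long-format
#' CSV with mandatory header `t, joint, x, y, z, ox, oy, oz, valid`
#' (orientation columns are only filled on `head` rows; `valid` is 0/1).
#' Optional comment lines `# partner=<label>` and `# frame=<label>` carry
#' stream metadata. The XML dialect mirrors the structure
#' `<stream partner frame><frame t><joint name x y z/><orientation ox oy oz/></frame>...`.
#'
#' Untracked frames are flagged invalid, never dropped, so downstream validity
#' masks line up with the original frame grid.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"xml"`; default guessed from the file extension.
#' @param partner override the partner label stored in the file.
#' @return A [skeleton_stream()].
#' @export
read_skeleton_stream <- function(path, dialect = c("auto", "csv", "xml"),
                                 partner = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_skeleton_stream: no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  if (dialect == "csv") read_skeleton_csv(path, partner)
  else read_skeleton_xml(path, partner)
}

read_skeleton_csv <- function(path, partner = NULL) {
  hdr <- readLines(path, n = 20L)
  meta_line <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^#\\s*%s\\s*=\\s*", key), "", m[1L]) else NULL
  }
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("read_skeleton_stream: malformed CSV \"", path,
                             "\": ", conditionMessage(e)))
  need <- c("t", "joint", "x", "y", "z", "ox", "oy", "oz", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_skeleton_stream: \"", path, "\" is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("read_skeleton_stream: \"", path, "\" has no data rows")
  timestamps <- unique(df$t)           # file order, deliberately unsorted
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("read_skeleton_stream: timestamps in \"", path,
         "\" are not strictly increasing")
  T <- length(timestamps)
  joints <- list()
  ho <- matrix(NA_real_, T, 3L)
  for (jn in unique(df$joint)) {
    sub <- df[df$joint == jn, , drop = FALSE]
    idx <- match(sub$t, timestamps)
    if (anyDuplicated(idx))
      stop("read_skeleton_stream: duplicate (t, joint) row for joint \"",
           jn, "\" in \"", path, "\"")
    pos <- matrix(NA_real_, T, 3L)
    pos[idx, ] <- as.matrix(sub[, c("x", "y", "z")])
    vld <- rep(FALSE, T)
    vld[idx] <- as.logical(sub$valid) & apply(is.finite(pos[idx, , drop = FALSE]), 1L, all)
    pos[!vld, ] <- NA_real_
    joints[[jn]] <- joint_track(pos, vld)
    if (jn == "head") ho[idx, ] <- as.matrix(sub[, c("ox", "oy", "oz")])
  }
  skeleton_stream(partner = partner %||% meta_line("partner") %||% "unknown",
                  timestamps = timestamps, joints = joints,
                  head_orientation = ho,
                  frame_id = meta_line("frame") %||% "sensor")
}

read_skeleton_xml <- function(path, partner = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_skeleton_stream: malformed XML \"",
                                           path, "\": ", conditionMessage(e)))
  frames <- xml2::xml_find_all(doc, "./frame")
  if (!length(frames)) stop("read_skeleton_stream: no <frame> elements in \"", path, "\"")
  timestamps <- as.numeric(xml2::xml_attr(frames, "t"))
  if (any(is.na(timestamps)))
    stop("read_skeleton_stream: <frame> element without numeric t attribute in \"",
         path, "\"")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("read_skeleton_stream: timestamps in \"", path,
         "\" are not strictly increasing")
  T <- length(timestamps)
  jnodes <- xml2::xml_find_all(doc, "./frame/joint")
  # note: xml_parent() on a whole nodeset deduplicates, so resolve each
  # node's own parent frame
  parent_t <- vapply(seq_along(jnodes), function(k)
    as.numeric(xml2::xml_attr(xml2::xml_parent(jnodes[[k]]), "t")),
    numeric(1L))
  jdf <- data.frame(
    t = parent_t,
    joint = xml2::xml_attr(jnodes, "name"),
    x = as.numeric(xml2::xml_attr(jnodes, "x")),
    y = as.numeric(xml2::xml_attr(jnodes, "y")),
    z = as.numeric(xml2::xml_attr(jnodes, "z")),
    stringsAsFactors = FALSE)
  joints <- list()
  for (jn in unique(jdf$joint)) {
    sub <- jdf[jdf$joint == jn, , drop = FALSE]
    idx <- match(sub$t, timestamps)
    pos <- matrix(NA_real_, T, 3L)
    pos[idx, ] <- as.matrix(sub[, c("x", "y", "z")])
    vld <- apply(is.finite(pos), 1L, all)
    pos[!vld, ] <- NA_real_
    joints[[jn]] <- joint_track(pos, vld)
  }
  onodes <- xml2::xml_find_all(doc, "./frame/orientation")
  ho <- matrix(NA_real_, T, 3L)
  if (length(onodes)) {
    o_t <- vapply(seq_along(onodes), function(k)
      as.numeric(xml2::xml_attr(xml2::xml_parent(onodes[[k]]), "t")),
      numeric(1L))
    idx <- match(o_t, timestamps)
    ho[idx, ] <- cbind(as.numeric(xml2::xml_attr(onodes, "ox")),
                       as.numeric(xml2::xml_attr(onodes, "oy")),
                       as.numeric(xml2::xml_attr(onodes, "oz")))
  }
  skeleton_stream(partner = partner %||% xml2::xml_attr(doc, "partner") %||% "unknown",
                  timestamps = timestamps, joints = joints,
                  head_orientation = ho,
                  frame_id = xml2::xml_attr(doc, "frame") %||% "sensor")
}

#' Write a skeleton stream to disk
#'
#' Inverse of [read_skeleton_stream()]; round-trips positions to better than
#' 1e-9 m in either dialect.
#'
#' @param stream a [skeleton_stream()].
#' @param path destination file.
#' @param dialect `"csv"` (reference) or `"xml"`; default from extension.
#' @export
write_skeleton_stream <- function(stream, path,
                                  dialect = c("auto", "csv", "xml")) {
  stopifnot(inherits(stream, "skeleton_stream"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  if (dialect == "csv") write_skeleton_csv(stream, path)
  else write_skeleton_xml(stream, path)
  invisible(path)
}

write_skeleton_csv <- function(stream, path) {
  rows <- lapply(names(stream$joints), function(jn) {
    jt <- stream$joints[[jn]]
    d <- data.frame(t = stream$timestamps, joint = jn,
                    x = jt$positions[, 1L], y = jt$positions[, 2L],
                    z = jt$positions[, 3L],
                    ox = NA_real_, oy = NA_real_, oz = NA_real_,
                    valid = as.integer(jt$valid))
    if (jn == "head") {
      d$ox <- stream$head_orientation[, 1L]
      d$oy <- stream$head_orientation[, 2L]
      d$oz <- stream$head_orientation[, 3L]
    }
    d
  })
  df <- do.call(rbind, rows)
  df <- df[order(match(df$t, stream$timestamps)), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# partner=%s", stream$partner),
               sprintf("# frame=%s", stream$frame_id)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

write_skeleton_xml <- function(stream, path) {
  T <- length(stream$timestamps)
  num <- function(v) sprintf("%.12g", v)
  frame_chunks <- character(T)
  jnames <- names(stream$joints)
  for (i in seq_len(T)) {
    parts <- sprintf("<frame t=\"%s\">", num(stream$timestamps[i]))
    for (jn in jnames) {
      jt <- stream$joints[[jn]]
      if (jt$valid[i])
        parts <- c(parts, sprintf("<joint name=\"%s\" x=\"%s\" y=\"%s\" z=\"%s\"/>",
                                  jn, num(jt$positions[i, 1L]),
                                  num(jt$positions[i, 2L]), num(jt$positions[i, 3L])))
    }
    if (stream$orientation_valid[i])
      parts <- c(parts, sprintf("<orientation ox=\"%s\" oy=\"%s\" oz=\"%s\"/>",
                                num(stream$head_orientation[i, 1L]),
                                num(stream$head_orientation[i, 2L]),
                                num(stream$head_orientation[i, 3L])))
    frame_chunks[i] <- paste0(paste(parts, collapse = ""), "</frame>")
  }
  writeLines(c(sprintf("<stream partner=\"%s\" frame=\"%s\">",
                       stream$partner, stream$frame_id),
               frame_chunks, "</stream>"), path)
}

#' Resample a skeleton stream to a uniform rate
#'
#' Produces uniform timestamps `t0 + k/rate`, linearly interpolating positions
#' inside gaps no longer than `max_gap`; frames falling in longer gaps, or
#' outside a joint's tracked span, stay invalid. Orientation vectors are
#' interpolated the same way and re-normalized to unit length.
#'
#' @param stream a [skeleton_stream()].
#' @param rate target rate in Hz.
#' @param max_gap longest gap (seconds) bridged by interpolation. The default
#'   0.33 s is about ten frames at the 30 Hz sensor-native rate.
#' @param timestamps optional explicit target timestamps (overrides `rate`'s
#'   grid construction but keeps the gap policy); used by [align_dyad()].
#' @return A [skeleton_stream()] on the new grid.
#' @export
resample_stream <- function(stream, rate, max_gap = 0.33, timestamps = NULL) {
  stopifnot(inherits(stream, "skeleton_stream"))
  if (!is.numeric(rate) || rate <= 0) stop("resample_stream: rate must be > 0")
  t_old <- stream$timestamps
  if (is.null(timestamps)) {
    n_int <- floor((t_old[length(t_old)] - t_old[1L]) * rate + 1e-9)
    timestamps <- t_old[1L] + seq(0L, n_int) / rate
  }
  eps <- 1e-9
  interp_block <- function(mat, valid, what) {
    tv <- t_old[valid]
    if (length(tv) < 2L)
      stop("resample_stream: fewer than 2 valid frames for ", what)
    out <- matrix(NA_real_, length(timestamps), 3L)
    for (k in 1:3)
      out[, k] <- approx(tv, mat[valid, k], xout = timestamps,
                         method = "linear", rule = 1L, ties = "ordered")$y
    # valid iff inside a bridged gap (<= max_gap) or exactly on a valid sample
    iv <- findInterval(timestamps, tv)
    ok <- rep(FALSE, length(timestamps))
    inside <- iv >= 1L & iv < length(tv)
    ok[inside] <- (tv[iv[inside] + 1L] - tv[iv[inside]]) <= max_gap + eps
    on_node <- (iv >= 1L & abs(timestamps - tv[pmax(iv, 1L)]) <= eps)
    ok <- ok | on_node
    out[!ok, ] <- NA_real_
    list(values = out, valid = ok)
  }
  joints <- lapply(names(stream$joints), function(jn) {
    jt <- stream$joints[[jn]]
    if (!any(jt$valid))
      stop("resample_stream: joint \"", jn, "\" has no valid frames")
    b <- interp_block(jt$positions, jt$valid, paste0("joint \"", jn, "\""))
    joint_track(b$values, b$valid)
  })
  names(joints) <- names(stream$joints)
  ho <- matrix(NA_real_, length(timestamps), 3L)
  ho_valid <- rep(FALSE, length(timestamps))
  if (sum(stream$orientation_valid) >= 2L) {
    b <- interp_block(stream$head_orientation, stream$orientation_valid,
                      "head orientation")
    ho <- normalize_rows(b$values)
    ho_valid <- b$valid & is.finite(ho[, 1L])
    ho[!ho_valid, ] <- NA_real_
  }
  skeleton_stream(partner = stream$partner, timestamps = timestamps,
                  joints = joints, head_orientation = ho,
                  orientation_valid = ho_valid, frame_id = stream$frame_id)
}

#' Canonical feature names
#'
#' The fixed 17-element feature roster, in canonical column order: per-partner
#' quantity-of-movement mean/sd and activity ratios, inter-head distance
#' mean/sd and per-partner contribution shares, face-to-face ratio,
#' per-partner task-orientation ratios, the two directed synchrony ratios, and
#' the overlap and pause ratios.
#'
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c("mother_qom_mean", "mother_qom_sd", "infant_qom_mean", "infant_qom_sd",
    "mother_activity_ratio", "infant_activity_ratio",
    "heads_distance_mean", "heads_distance_sd",
    "mother_heads_contribution", "infant_heads_contribution",
    "face_to_face_ratio", "mother_task_ratio", "infant_task_ratio",
    "sync_parent_to_infant", "sync_infant_to_parent",
    "overlap_ratio", "pause_ratio")
}

#' Write a session feature table
#'
#' One row per session with columns `session_id, group, <17 features>` in
#' canonical order. An empty feature list yields a header-only file.
#'
#' @param features list of [extract_feature_vector()] results (class
#'   `motion_feature_set`).
#' @param path destination CSV.
#' @param session_ids,groups optional per-session identifiers and labels;
#'   default to attributes stored on the feature sets.
#' @export
write_feature_table <- function(features, path, session_ids = NULL,
                                groups = NULL) {
  canon <- feature_names()
  if (length(features)) {
    for (i in seq_along(features)) {
      nm <- names(features[[i]])
      if (!identical(nm, canon))
        stop("write_feature_table: feature set ", i,
             " does not match the canonical 17-name order; unexpected: ",
             paste(setdiff(nm, canon), collapse = ", "),
             "; missing: ", paste(setdiff(canon, nm), collapse = ", "))
    }
  }
  ids <- session_ids %||% vapply(seq_along(features), function(i)
    attr(features[[i]], "session_id") %||% sprintf("session_%03d", i), "")
  grp <- groups %||% vapply(features, function(f)
    as.character(attr(f, "group") %||% NA_character_), "")
  df <- as.data.frame(do.call(rbind, lapply(features, as.numeric)))
  if (!length(features)) df <- as.data.frame(matrix(numeric(), 0L, 17L))
  names(df) <- canon
  df <- cbind(data.frame(session_id = as.character(ids),
                         group = as.character(grp),
                         stringsAsFactors = FALSE), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with `session_id`, `group` and the 17 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("session_id", "group", feature_names()), names(df))
  if (length(miss))
    stop("read_feature_table: missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read sensor calibration point correspondences
#'
#' CSV with columns `x_src,y_src,z_src,x_dst,y_dst,z_dst`: the same physical
#' points (e.g. chessboard corners) expressed in the source and destination
#' sensor frames.
#'
#' @param path CSV path.
#' @return list with `src` and `dst` N x 3 matrices.
#' @export
read_calibration_points <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("x_src", "y_src", "z_src", "x_dst", "y_dst", "z_dst")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_calibration_points: missing column(s): ",
         paste(miss, collapse = ", "))
  list(src = as.matrix(df[, need[1:3]]), dst = as.matrix(df[, need[4:6]]))
}

#' Read a 1-D synchronization signal
#'
#' Single-column CSV (header `value`) preceded by a comment line
#' `# rate=<Hz>`; typically an audio- or motion-energy envelope containing the
#' shared clap event.
#'
#' @param path CSV path.
#' @return list with `samples` (numeric vector) and `rate` (Hz).
#' @export
read_sync_signal <- function(path) {
  hdr <- readLines(path, n = 5L)
  m <- grep("^#\\s*rate\\s*=", hdr, value = TRUE)
  if (!length(m))
    stop("read_sync_signal: \"", path, "\" lacks a '# rate=<Hz>' header line")
  rate <- as.numeric(sub("^#\\s*rate\\s*=\\s*", "", m[1L]))
  if (!is.finite(rate) || rate <= 0)
    stop("read_sync_signal: invalid rate in \"", path, "\"")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  list(samples = as.numeric(df[[1L]]), rate = rate)
}

#' Write a 1-D synchronization signal in the [read_sync_signal()] format
#' @param samples numeric vector.
#' @param rate sampling rate in Hz.
#' @param path destination CSV.
#' @export
write_sync_signal <- function(samples, rate, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%.10g", rate), con)
  write.csv(data.frame(value = samples), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
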