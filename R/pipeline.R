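#' End-to-end feature extraction for one session directory
#'
#' Orchestrates calibrate -> align -> extract for one recorded session. The
#' directory must contain two skeleton files, `mother.csv`/`mother.xml` and
#' `infant.csv`/`infant.xml`, and may contain `calibration.csv` (point
#' correspondences, infant-sensor to common frame) and `sync_mother.csv` /
#' `sync_infant.csv` (synchronization envelopes). Without calibration files
#' the streams are assumed co-registered; without sync files, clock-aligned.
#' Deterministic: a run manifest (config snapshot, input digests, stage
#' timings, package version) accompanies the feature vector.
#'
#' @param session_dir directory with the session's input files.
#' @param config an [extraction_config()].
#' @param rate common resampling rate in Hz.
#' @param max_lag synchronization search half-width in seconds.
#' @param output_dir if non-`NULL`, write `features.csv` and `manifest.json`
#'   there.
#' @param session_id,group identifiers recorded in the feature table.
#' @return list with `features` (a `motion_feature_set`), `recording` and
#'   `manifest`.
#' @export
run_extract <- function(session_dir, config = extraction_config(), rate = 30,
                        max_lag = 5, output_dir = NULL,
                        session_id = basename(session_dir), group = NA) {
  find_input <- function(stem, required = TRUE) {
    for (ext in c("csv", "xml")) {
      p <- file.path(session_dir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
    if (required)
      stop("run_extract: missing input \"", stem, ".csv\" (or .xml) in ",
           session_dir, "; expected mother.*, infant.* skeleton files")
    NULL
  }
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  mother_path <- find_input("mother")
  infant_path <- find_input("infant")
  calib_path <- find_input("calibration", required = FALSE)
  sync_m_path <- find_input("sync_mother", required = FALSE)
  sync_i_path <- find_input("sync_infant", required = FALSE)

  streams <- clock("read", list(
    mother = read_skeleton_stream(mother_path, partner = "mother"),
    infant = read_skeleton_stream(infant_path, partner = "infant")))
  mother <- streams$mother
  infant <- streams$infant
  xf <- clock("calibrate", {
    if (!is.null(calib_path)) {
      pts <- read_calibration_points(calib_path)
      estimate_rigid_transform(pts$src, pts$dst)
    } else rigid_transform()
  })
  ta <- clock("synchronize", {
    if (!is.null(sync_m_path) && !is.null(sync_i_path)) {
      sm <- read_sync_signal(sync_m_path)
      si <- read_sync_signal(sync_i_path)
      if (abs(sm$rate - si$rate) > 1e-9)
        stop("run_extract: sync signals have different rates")
      estimate_temporal_offset(sm$samples, si$samples, sm$rate, max_lag)
    } else structure(list(offset = 0, confidence = NA_real_),
                     class = "temporal_alignment")
  })
  dyad <- clock("align", align_dyad(mother, infant, xf, ta, rate))
  features <- clock("extract",
                    extract_feature_vector(dyad, config,
                                           session_id = session_id,
                                           group = group))
  manifest <- list(
    session_dir = session_dir,
    inputs = as.list(tools::md5sum(c(mother_path, infant_path,
                                     calib_path %||% character(),
                                     sync_m_path %||% character(),
                                     sync_i_path %||% character()))),
    config = unclass(config),
    rate = rate,
    temporal_offset = ta$offset,
    sync_confidence = ta$confidence,
    package_version = as.character(packageVersion("dyadsync")),
    timings = as.list(timings))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(list(features), file.path(output_dir, "features.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(features = features, recording = dyad, manifest = manifest)
}

#' Validate a feature table against rated composites and group labels
#'
#' Runs the two validation analyses on an extracted feature table: the
#' Spearman/Holm correlation report against the eight CIB composites, and
#' linear-SVM group classification with stratified k-fold cross-validation.
#'
#' @param features data.frame as from [read_feature_table()] (needs
#'   `session_id` and the 17 canonical columns; a `group` column supplies
#'   labels when `labels` is `NULL`).
#' @param cib data.frame with `session_id` and the eight composite columns;
#'   `NULL` skips the correlation stage.
#' @param labels binary group labels; default taken from `features$group`.
#' @param k,seed cross-validation folds and shuffle seed.
#' @param family Holm family, see [correlate_features_with_cib()].
#' @param output_dir if non-`NULL`, write `correlations.csv` (long format)
#'   and `classification.json` there.
#' @return list with `report` (a `correlation_report` or `NULL`) and
#'   `classification` (a `classification_result`).
#' @export
run_validate <- function(features, cib = NULL, labels = NULL, k = 15,
                         seed = 1, family = "per_composite",
                         output_dir = NULL) {
  labels <- labels %||% features$group
  if (is.null(labels))
    stop("run_validate: no labels given and no `group` column present")
  report <- if (!is.null(cib))
    correlate_features_with_cib(features, cib, family = family)
  classification <- classify_dyads(features[, feature_names(), drop = FALSE],
                                   labels, k = k, seed = seed)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report)) {
      long <- data.frame(
        feature = rep(rownames(report$rho), times = ncol(report$rho)),
        composite = rep(colnames(report$rho), each = nrow(report$rho)),
        rho = as.numeric(report$rho),
        p_raw = as.numeric(report$p_raw),
        p_holm = as.numeric(report$p_holm))
      write.csv(long, file.path(output_dir, "correlations.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(k = classification$k, seed = classification$seed,
           fold_accuracies = classification$fold_accuracies,
           total_accuracy = classification$total_accuracy,
           training_accuracy = classification$training_accuracy,
           confusion = as.data.frame(classification$confusion)),
      file.path(output_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, classification = classification)
}
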