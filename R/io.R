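#' Write a marker trajectory set to CSV
#'
#' Flat CSV with header `frame,t_s,m01_x,m01_y,m01_z,...`; units cm, frame
#' numbering 0-based. Values are written with full precision so that a
#' write/read round trip reproduces the array bitwise.
#'
#' @param tracks A `marker_tracks` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "marker_tracks"))
  pos <- tracks$positions
  nm <- dim(pos)[2]
  df <- data.frame(frame = seq_len(dim(pos)[1]) - 1L, t_s = tracks$time_s)
  for (i in seq_len(nm)) {
    df[[sprintf("m%02d_x", i)]] <- pos[, i, 1]
    df[[sprintf("m%02d_y", i)]] <- pos[, i, 2]
    df[[sprintf("m%02d_z", i)]] <- pos[, i, 3]
  }
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write marker tracks to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a marker trajectory CSV
#'
#' @param path Marker-coordinate CSV written by [write_marker_tracks()] (or
#'   any file with the documented `frame,t_s,mNN_x/y/z` header).
#' @param frame_rate_hz Frame rate; if `NULL`, inferred from `t_s`.
#' @param metadata Optional named list of trial metadata (individual, sex,
#'   age_class, temperature_C, handedness, ...).
#' @return A `marker_tracks` object.
#' @export
read_marker_tracks <- function(path, frame_rate_hz = NULL, metadata = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "t_s")
  if (!all(need %in% names(df))) {
    stop("'", path, "' is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  mcols <- grep("^m[0-9]+_[xyz]$", names(df), value = TRUE)
  ids <- sort(unique(sub("^m([0-9]+)_[xyz]$", "\\1", mcols)))
  if (length(ids) == 0) stop("'", path, "' contains no marker columns (mNN_x/y/z)")
  nm <- length(ids)
  for (id in ids) {
    miss <- setdiff(paste0("m", id, "_", c("x", "y", "z")), names(df))
    if (length(miss)) stop("'", path, "' is missing columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(df)
  pos <- array(NA_real_, dim = c(n, nm, 3))
  for (i in seq_len(nm)) {
    pos[, i, 1] <- df[[paste0("m", ids[i], "_x")]]
    pos[, i, 2] <- df[[paste0("m", ids[i], "_y")]]
    pos[, i, 3] <- df[[paste0("m", ids[i], "_z")]]
  }
  if (is.null(frame_rate_hz)) frame_rate_hz <- 1 / stats::median(diff(df$t_s))
  out <- list(positions = pos, time_s = df$t_s, frame_rate_hz = frame_rate_hz,
              metadata = metadata)
  class(out) <- "marker_tracks"
  out
}

#' Write a complete synthetic fixture set
#'
#' Writes one marker-coordinate CSV per trial, a trial metadata CSV, a
#' morphometrics CSV and a ground-truth JSON sidecar. Everything round-trips
#' losslessly through [read_marker_tracks()] / [utils::read.csv()].
#'
#' @param gt_list List of [trial_ground_truth()] objects (may be empty).
#' @param morpho_cfg A [morpho_gen_config()], or `NULL` to skip morphometrics.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a manifest list of the files written.
#' @export
write_fixture_set <- function(gt_list, morpho_cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory '", out_dir, "'")
  manifest <- list(trials = character(0))
  meta <- NULL
  truth <- list()
  for (gt in gt_list) {
    tr <- generate_trajectory(gt)
    f <- file.path(out_dir, paste0(gt$trial_id, "_markers.csv"))
    write_marker_tracks(tr, f)
    manifest$trials <- c(manifest$trials, f)
    meta <- rbind(meta, data.frame(
      trial_id = gt$trial_id, individual = gt$individual, sex = gt$sex,
      age_class = gt$age_class, temperature_C = gt$temperature_C,
      handedness = gt$wave$handedness, frame_rate_hz = gt$frame_rate_hz,
      representative = TRUE, file = basename(f)))
    truth[[gt$trial_id]] <- c(unclass(gt$wave),
                              list(stride_cm = gt$stride_cm,
                                   centroid_speed_cm_s = gt$centroid_speed_cm_s,
                                   svl_cm = gt$svl_cm, n_frames = gt$n_frames,
                                   noise_sd_cm = gt$noise_sd_cm, seed = gt$seed))
  }
  if (!is.null(meta)) {
    manifest$metadata <- file.path(out_dir, "trial_metadata.csv")
    utils::write.csv(meta, manifest$metadata, row.names = FALSE)
  }
  if (!is.null(morpho_cfg)) {
    morpho <- generate_morphometrics(morpho_cfg)
    manifest$morphometrics <- file.path(out_dir, "morphometrics.csv")
    utils::write.csv(morpho, manifest$morphometrics, row.names = FALSE)
  }
  if (length(truth)) {
    manifest$ground_truth <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(truth, manifest$ground_truth, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(manifest)
}

#' Read the trial metadata table
#'
#' @param path CSV with columns `trial_id`, `individual`, `sex`, `age_class`,
#'   `temperature_C`, `handedness`, `frame_rate_hz`, `representative`, `file`.
#' @return Data frame.
#' @export
read_trial_metadata <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "individual", "handedness", "frame_rate_hz", "file")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("'", path, "' is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a morphometrics table
#'
#' @param path CSV with one row per individual; must contain `id`, `sex`,
#'   `age_class` and `svl_cm`.
#' @return Data frame.
#' @export
read_morphometrics <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "sex", "age_class", "svl_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("'", path, "' is missing columns: ", paste(miss, collapse = ", "))
  df
}
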