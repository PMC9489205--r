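#' Construct a landmark pose track
#'
#' A `pose_track` holds per-frame pixel coordinates and tracking confidence for
#' a named set of body parts from a single camera, as produced by markerless
#' pose estimation (DeepLabCut-style). Missing samples are `NA` ("gaps"), never
#' zeros.
#'
#' @param landmarks Named list; each element a data.frame with numeric columns
#'   `x`, `y` (pixels) and `confidence` (in `[0, 1]`, `NA` allowed on gaps).
#'   All landmarks must have the same number of frames.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param camera_id One of `"side"`, `"top"`, `"left_eye"`, `"right_eye"`.
#' @param frames Integer frame indices (0-based, strictly increasing). Default
#'   `0:(n-1)`.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(landmarks, sample_rate, camera_id = "side",
                       frames = NULL) {
  if (!is.list(landmarks) || length(landmarks) == 0L ||
      is.null(names(landmarks)) || any(!nzchar(names(landmarks)))) {
    stop("`landmarks` must be a non-empty named list")
  }
  lens <- vapply(landmarks, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all landmark series must share the same length")
  }
  n <- lens[[1]]
  landmarks <- lapply(landmarks, function(lm) {
    stopifnot(all(c("x", "y", "confidence") %in% names(lm)))
    data.frame(x = as.numeric(lm$x), y = as.numeric(lm$y),
               confidence = as.numeric(lm$confidence))
  })
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  camera_id <- match.arg(camera_id, c("side", "top", "left_eye", "right_eye"))
  if (is.null(frames)) frames <- seq_len(n) - 1L
  frames <- as.integer(frames)
  if (length(frames) != n || (n > 1L && any(diff(frames) <= 0L))) {
    stop("`frames` must be strictly increasing and match the series length")
  }
  structure(
    list(camera_id = camera_id, sample_rate = sample_rate,
         frames = frames, landmarks = landmarks),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> camera=%s  %d frames @ %g Hz  landmarks: %s\n",
              x$camera_id, length(x$frames), x$sample_rate,
              paste(names(x$landmarks), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a pose track
#' @param track A `pose_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) length(track$frames)

#' Read a DeepLabCut-dialect pose CSV
#'
#' Parses the three-row DLC header (scorer / bodyparts / coords) followed by
#' one row per frame, first column the frame index. Blank cells become `NA`
#' gaps. Column triplets must be `x`, `y`, `likelihood` per body part.
#'
#' @param path Path to the CSV file.
#' @param sample_rate Sampling rate in Hz to attach (not stored in DLC files).
#' @param camera_id Camera label to attach.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, sample_rate = 60, camera_id = "side") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) stop("malformed header: fewer than 3 header rows")
  split_row <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  r1 <- split_row(hdr[1]); r2 <- split_row(hdr[2]); r3 <- split_row(hdr[3])
  if (tolower(r1[1]) != "scorer") {
    stop("malformed header row 1: expected leading 'scorer', got '", r1[1], "'")
  }
  if (tolower(r2[1]) != "bodyparts") {
    stop("malformed header row 2: expected leading 'bodyparts', got '", r2[1], "'")
  }
  if (tolower(r3[1]) != "coords") {
    stop("malformed header row 3: expected leading 'coords', got '", r3[1], "'")
  }
  bp <- r2[-1]; coords <- tolower(r3[-1])
  if (length(bp) != length(coords) || length(bp) %% 3L != 0L) {
    stop("malformed header: body-part/coords columns not in x,y,likelihood triplets")
  }
  key <- paste(bp, coords, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated body-part+coord column: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "numeric", na.strings = c("", "NA"))
  if (ncol(dat) != length(bp) + 1L) {
    stop("data rows have ", ncol(dat), " columns; header implies ", length(bp) + 1L)
  }
  frames <- as.integer(dat[[1]])
  parts <- unique(bp)
  landmarks <- lapply(parts, function(p) {
    cols <- function(coord) which(bp == p & coords == coord) + 1L
    ix <- cols("x"); iy <- cols("y"); il <- cols("likelihood")
    if (length(ix) != 1L || length(iy) != 1L || length(il) != 1L) {
      stop("body part '", p, "' lacks a complete x/y/likelihood triplet")
    }
    data.frame(x = dat[[ix]], y = dat[[iy]], confidence = dat[[il]])
  })
  names(landmarks) <- parts
  pose_track(landmarks, sample_rate = sample_rate, camera_id = camera_id,
             frames = frames)
}

#' Write a pose track as a DeepLabCut-dialect CSV
#'
#' Inverse of [read_pose_table()]; gaps serialize as empty cells.
#'
#' @param track A `pose_track`.
#' @param path Output path.
#' @param scorer Scorer label for the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, scorer = "ethokit") {
  stopifnot(inherits(track, "pose_track"))
  parts <- names(track$landmarks)
  if (length(parts) == 0L) stop("pose track has no landmarks: nothing to write")
  ncol3 <- 3L * length(parts)
  h1 <- paste(c("scorer", rep(scorer, ncol3)), collapse = ",")
  h2 <- paste(c("bodyparts", rep(parts, each = 3L)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
              collapse = ",")
  mat <- do.call(cbind, lapply(track$landmarks, function(lm) {
    cbind(lm$x, lm$y, lm$confidence)
  }))
  body <- cbind(track$frames, mat)
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, format = "g", digits = 15))
  rows <- apply(body, 1L, function(r) paste(fmt(r), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(h1, h2, h3, rows), con)
  invisible(path)
}

#' Read / write a session trial-metadata table
#'
#' One row per trial with columns `trial_id`, `session_id`, `animal_id`,
#' `ocular_condition` (binocular|monocular), `laser` (off|on|none),
#' `gap_distance_cm`, `platform_width_cm`, `outcome`
#' (success|failure|abort), `start_frame`, `jump_frame`, `land_frame`.
#' Frame indices are 0-based; the decision period is the half-open
#' `[start_frame, jump_frame)`.
#'
#' @param path CSV path.
#' @return A data.frame of trial records.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
  df
}

#' @rdname read_trial_table
#' @param trials Trial-record data.frame.
#' @export
write_trial_table <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Validate a trial-record table
#'
#' Checks required columns, outcome/condition levels, and frame ordering
#' (`start_frame < jump_frame <= land_frame`).
#'
#' @param trials Data.frame of trial records.
#' @return `trials`, invisibly.
#' @export
validate_trials <- function(trials) {
  need <- c("trial_id", "session_id", "animal_id", "ocular_condition", "laser",
            "gap_distance_cm", "platform_width_cm", "outcome",
            "start_frame", "jump_frame", "land_frame")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  if (!all(trials$ocular_condition %in% c("binocular", "monocular"))) {
    stop("ocular_condition must be binocular|monocular")
  }
  if (!all(trials$laser %in% c("off", "on", "none"))) stop("laser must be off|on|none")
  if (!all(trials$outcome %in% c("success", "failure", "abort"))) {
    stop("outcome must be success|failure|abort")
  }
  if (any(trials$gap_distance_cm <= 0) || any(trials$platform_width_cm <= 0)) {
    stop("gap_distance_cm and platform_width_cm must be positive")
  }
  bad <- trials$start_frame >= trials$jump_frame | trials$jump_frame > trials$land_frame
  if (any(bad)) {
    stop("frame ordering violated (need start < jump <= land) for trial(s): ",
         paste(trials$trial_id[bad], collapse = ", "))
  }
  invisible(trials)
}
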