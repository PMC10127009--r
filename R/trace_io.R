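#' Write a midline trace to a delimited text file
#'
#' One row per digitised point: `frame_index` (1-based), `time_s`, `part`
#' (`head` or `tail`), `arclength_um`, `x_um`, `y_um`. Comma-separated,
#' UTF-8, header row required; numeric values keep at least 9 significant
#' digits so that a read/write round trip is lossless to float precision.
#'
#' @param trace A [midline_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "midline_trace"))
  rows <- lapply(seq_along(trace$frames), function(k) {
    fr <- trace$frames[[k]]
    do.call(rbind, lapply(c("head", "tail"), function(part) {
      m <- fr[[part]]
      data.frame(frame_index = k, time_s = fr$time, part = part,
                 arclength_um = m[, 1], x_um = m[, 2], y_um = m[, 3])
    }))
  })
  df <- do.call(rbind, rows)
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("refusing to write non-finite coordinates", call. = FALSE)
  write_table(df, path)
  tc_log("write_trace", "%d frames, %d rows -> %s",
         length(trace$frames), nrow(df), path)
  invisible(path)
}

#' Read a midline trace from a delimited text file
#'
#' Accepts the schema written by [write_trace()]. Row order is immaterial:
#' points are reordered by arc length within each frame and part. The frame
#' rate is inferred from the time stamps. Malformed input (missing columns,
#' non-monotone time, duplicate (frame, part, arclength) records) is
#' rejected with a message naming the offending record.
#'
#' @param path Input file path.
#' @return A [midline_trace()].
#' @export
read_trace <- function(path) {
  df <- read_table(path, c("frame_index", "time_s", "part",
                           "arclength_um", "x_um", "y_um"))
  if (nrow(df) == 0) stop("no frames", call. = FALSE)
  bad <- !df$part %in% c("head", "tail")
  if (any(bad))
    stop("unknown part '", df$part[which(bad)[1]], "' at data row ",
         which(bad)[1], call. = FALSE)
  key <- paste(df$frame_index, df$part, signif(df$arclength_um, 12))
  if (anyDuplicated(key))
    stop("duplicate (frame, part, arclength) record at data row ",
         which(duplicated(key))[1], call. = FALSE)
  idx <- sort(unique(df$frame_index))
  tmap <- tapply(df$time_s, df$frame_index, function(v) v[1])
  times <- as.numeric(tmap[as.character(idx)])
  if (any(diff(times) <= 0))
    stop("non-monotone time stamps across frames", call. = FALSE)
  fps <- if (length(times) > 1) 1 / median(diff(times)) else 1
  frames <- lapply(seq_along(idx), function(j) {
    sub <- df[df$frame_index == idx[j], ]
    fr <- list(time = times[j])
    for (part in c("head", "tail")) {
      p <- sub[sub$part == part, ]
      p <- p[order(p$arclength_um), ]
      fr[[part]] <- cbind(arclength_um = p$arclength_um,
                          x_um = p$x_um, y_um = p$y_um)
    }
    fr
  })
  tc_log("read_trace", "%d frames, %d rows <- %s (fps %.6g)",
         length(frames), nrow(df), path, fps)
  midline_trace(frames, fps)
}

#' Write a mid-piece track to a delimited text file
#'
#' One row per frame: `frame_index`, `time_s`, `x_um`, `y_um`.
#'
#' @param track A [midpiece_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "midpiece_track"))
  df <- data.frame(frame_index = seq_len(nrow(track$positions)),
                   time_s = track$time,
                   x_um = track$positions[, 1], y_um = track$positions[, 2])
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("refusing to write non-finite coordinates", call. = FALSE)
  write_table(df, path)
  invisible(path)
}

#' Read a mid-piece track from a delimited text file
#'
#' @param path Input file path.
#' @return A [midpiece_track()].
#' @export
read_track <- function(path) {
  df <- read_table(path, c("frame_index", "time_s", "x_um", "y_um"))
  if (nrow(df) == 0) stop("no frames", call. = FALSE)
  df <- df[order(df$frame_index), ]
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time stamps", call. = FALSE)
  fps <- if (nrow(df) > 1) 1 / median(diff(df$time_s)) else 1
  midpiece_track(cbind(df$x_um, df$y_um), fps)
}

#' Read a run configuration (YAML or JSON)
#'
#' Loads analysis settings and fills defaults: `station_spacing` 1 um,
#' `window_frames` 10, `beat_station` 5 um, `alpha` 0.01, `turn_threshold`
#' 90 deg/s, `fps` 150, `seed` 1. Format is chosen by file extension
#' (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(list(
    species_label = "Paramacrobiotus sp.",
    station_spacing = 1, window_frames = 10L, beat_station = 5,
    alpha = 0.01, turn_threshold = 90, fps = 150, seed = 1L,
    output_dir = "."), user)
  if (cfg$window_frames < 2) stop("window_frames must be >= 2", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  check_positive(cfg$beat_station, "beat_station")
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration or ground truth sidecar
#'
#' @param x A `run_config` or [ground_truth()] object (any plain list works).
#' @param path Output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(x, path) {
  strip <- function(v) if (is.list(v)) lapply(unclass(v), strip) else v
  x <- strip(x)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

# -- internals ---------------------------------------------------------------

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

read_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("no frames", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df
}

# stage-tagged logging; silence with options(tardicasa.verbose = FALSE)
tc_log <- function(stage, fmt, ...) {
  if (isFALSE(getOption("tardicasa.verbose", FALSE))) return(invisible())
  message(sprintf("[tardicasa:%s] %s", stage, sprintf(fmt, ...)))
}
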