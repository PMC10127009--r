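#' Resample a midline polyline at fixed arc-length stations
#'
#' Places stations every `spacing` micrometres of cumulative chord length
#' along the ordered polyline, from the base (station 0, kept as a reference
#' point) up to the largest multiple of the spacing not exceeding the total
#' length. Station points are linear interpolations between input vertices.
#' Tangent angles are secant directions and signed curvature is the turn
#' angle between consecutive unit secants divided by the spacing
#' (three-point discrete curvature), positive for counter-clockwise turning.
#' The last station only has a one-sided estimate and is flagged as a
#' boundary station; boundary stations are excluded from downstream
#' variance statistics.
#'
#' @param points Numeric matrix (n x 2) of (x, y) in um, ordered from the
#'   part base outward; a 3-column matrix with a leading arc-length column
#'   (as stored in a [midline_trace()]) is also accepted.
#' @param spacing Station spacing in micrometres (default 1).
#' @param part Optional part label (`"head"` or `"tail"`) carried through.
#' @return An object of class `station_frame`: list with `part`, `spacing`,
#'   `stations` (um, including station 0), `points`, `tangent_angle`,
#'   `curvature` and logical `boundary` per station.
#' @export
resample_stations <- function(points, spacing = 1, part = NA_character_) {
  check_positive(spacing, "spacing")
  points <- as.matrix(points)
  if (ncol(points) == 3) points <- points[, 2:3, drop = FALSE]
  if (ncol(points) != 2) stop("points must have two columns", call. = FALSE)
  if (nrow(points) < 2) stop("polyline needs at least two points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0))
    stop("degenerate polyline: repeated consecutive points", call. = FALSE)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < 2 * spacing)
    stop("polyline shorter than two station spacings", call. = FALSE)
  k_max <- floor(total / spacing + 1e-9)
  st <- (0:k_max) * spacing
  x <- approx(cum, points[, 1], xout = st)$y
  y <- approx(cum, points[, 2], xout = st)$y
  station_frame(part, spacing, st, cbind(x, y))
}

# build a station_frame from already-placed station points
station_frame <- function(part, spacing, stations, pts) {
  n <- length(stations)
  if (n < 3) stop("need at least 3 stations", call. = FALSE)
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  if (any(dx == 0 & dy == 0))
    stop("coincident station points", call. = FALSE)
  sec <- atan2(dy, dx)                       # n-1 secant angles
  turn <- wrap_angle(diff(sec))              # turn at interior vertices 1..n-2
  curv <- c(NA, turn, turn[length(turn)]) / spacing
  tang <- c(sec[1], wrap_angle(sec[-1] - sec[-(n - 1)]) / 2 + sec[-(n - 1)],
            sec[n - 1])
  boundary <- c(TRUE, rep(FALSE, n - 2), TRUE)
  structure(list(part = part, spacing = spacing, stations = stations,
                 points = unname(pts), tangent_angle = tang,
                 curvature = curv, boundary = boundary),
            class = "station_frame")
}

#' @export
print.station_frame <- function(x, ...) {
  cat(sprintf("Station frame (%s): %d stations at %g um spacing\n",
              ifelse(is.na(x$part), "unlabelled", x$part),
              length(x$stations) - 1, x$spacing))
  invisible(x)
}

#' Register a station frame in the body frame
#'
#' Rigidly transforms the station points so the base (station 0) sits at
#' the origin and the base secant (station 0 to station 1) points along +x.
#' The shape is otherwise unchanged; curvature is unaffected. Optionally the
#' registered coordinates can also be rescaled by the total filament length,
#' giving dimensionless waveforms comparable across cells of different size.
#'
#' @param sf A `station_frame` with at least 3 stations.
#' @param rescale If `TRUE`, divide registered coordinates by the arc length
#'   of the last station (default `FALSE`).
#' @return An object of class `normalized_waveform`: `stations` and
#'   registered `points` (base at (0,0), base tangent along +x).
#' @export
normalize_waveform <- function(sf, rescale = FALSE) {
  stopifnot(inherits(sf, "station_frame"))
  if (length(sf$stations) < 3) stop("need at least 3 stations", call. = FALSE)
  p <- sweep(sf$points, 2, sf$points[1, ])
  ang <- atan2(p[2, 2], p[2, 1])
  rot <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  q <- p %*% t(rot)
  if (rescale) q <- q / sf$stations[length(sf$stations)]
  structure(list(part = sf$part, stations = sf$stations, points = q,
                 rescaled = rescale),
            class = "normalized_waveform")
}

#' Signed curvature profile of a station frame
#'
#' Returns the per-station discrete signed curvature (1/um): the turn angle
#' between consecutive unit secants divided by the station spacing, exact in
#' the circle limit. Counter-clockwise turning is positive. Endpoint
#' stations carry one-sided estimates and are flagged `boundary`.
#'
#' @param sf A `station_frame`.
#' @return A data frame with columns `station_um`, `curvature`, `boundary`.
#' @export
curvature_profile <- function(sf) {
  stopifnot(inherits(sf, "station_frame"))
  data.frame(station_um = sf$stations, curvature = sf$curvature,
             boundary = sf$boundary)
}

#' Collect per-station curvature across a window of frames
#'
#' Resamples one part of the trace in every frame of a sequential window and
#' assembles the signed curvature samples into a stations x frames matrix.
#' Only stations interior in every frame of the window are kept (filament
#' length can fluctuate under coordinate noise), so the matrix has no
#' missing values; station 0 and boundary stations are excluded.
#'
#' @param trace A [midline_trace()].
#' @param part `"head"` or `"tail"`.
#' @param start_frame First frame of the window (1-based, default 1).
#' @param window_frames Number of sequential frames (default 10).
#' @param spacing Station spacing in um (default 1).
#' @param condition_label Free-text label carried into reports.
#' @return An object of class `station_series`: `part`, `stations`,
#'   `samples` (matrix stations x frames), `window_frames`,
#'   `condition_label`.
#' @export
collect_series <- function(trace, part = c("tail", "head"), start_frame = 1,
                           window_frames = 10, spacing = 1,
                           condition_label = part) {
  part <- match.arg(part)
  stopifnot(inherits(trace, "midline_trace"))
  last <- start_frame + window_frames - 1
  if (start_frame < 1 || last > length(trace$frames))
    stop("window [", start_frame, ", ", last, "] exceeds trace of ",
         length(trace$frames), " frames", call. = FALSE)
  sfs <- lapply(trace$frames[start_frame:last], function(fr)
    resample_stations(fr[[part]], spacing = spacing, part = part))
  n_int <- vapply(sfs, function(sf) sum(!sf$boundary), integer(1))
  k <- min(n_int)
  if (k < 1) stop("no interior stations common to the window", call. = FALSE)
  samples <- vapply(sfs, function(sf) sf$curvature[!sf$boundary][1:k],
                    numeric(k))
  samples <- matrix(samples, nrow = k)
  structure(list(part = part, stations = (1:k) * spacing, samples = samples,
                 window_frames = window_frames,
                 condition_label = condition_label[1], spacing = spacing),
            class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("Station curvature series (%s, '%s'): %d stations x %d frames\n",
              x$part, x$condition_label, nrow(x$samples), ncol(x$samples)))
  invisible(x)
}

#' Split a head curvature series into nucleus and acrosome regions
#'
#' Stations with arc length not exceeding the morphology's nucleus length
#' belong to the coiled nucleus; the remainder is the acrosome. Only head
#' series can be split; the tail has no such partition.
#'
#' @param series A `station_series` with `part == "head"`.
#' @param morphology A [sperm_morphology()] providing `nucleus_length`.
#' @return A list with `nucleus` and `acrosome` station series (the
#'   `acrosome` element may hold zero stations, with a warning, when the
#'   digitised head is shorter than the nominal nucleus).
#' @export
split_head_regions <- function(series, morphology) {
  stopifnot(inherits(series, "station_series"),
            inherits(morphology, "sperm_morphology"))
  if (series$part != "head")
    stop("can only split a head series into nucleus/acrosome", call. = FALSE)
  in_nuc <- series$stations <= morphology$nucleus_length + 1e-9
  if (all(in_nuc))
    warning("digitised head does not extend beyond the nucleus; ",
            "acrosome region is empty", call. = FALSE)
  list(nucleus = subset_series(series, in_nuc, "nucleus"),
       acrosome = subset_series(series, !in_nuc, "acrosome"))
}

subset_series <- function(series, keep, label) {
  structure(list(part = series$part, stations = series$stations[keep],
                 samples = series$samples[keep, , drop = FALSE],
                 window_frames = series$window_frames,
                 condition_label = paste(series$condition_label, label),
                 spacing = series$spacing),
            class = "station_series")
}

#' Export a station series as a long-format data frame
#'
#' @param series A `station_series`.
#' @return Data frame with `part`, `station_um`, `frame_index`,
#'   `curvature_per_um`.
#' @export
series_to_df <- function(series) {
  stopifnot(inherits(series, "station_series"))
  data.frame(part = series$part,
             station_um = rep(series$stations, ncol(series$samples)),
             frame_index = rep(seq_len(ncol(series$samples)),
                               each = nrow(series$samples)),
             curvature_per_um = as.vector(series$samples))
}

# wrap angle differences into (-pi, pi]
wrap_angle <- function(a) {
  w <- a %% (2 * pi)
  w - 2 * pi * (w > pi)
}
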