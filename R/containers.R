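#' Midline trace container
#'
#' Per-frame digitised midlines of one spermatozoon: for every frame, two
#' ordered point sequences running outward from the mid-piece junction, one
#' for the head and one for the tail. Coordinates are micrometres in a fixed
#' laboratory frame with mathematical y (counter-clockwise angles positive).
#'
#' @param frames List of frames; each frame is a list with elements `time`
#'   (seconds) and `head`/`tail`, each a numeric matrix with columns
#'   `arclength_um`, `x_um`, `y_um` ordered from the base outward.
#' @param fps Sampling rate in frames per second.
#' @return An object of class `midline_trace`.
#' @export
midline_trace <- function(frames, fps) {
  check_positive(fps, "fps")
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0))
    stop("frame time stamps must be strictly increasing", call. = FALSE)
  for (fr in frames) {
    for (part in c("head", "tail")) {
      m <- fr[[part]]
      if (!is.matrix(m) || ncol(m) != 3)
        stop("each frame part must be a 3-column matrix ",
             "(arclength_um, x_um, y_um)", call. = FALSE)
      if (any(!is.finite(m)))
        stop("non-finite coordinate in ", part, " points", call. = FALSE)
    }
  }
  structure(list(frames = frames, fps = fps), class = "midline_trace")
}

#' @export
print.midline_trace <- function(x, ...) {
  np <- nrow(x$frames[[1]]$head) + nrow(x$frames[[1]]$tail)
  cat(sprintf("Midline trace: %d frames at %g fps, %d points/frame\n",
              length(x$frames), x$fps, np))
  invisible(x)
}

#' Mid-piece track container
#'
#' Time series of the tracked mid-piece position, the landmark from which
#' curvilinear velocity and the swimming-path classification are computed.
#'
#' @param positions Numeric matrix (frames x 2) of (x, y) in micrometres.
#' @param fps Sampling rate in frames per second.
#' @return An object of class `midpiece_track`.
#' @export
midpiece_track <- function(positions, fps) {
  check_positive(fps, "fps")
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must have two columns", call. = FALSE)
  if (any(!is.finite(positions)))
    stop("non-finite coordinate in track", call. = FALSE)
  structure(list(positions = positions, fps = fps,
                 time = (seq_len(nrow(positions)) - 1) / fps),
            class = "midpiece_track")
}

#' @export
print.midpiece_track <- function(x, ...) {
  cat(sprintf("Mid-piece track: %d frames at %g fps\n",
              nrow(x$positions), x$fps))
  invisible(x)
}
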