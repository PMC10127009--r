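#' Simulate a swimming spermatozoon with known kinematic ground truth
#'
#' Builds each frame's midline in a body frame and places it rigidly on a
#' swimming path. The shape model imposes a signed-curvature travelling wave
#' kappa(s, t) = A(s) sin(2 pi s / wavelength - 2 pi frequency t + phase0)
#' on both filaments, with A(s) equal to the tail amplitude on the tail and
#' the head-factor-scaled amplitude on the head (optionally ramped linearly
#' from the base). The tangent angle is the running integral of kappa over
#' arc length and the midline the running integral of the unit tangent,
#' evaluated on an internal 0.1-um grid so that downstream 1-um station
#' resampling is not limited by generator discretisation. The mid-piece
#' (the shared base point of head and tail) advances with constant
#' curvilinear speed while its heading changes at a constant rate; the body
#' orientation follows the path heading. Swimming is imposed, not emergent:
#' no hydrodynamic propulsion is modelled because the analysis measures
#' kinematics only.
#'
#' Isotropic Gaussian noise of standard deviation `noise_sd` is added
#' independently to every exported coordinate (midline points and track),
#' using the seed carried in the swim parameters, so identical ground truth
#' yields bit-identical output.
#'
#' @param truth A [ground_truth()] object.
#' @param export_spacing Arc-length spacing (um) of the exported midline
#'   points (default 0.25, finer than the 1-um analysis stations).
#' @return A list with elements `trace` ([midline_trace()]) and `track`
#'   ([midpiece_track()]).
#' @examples
#' tr <- simulate_sperm(ground_truth(species_presets("Macrobiotus shonaicus"),
#'                                   swim = swim_parameters(duration = 0.1)))
#' tr$trace
#' @export
simulate_sperm <- function(truth, export_spacing = 0.25) {
  stopifnot(inherits(truth, "ground_truth"))
  check_positive(export_spacing, "export_spacing")
  morph <- truth$morphology; beat <- truth$beat; swim <- truth$swim
  if (swim$fps <= 2 * beat$frequency)
    stop("fps must exceed 2 * frequency (aliasing)", call. = FALSE)

  # frames sample t = 0 .. duration inclusive, so the record's elapsed time
  # (interval count / fps) equals the requested duration exactly
  n_frames <- round(swim$duration * swim$fps) + 1
  if (n_frames < 2) stop("duration too short for one frame interval", call. = FALSE)
  times <- (seq_len(n_frames) - 1) / swim$fps

  # swimming path of the base point; heading psi(t) = omega * t
  omega <- swim$heading_rate * pi / 180
  psi <- omega * times
  if (abs(omega) < 1e-12) {
    base_x <- swim$speed * times
    base_y <- rep(0, n_frames)
  } else {
    base_x <- swim$speed / omega * sin(psi)
    base_y <- swim$speed / omega * (1 - cos(psi))
  }

  ds <- 0.1
  grids <- list(head = body_grid(morph$head_length, ds),
                tail = body_grid(morph$tail_length, ds))
  amp <- list(head = beat$tail_amplitude * beat$head_amplitude_factor,
              tail = beat$tail_amplitude)
  # head and tail trail the mid-piece on either side of the anti-heading
  # direction; the split angle is arbitrary (per-part analyses never use it)
  split <- 0.35
  base_dir <- list(head = pi - split, tail = pi + split)

  exp_s <- list(head = export_stations(morph$head_length, export_spacing),
                tail = export_stations(morph$tail_length, export_spacing))

  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    fr <- list(time = times[k])
    for (part in c("head", "tail")) {
      s <- grids[[part]]
      env <- switch(beat$amplitude_envelope,
                    constant = 1,
                    linear_ramp = s / max(s))
      kap <- amp[[part]] * env *
        sin(2 * pi * s / beat$wavelength -
            2 * pi * beat$frequency * times[k] + beat$phase0)
      theta <- psi[k] + base_dir[[part]] + cumtrapz(s, kap)
      x <- base_x[k] + cumtrapz(s, cos(theta))
      y <- base_y[k] + cumtrapz(s, sin(theta))
      se <- exp_s[[part]]
      pts <- cbind(arclength_um = se,
                   x_um = approx(s, x, xout = se)$y,
                   y_um = approx(s, y, xout = se)$y)
      fr[[part]] <- pts
    }
    frames[[k]] <- fr
  }

  with_seed(swim$seed, {
    if (beat$noise_sd > 0) {
      for (k in seq_len(n_frames)) {
        for (part in c("head", "tail")) {
          np <- nrow(frames[[k]][[part]])
          frames[[k]][[part]][, 2:3] <- frames[[k]][[part]][, 2:3] +
            matrix(rnorm(2 * np, sd = beat$noise_sd), ncol = 2)
        }
      }
      track_xy <- cbind(base_x, base_y) +
        matrix(rnorm(2 * n_frames, sd = beat$noise_sd), ncol = 2)
    } else {
      track_xy <- cbind(base_x, base_y)
    }
  })

  list(trace = midline_trace(frames, swim$fps),
       track = midpiece_track(track_xy, swim$fps))
}

# uniform internal arc-length grid covering [0, len] exactly
body_grid <- function(len, ds) {
  s <- seq(0, len, by = ds)
  if (s[length(s)] < len) s <- c(s, len)
  s
}

export_stations <- function(len, spacing) {
  s <- seq(0, len, by = spacing)
  if (s[length(s)] < len - 1e-9) s <- c(s, len)
  s
}

# cumulative trapezoidal integral of y over x, anchored at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# run code with a local, restorable RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
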