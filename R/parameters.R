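#' Sperm morphology description
#'
#' Describes the two filaments of a tardigrade spermatozoon as seen from the
#' mid-piece: a head part (coiled nucleus plus acrosome) and a tail, both
#' measured in micrometres from their junction with the mid-piece. The
#' nucleus/acrosome boundary is given as an arc-length position from the head
#' base, following the morphometric convention that the nucleus occupies the
#' proximal region and the acrosome the remainder.
#'
#' @param species_label Character label, e.g. `"Paramacrobiotus sp."`.
#' @param head_length Head filament length in micrometres (nucleus + acrosome).
#' @param tail_length Tail filament length in micrometres.
#' @param nucleus_length Arc-length position (um from the head base) of the
#'   nucleus/acrosome boundary; must lie strictly inside the head.
#' @param station_spacing Arc-length sampling interval in micrometres
#'   (default 1, one station per micrometre).
#' @return An object of class `sperm_morphology`.
#' @seealso [species_presets()]
#' @export
sperm_morphology <- function(species_label, head_length, tail_length,
                             nucleus_length, station_spacing = 1) {
  stopifnot(is.character(species_label), length(species_label) == 1)
  check_positive(head_length, "head_length")
  check_positive(tail_length, "tail_length")
  check_positive(nucleus_length, "nucleus_length")
  check_positive(station_spacing, "station_spacing")
  if (nucleus_length >= head_length)
    stop("nucleus_length must be strictly less than head_length", call. = FALSE)
  structure(list(species_label = species_label,
                 head_length = head_length,
                 tail_length = tail_length,
                 nucleus_length = nucleus_length,
                 station_spacing = station_spacing),
            class = "sperm_morphology")
}

#' Beat-wave parameters for the synthetic generator
#'
#' Parameterises the curvature travelling wave imposed on the flagellum:
#' kappa(s, t) = A(s) sin(2 pi s / wavelength - 2 pi frequency t + phase0),
#' where `s` is arc length from the part base. On the tail A(s) equals
#' `tail_amplitude` (times the envelope); on the head it is scaled by
#' `head_amplitude_factor`, modelling the stiffer nucleus/acrosome region that
#' trembles less than the tail.
#'
#' @param frequency Beat frequency in Hz (>= 0).
#' @param wavelength Wavelength of the curvature wave in micrometres.
#' @param tail_amplitude Peak curvature of the wave on the tail, 1/um.
#' @param head_amplitude_factor Dimensionless scale in \[0, 1\] applied to the
#'   wave amplitude on the head.
#' @param amplitude_envelope `"constant"` (default) or `"linear_ramp"`
#'   (amplitude grows linearly from 0 at the base to its nominal value at the
#'   tip), giving station-dependent beat variance.
#' @param phase0 Phase offset in radians at s = 0, t = 0.
#' @param noise_sd Standard deviation (um) of isotropic Gaussian noise added
#'   independently to every exported coordinate.
#' @return An object of class `beat_parameters`.
#' @export
beat_parameters <- function(frequency = 50, wavelength = 24,
                            tail_amplitude = 0.15, head_amplitude_factor = 0.3,
                            amplitude_envelope = c("constant", "linear_ramp"),
                            phase0 = 0, noise_sd = 0) {
  amplitude_envelope <- match.arg(amplitude_envelope)
  check_nonneg(frequency, "frequency")
  check_positive(wavelength, "wavelength")
  check_nonneg(tail_amplitude, "tail_amplitude")
  check_nonneg(noise_sd, "noise_sd")
  if (!is.numeric(head_amplitude_factor) || head_amplitude_factor < 0 ||
      head_amplitude_factor > 1)
    stop("head_amplitude_factor must lie in [0, 1]", call. = FALSE)
  structure(list(frequency = frequency, wavelength = wavelength,
                 tail_amplitude = tail_amplitude,
                 head_amplitude_factor = head_amplitude_factor,
                 amplitude_envelope = amplitude_envelope,
                 phase0 = phase0, noise_sd = noise_sd),
            class = "beat_parameters")
}

#' Rigid swimming parameters for the synthetic generator
#'
#' The cell swims mid-piece first: the base point shared by head and tail
#' advances along a path of constant curvilinear speed whose heading changes
#' at a constant rate (0 deg/s gives a straight path, a nonzero rate a
#' circular turn). Body orientation follows the path heading.
#'
#' @param speed Curvilinear speed of the mid-piece in um/s.
#' @param heading_rate Heading change rate in degrees/s (0 = straight).
#' @param duration Recording duration in seconds.
#' @param fps Sampling rate in frames/s (default 150). Must exceed twice the
#'   beat frequency so the beat is resolved.
#' @param seed Integer seed making the simulation reproducible.
#' @return An object of class `swim_parameters`.
#' @export
swim_parameters <- function(speed = 250, heading_rate = 0, duration = 2,
                            fps = 150, seed = 1L) {
  check_nonneg(speed, "speed")
  check_positive(duration, "duration")
  check_positive(fps, "fps")
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(speed = speed, heading_rate = heading_rate,
                 duration = duration, fps = fps, seed = as.integer(seed)),
            class = "swim_parameters")
}

#' Ground truth bundle for a simulated spermatozoon
#'
#' Collects the morphology, beat and swimming parameters that define one
#' simulated cell. Recovery tests compare pipeline estimates against these
#' known values.
#'
#' @param morphology A [sperm_morphology()].
#' @param beat A [beat_parameters()].
#' @param swim A [swim_parameters()].
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(morphology, beat = beat_parameters(),
                         swim = swim_parameters()) {
  stopifnot(inherits(morphology, "sperm_morphology"),
            inherits(beat, "beat_parameters"),
            inherits(swim, "swim_parameters"))
  if (swim$fps <= 2 * beat$frequency)
    stop("fps must exceed 2 * frequency: the sampling rate cannot resolve ",
         "the beat (aliasing)", call. = FALSE)
  structure(list(morphology = morphology, beat = beat, swim = swim),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic spermatozoon ground truth\n")
  cat(sprintf("  species: %s (head %g um, tail %g um, nucleus 0-%g um)\n",
              x$morphology$species_label, x$morphology$head_length,
              x$morphology$tail_length, x$morphology$nucleus_length))
  cat(sprintf("  beat:    %g Hz, wavelength %g um, tail amplitude %g 1/um, head factor %g\n",
              x$beat$frequency, x$beat$wavelength, x$beat$tail_amplitude,
              x$beat$head_amplitude_factor))
  cat(sprintf("  swim:    %g um/s, heading rate %g deg/s, %g s at %g fps, seed %d\n",
              x$swim$speed, x$swim$heading_rate, x$swim$duration, x$swim$fps,
              x$swim$seed))
  invisible(x)
}

#' Species morphology presets
#'
#' Returns morphologies for the two study species. The nucleus/acrosome
#' boundary is set at 21 um (Paramacrobiotus sp.) and 11 um (Macrobiotus
#' shonaicus) from the head base. Default head and tail lengths are chosen so
#' that, at 1-um station spacing, the head of Paramacrobiotus sp. carries 59
#' interior curvature stations and its tail 31, and M. shonaicus 13 and 21 --
#' the station counts over which per-position comparisons are reported for
#' these species. Each length carries half a station of headroom so that the
#' chord-length shortening of a curved digitised midline cannot drop the
#' final station.
#'
#' @param label Optional single species label; when given, that preset is
#'   returned directly.
#' @return A named list of [sperm_morphology()] objects, or a single preset
#'   when `label` is supplied.
#' @examples
#' species_presets("Paramacrobiotus sp.")$nucleus_length  # 21
#' @export
species_presets <- function(label = NULL) {
  presets <- list(
    "Paramacrobiotus sp." = sperm_morphology(
      "Paramacrobiotus sp.", head_length = 60.5, tail_length = 32.5,
      nucleus_length = 21),
    "Macrobiotus shonaicus" = sperm_morphology(
      "Macrobiotus shonaicus", head_length = 14.5, tail_length = 22.5,
      nucleus_length = 11))
  if (is.null(label)) return(presets)
  if (!label %in% names(presets))
    stop("unknown species label '", label, "'; available presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[label]]
}

# -- internal validation helpers ---------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive finite number", call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    stop(name, " must be a single non-negative finite number", call. = FALSE)
  invisible(x)
}
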