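#' Optical component descriptions
#'
#' Constructors for the small value objects used throughout the optics and
#' acquisition modules. All lengths are in micrometers unless the field name
#' says otherwise (focal lengths and working distances are in millimeters).
#'
#' @param name Free-text objective name.
#' @param numerical_aperture Numerical aperture, in (0, 1.6].
#' @param magnification Nominal objective magnification (> 0).
#' @param working_distance_mm Optional working distance in mm.
#' @param immersion_index Refractive index of the immersion medium (>= 1);
#'   must exceed the numerical aperture.
#' @return An object of class `objective_spec`.
#' @examples
#' obj <- objective_spec("MVPLAPO 2XC", 0.5, 2, working_distance_mm = 20)
#' @export
objective_spec <- function(name, numerical_aperture, magnification,
                           working_distance_mm = NULL, immersion_index = 1) {
  check_positive(numerical_aperture, "numerical_aperture")
  check_positive(magnification, "magnification")
  if (numerical_aperture > 1.6) {
    stop_domain("`numerical_aperture` must be <= 1.6")
  }
  if (immersion_index < 1) stop_domain("`immersion_index` must be >= 1")
  if (numerical_aperture >= immersion_index) {
    stop_domain("`numerical_aperture` must be below `immersion_index`")
  }
  structure(list(name = name,
                 numerical_aperture = numerical_aperture,
                 magnification = magnification,
                 working_distance_mm = working_distance_mm,
                 immersion_index = immersion_index),
            class = "objective_spec")
}

#' Detection path: objective + zoom body + camera
#'
#' Describes the detection side of the microscope: a macro objective behind a
#' continuously variable zoom body projecting onto an sCMOS sensor.
#'
#' @param objective An [objective_spec()].
#' @param zoom Zoom-body setting (dimensionless); must lie in `zoom_range`.
#' @param camera_pixel_pitch_um Physical camera pixel pitch in um.
#' @param sensor_shape_px Integer `(rows, cols)` of the sensor.
#' @param emission_wavelength_um Emission wavelength in um. The default
#'   0.52 um sits in the EGFP/EYFP emission band.
#' @param zoom_range Allowed zoom interval; defaults to the 0.63-6.3 range of
#'   a macro zoom body.
#' @return An object of class `detection_path`.
#' @export
detection_path <- function(objective, zoom = 1,
                           camera_pixel_pitch_um = 6.5,
                           sensor_shape_px = c(2048L, 2048L),
                           emission_wavelength_um = 0.52,
                           zoom_range = c(0.63, 6.3)) {
  stopifnot(inherits(objective, "objective_spec"))
  check_positive(camera_pixel_pitch_um, "camera_pixel_pitch_um")
  check_positive(emission_wavelength_um, "emission_wavelength_um")
  if (length(sensor_shape_px) != 2 || any(sensor_shape_px < 1)) {
    stop_domain("`sensor_shape_px` must be two positive integers")
  }
  if (zoom < zoom_range[1] || zoom > zoom_range[2]) {
    stop_domain(sprintf("`zoom` = %g outside configured range [%g, %g]",
                        zoom, zoom_range[1], zoom_range[2]))
  }
  structure(list(objective = objective, zoom = zoom,
                 camera_pixel_pitch_um = camera_pixel_pitch_um,
                 sensor_shape_px = as.integer(sensor_shape_px),
                 emission_wavelength_um = emission_wavelength_um,
                 zoom_range = zoom_range),
            class = "detection_path")
}

#' Convenience detection path for a macro zoom microscope
#'
#' A 2x/NA 0.5 macro objective behind a 0.63-6.3x zoom body and a 6.5 um
#' pitch sensor, the configuration whose total magnification runs from
#' 1.26x to 12.6x.
#'
#' @param zoom Zoom-body setting.
#' @param sensor_shape_px Sensor shape; small sensors are convenient for
#'   simulation.
#' @param ... Passed on to [detection_path()].
#' @export
macro_detection_path <- function(zoom = 6.3, sensor_shape_px = c(2048L, 2048L),
                                 ...) {
  detection_path(
    objective_spec("MVPLAPO 2XC", numerical_aperture = 0.5, magnification = 2,
                   working_distance_mm = 20),
    zoom = zoom, sensor_shape_px = sensor_shape_px, ...)
}

#' Gaussian light-sheet model
#'
#' The illumination sheet is modeled as a cylindrical Gaussian beam with
#' waist radius `w0` (1/e^2 half-width of the field amplitude) in the
#' detection (z) direction. The thickness grows away from the waist line as
#' `w(z) = w0 sqrt(1 + (z/zR)^2)` with Rayleigh range
#' `zR = pi w0^2 n / lambda`.
#'
#' @param waist_radius_w0_um Waist radius in um. The default 1.7 um gives an
#'   intensity FWHM across the sheet of about 2 um.
#' @param excitation_wavelength_um Excitation wavelength in um (488 nm
#'   default).
#' @param medium_index Refractive index of the imaging medium.
#' @param aperture_fraction Fraction of the illumination back aperture that
#'   is open, in (0, 1]; closing the aperture widens the waist.
#' @return An object of class `sheet_model`.
#' @export
sheet_model <- function(waist_radius_w0_um = 1.7,
                        excitation_wavelength_um = 0.488,
                        medium_index = 1.33,
                        aperture_fraction = 1) {
  check_positive(waist_radius_w0_um, "waist_radius_w0_um")
  check_positive(excitation_wavelength_um, "excitation_wavelength_um")
  check_positive(medium_index, "medium_index")
  check_positive(aperture_fraction, "aperture_fraction")
  if (aperture_fraction > 1) stop_domain("`aperture_fraction` must be <= 1")
  structure(list(waist_radius_w0_um = waist_radius_w0_um,
                 excitation_wavelength_um = excitation_wavelength_um,
                 medium_index = medium_index,
                 aperture_fraction = aperture_fraction),
            class = "sheet_model")
}

#' Relative image brightness in light-sheet microscopy
#'
#' In light-sheet microscopy the illumination is decoupled from detection, so
#' image brightness scales as the light-gathering power of the detection
#' objective over the image area: `NA^2 / Mag^2` (proportionality constant
#' 1, relative units).
#'
#' @param na Numerical aperture (> 0).
#' @param mag Magnification (> 0).
#' @return Relative brightness (dimensionless).
#' @examples
#' relative_brightness_lsfm(0.5, 2.0)
#' @export
relative_brightness_lsfm <- function(na, mag) {
  check_positive(na, "na"); check_positive(mag, "mag")
  na^2 / mag^2
}

#' Relative image brightness in wide-field epifluorescence
#'
#' Wide-field microscopy both condenses excitation and gathers emission
#' through the same objective, so brightness scales as `NA^4 / Mag^2`.
#'
#' @inheritParams relative_brightness_lsfm
#' @return Relative brightness (dimensionless).
#' @export
relative_brightness_widefield <- function(na, mag) {
  check_positive(na, "na"); check_positive(mag, "mag")
  na^4 / mag^2
}

#' Total magnification of the detection chain
#'
#' @param zoom Zoom-body setting.
#' @param objective_mag Objective magnification.
#' @return `zoom * objective_mag`.
#' @examples
#' total_magnification(6.3, 2)  # 12.6
#' @export
total_magnification <- function(zoom, objective_mag) {
  check_positive(zoom, "zoom"); check_positive(objective_mag, "objective_mag")
  zoom * objective_mag
}

#' Effective pixel size in sample space
#'
#' @param camera_pitch_um Physical camera pixel pitch in um.
#' @param total_mag Total detection magnification.
#' @param expansion_factor Scalar tissue expansion factor (>= 1 for expanded
#'   samples); sizes are reported in pre-expansion sample space.
#' @return Pixel size in um of (pre-expansion) sample space.
#' @examples
#' effective_pixel_size(6.5, 12.6)  # ~0.52 um
#' @export
effective_pixel_size <- function(camera_pitch_um, total_mag,
                                 expansion_factor = 1) {
  check_positive(camera_pitch_um, "camera_pitch_um")
  check_positive(total_mag, "total_mag")
  check_positive(expansion_factor, "expansion_factor")
  camera_pitch_um / (total_mag * expansion_factor)
}

#' Rayleigh diffraction-limited lateral resolution
#'
#' `0.61 lambda / NA`, the classical two-point Rayleigh criterion.
#'
#' @param emission_wavelength_um Emission wavelength in um.
#' @param na Numerical aperture of the detection objective.
#' @return Resolution in um.
#' @examples
#' rayleigh_resolution(0.52, 0.5)  # ~0.63 um
#' @export
rayleigh_resolution <- function(emission_wavelength_um, na) {
  check_positive(emission_wavelength_um, "emission_wavelength_um")
  check_positive(na, "na")
  0.61 * emission_wavelength_um / na
}

#' Beam expansion ratio of a two-lens telescope
#'
#' @param f_in_mm Focal length of the input lens (mm).
#' @param f_out_mm Focal length of the output lens (mm).
#' @return Expansion ratio `f_out / f_in`.
#' @examples
#' telescope_expansion(40, 200)     # 5x beam expander
#' telescope_expansion(24.88, 75)   # ~3x cylindrical telescope
#' @export
telescope_expansion <- function(f_in_mm, f_out_mm) {
  check_positive(f_in_mm, "f_in_mm"); check_positive(f_out_mm, "f_out_mm")
  f_out_mm / f_in_mm
}

#' Rayleigh range of the sheet-forming Gaussian beam
#'
#' @param sheet A [sheet_model()].
#' @return Rayleigh range `zR = pi w0^2 n / lambda` in um.
#' @export
rayleigh_range <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_model"))
  pi * sheet$waist_radius_w0_um^2 * sheet$medium_index /
    sheet$excitation_wavelength_um
}

#' Half-thickness of the light sheet away from the waist line
#'
#' @param sheet A [sheet_model()].
#' @param z_offset_um Distance from the waist line along the propagation
#'   axis, in um (may be a vector; the function is even in its argument).
#' @return Sheet half-thickness `w(z)` in um.
#' @export
sheet_half_thickness <- function(sheet, z_offset_um) {
  stopifnot(inherits(sheet, "sheet_model"))
  zr <- rayleigh_range(sheet)
  sheet$waist_radius_w0_um * sqrt(1 + (z_offset_um / zr)^2)
}

#' Intensity FWHM of the sheet profile
#'
#' The sheet intensity profile across its thickness is
#' `exp(-2 r^2 / w^2)`, a Gaussian with `sigma = w/2`, so the intensity
#' FWHM is `sqrt(2 ln 2) w ~= 1.177 w`.
#'
#' @inheritParams sheet_half_thickness
#' @return Intensity FWHM in um.
#' @export
sheet_fwhm <- function(sheet, z_offset_um = 0) {
  sqrt(2 * log(2)) * sheet_half_thickness(sheet, z_offset_um)
}

#' Waist radius set by the illuminated aperture fraction
#'
#' Trimming the beam entering the illumination objective to a fraction of
#' its back aperture reduces the effective illumination NA proportionally
#' and widens the Gaussian waist: `w0 = lambda / (pi a NA_max)`.
#'
#' @param sheet A [sheet_model()] supplying wavelength and aperture fraction.
#' @param na_illum_max Full-aperture illumination NA (> 0).
#' @return Waist radius in um.
#' @export
aperture_to_waist <- function(sheet, na_illum_max) {
  stopifnot(inherits(sheet, "sheet_model"))
  check_positive(na_illum_max, "na_illum_max")
  sheet$excitation_wavelength_um /
    (pi * sheet$aperture_fraction * na_illum_max)
}

#' Bundled numerical-aperture versus magnification table
#'
#' A synthetic table of (magnification, NA) pairs emulating the monotone,
#' concave growth of NA with magnification across commercial objective
#' lines. Under the light-sheet brightness law `NA^2/Mag^2` this table
#' yields brightness strictly decreasing in magnification, while under the
#' wide-field law `NA^4/Mag^2` the brightest objective lies at an interior
#' magnification (around 60x).
#'
#' @return A data frame with columns `magnification` and `numerical_aperture`.
#' @export
objective_na_table <- function() {
  path <- system.file("extdata", "objective_na_mag_synthetic.csv",
                      package = "mlsfm", mustWork = TRUE)
  utils::read.csv(path)
}
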