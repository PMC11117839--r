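#' Globe/optic-nerve tether geometry
#'
#' Parameters of the rotational loading geometry: a globe of radius `r`
#' (mm) rotating about its centre, an optic-nerve (ON) gripper at distance
#' `R` from the globe centre, offset from the ON junction by the angle
#' `chi` (deg), and a virtual orbital apex at `apex_distance` from the globe
#' centre, `apex_angle` degrees off the sagittal plane.  The ON junction
#' sits `fovea_disc_angle` degrees nasal to the posterior pole.  All
#' kinematics use a right-handed globe-centred frame with nasal = +x (for a
#' right eye; left eyes are handled by mirroring), superior = +y, anterior
#' = +z.
#'
#' @param r globe radius (mm), e.g. half the transverse diameter.
#' @param R globe-centre-to-gripper distance (mm); must exceed `r`.
#' @param chi offset angle between ON junction and gripper (deg).
#' @param phi azimuth of the ON junction (deg, metadata).
#' @param apex_distance globe-centre-to-orbital-apex distance (mm).
#' @param apex_angle angle between the sagittal plane and the centre-apex
#'   line (deg).
#' @param fovea_disc_angle angle between fovea and optic disc (deg).
#' @param on_length measured straight ON length (mm), or NA.
#' @param sinuosity fractional slack of the ON over its chord in central
#'   gaze.
#' @return object of class `globe_tether_geometry`.
#' @export
globe_tether_geometry <- function(r = 12, R = 41, chi = 10, phi = 0,
                                  apex_distance = 41, apex_angle = 22,
                                  fovea_disc_angle = 17,
                                  on_length = NA_real_, sinuosity = 0.03) {
  stopifnot(r > 0, R > r, is.finite(chi), apex_distance > 0,
            sinuosity >= 0)
  structure(list(r = r, R = R, chi = chi, phi = phi,
                 apex_distance = apex_distance, apex_angle = apex_angle,
                 fovea_disc_angle = fovea_disc_angle,
                 on_length = on_length, sinuosity = sinuosity),
            class = "globe_tether_geometry")
}

#' @export
print.globe_tether_geometry <- function(x, ...) {
  cat("globe/tether geometry: r =", x$r, "mm, R =", x$R, "mm, chi =",
      x$chi, "deg; apex", x$apex_distance, "mm @", x$apex_angle, "deg\n")
  invisible(x)
}

#' Adduction loading scenario
#'
#' @param start_angle initial adduction angle (deg; tethering threshold).
#' @param end_angle final adduction angle (deg).
#' @param iop_reference,iop_elevated intraocular pressures (mmHg, metadata).
#' @return object of class `adduction_scenario`.
#' @export
adduction_scenario <- function(start_angle = 26, end_angle = 32,
                               iop_reference = 15, iop_elevated = 30) {
  if (end_angle <= start_angle)
    stop("end_angle must exceed start_angle")
  structure(list(start_angle = start_angle, end_angle = end_angle,
                 iop_reference = iop_reference,
                 iop_elevated = iop_elevated),
            class = "adduction_scenario")
}

#' Optic-nerve length by the law of cosines
#'
#' Length of the straight ON between the junction (on a globe of radius r)
#' and the gripper (at distance R from the globe centre) when the included
#' angle is `chi + extra_angle`:
#' \deqn{L = \sqrt{r^2 + R^2 - 2 r R \cos(\chi + \psi)}.}
#'
#' @param g a `globe_tether_geometry`.
#' @param extra_angle additional included angle psi (or theta) in degrees.
#' @return ON length (mm).
#' @export
on_length <- function(g, extra_angle = 0) {
  a <- g$chi + extra_angle
  if (any(a < 0 | a >= 180))
    stop("included angle chi + extra_angle must lie in [0, 180) degrees")
  sqrt(g$r^2 + g$R^2 - 2 * g$r * g$R * cos(a * pi / 180))
}

#' Eye-rotation versus gripper-rotation equivalence
#'
#' Rotating the eye by theta and rotating the gripper along its arc by psi
#' produce congruent centre-junction-gripper triangles whenever theta =
#' psi, hence identical ON lengths.  Returns both lengths and their
#' absolute difference.
#'
#' @param g a `globe_tether_geometry`.
#' @param theta eye rotation (deg).
#' @param psi gripper arc travel (deg).
#' @param tol equality tolerance (mm).
#' @return list with `length_eye`, `length_gripper`, `difference`,
#'   `equivalent`.
#' @export
equivalence_check <- function(g, theta, psi, tol = 1e-12) {
  le <- on_length(g, theta)
  lg <- on_length(g, psi)
  list(length_eye = le, length_gripper = lg,
       difference = abs(le - lg), equivalent = abs(le - lg) < tol)
}

# unit vector from globe centre to the ON junction (central gaze):
# posterior pole is -z (anterior +z); the junction sits fovea_disc_angle
# degrees nasal (+x) of the pole.
junction_direction <- function(g) {
  a <- g$fovea_disc_angle * pi / 180
  c(sin(a), 0, -cos(a))
}

# virtual orbital apex position: posterior, apex_angle off the sagittal
# plane toward the nasal side (the medial orbital wall).
apex_position <- function(g) {
  a <- g$apex_angle * pi / 180
  g$apex_distance * c(sin(a), 0, -cos(a))
}

#' Place the gripper tip from a measured ON length
#'
#' The gripper tip lies on the segment from the ON junction to the virtual
#' orbital apex, at the measured straight ON length from the junction.
#'
#' @param g a `globe_tether_geometry`.
#' @param measured_on_length straight ON length (mm).
#' @return list with `gripper` (3D position mm), `junction`, `apex`,
#'   `junction_apex_distance`.
#' @export
place_virtual_apex <- function(g, measured_on_length = g$on_length) {
  if (!is.finite(measured_on_length) || measured_on_length < 0)
    stop("measured ON length must be a non-negative number")
  J <- g$r * junction_direction(g)
  A <- apex_position(g)
  d <- sqrt(sum((A - J)^2))
  if (measured_on_length > d + 1e-9)
    stop("ON length (", measured_on_length, " mm) exceeds the junction-",
         "apex distance (", format(d, digits = 4), " mm): the nerve is ",
         "slack and the gripper cannot be placed on the segment")
  if (measured_on_length == 0)
    warning("zero ON length: gripper placed at the junction")
  P <- J + measured_on_length * (A - J) / d
  list(gripper = P, junction = J, apex = A, junction_apex_distance = d)
}

# rotate a point about the vertical (+y) axis by ang degrees of adduction:
# the anterior pole (+z) swings nasally (+x), so posterior points such as
# the ON junction swing temporally, away from the medial orbital apex
rotate_adduction <- function(X, ang_deg) {
  a <- ang_deg * pi / 180
  Rm <- rbind(c(cos(a), 0, sin(a)),
              c(0, 1, 0),
              c(-sin(a), 0, cos(a)))
  rbind(X) %*% t(Rm)
}

#' Extension proportion of the apex-junction distance under adduction
#'
#' Rotates the globe (and with it the ON junction) about its centre from
#' the start to the end adduction angle while the virtual orbital apex
#' stays fixed, and returns the fractional increase of the apex-junction
#' distance, (d(end) - d(start)) / d(start).  The straight ON is stretched
#' by the same proportion.
#'
#' @param g a `globe_tether_geometry`.
#' @param scenario an [adduction_scenario()] (or any list with start/end
#'   angles).
#' @return fractional extension (dimensionless).
#' @export
extension_proportion <- function(g, scenario = adduction_scenario()) {
  J0 <- g$r * junction_direction(g)
  A <- apex_position(g)
  d_at <- function(ang) {
    J <- rotate_adduction(J0, ang)
    sqrt(sum((A - J)^2))
  }
  d0 <- d_at(scenario$start_angle)
  (d_at(scenario$end_angle) - d0) / d0
}

#' Sinuosity-corrected optic-nerve strain
#'
#' Converts a percentage elongation of the apex-junction distance into ON
#' strain, subtracting the sinuosity slack of the nerve in central gaze
#' (chord-referenced convention: 6.6% elongation less 3% sinuosity leaves
#' 3.6% strain), floored at zero.  The ratio convention
#' ((1 + e)/(1 + s) - 1) is available via `convention = "ratio"`.
#'
#' @param elongation_pct elongation of the apex-junction distance (percent).
#' @param sinuosity_pct ON slack in central gaze (percent).
#' @param convention "chord" (percent subtraction, default) or "ratio".
#' @return strain in percent.
#' @examples
#' strain_from_elongation(6.6, 3)  # 3.6
#' @export
strain_from_elongation <- function(elongation_pct, sinuosity_pct = 3,
                                   convention = c("chord", "ratio")) {
  stopifnot(all(elongation_pct >= 0), all(sinuosity_pct >= 0))
  convention <- match.arg(convention)
  out <- switch(convention,
    chord = elongation_pct - sinuosity_pct,
    ratio = ((1 + elongation_pct / 100) / (1 + sinuosity_pct / 100) - 1) *
      100)
  pmax(out, 0)
}

#' Per-specimen kinematics report
#'
#' Summarizes the tether kinematics for a table of specimens (columns
#' `axial_length`, `transverse_diameter`, `on_length`,
#' `sheath_outer_radius`, all mm): globe radius, junction-apex distance,
#' extension proportion over the adduction scenario, and the
#' sinuosity-corrected ON strain.
#'
#' @param specimens data.frame of specimen dimensions.
#' @param scenario an [adduction_scenario()].
#' @param sinuosity fractional ON slack in central gaze.
#' @return data.frame, one row per specimen.
#' @export
kinematics_report <- function(specimens, scenario = adduction_scenario(),
                              sinuosity = 0.03) {
  stopifnot(all(c("transverse_diameter", "on_length") %in%
                  names(specimens)))
  out <- lapply(seq_len(nrow(specimens)), function(i) {
    r <- specimens$transverse_diameter[i] / 2
    g <- globe_tether_geometry(r = r, on_length = specimens$on_length[i],
                               sinuosity = sinuosity)
    pl <- place_virtual_apex(g)
    ext <- extension_proportion(g, scenario)
    data.frame(specimen = i, globe_radius_mm = r,
               junction_apex_mm = pl$junction_apex_distance,
               extension_pct = 100 * ext,
               on_strain_pct = strain_from_elongation(100 * ext,
                                                      100 * sinuosity))
  })
  do.call(rbind, out)
}
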