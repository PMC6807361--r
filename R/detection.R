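#' Acceptance half-angle of an objective
#'
#' `asin(NA / n_medium)` in degrees.  An explicit override is honored when
#' given — the bundled microscope preset pins the cone to exactly 15
#' degrees, the rounded acceptance angle of an NA 0.25 objective in air.
#'
#' @param na Numerical aperture (0 < NA <= n_medium).
#' @param n_medium Refractive index of the collection medium (default 1).
#' @param override_deg Optional explicit half-angle in degrees.
#' @return Half-angle in degrees.
#' @examples
#' acceptance_half_angle(0.25)  # 14.48 degrees
#' @export
acceptance_half_angle <- function(na, n_medium = 1, override_deg = NULL) {
  if (!is.null(override_deg)) {
    stopifnot(override_deg > 0, override_deg <= 90)
    return(override_deg)
  }
  if (!is.numeric(na) || na <= 0 || na > n_medium)
    stop("need 0 < NA <= n_medium")
  asin(na / n_medium) * 180 / pi
}

#' Detector (collection-optics) specification
#'
#' Collection geometry of an epifluorescence objective above the animal:
#' the numerical aperture defines an acceptance cone for photons exiting
#' the top surface; accepted photons are binned by exit radius.  The
#' optional magnification, camera-side resolvable distance `e` and
#' wavelength feed the Berek depth-of-field equation.
#'
#' @param na Numerical aperture.
#' @param n_medium Refractive index of the collection medium (default 1).
#' @param half_angle_deg Optional explicit acceptance half-angle override
#'   in degrees; when `NULL` the angle is `asin(na / n_medium)`.
#' @param bin_width Radial bin width in cm (default 0.005, i.e. 0.05 mm).
#' @param magnification Total magnification (for the Berek equation).
#' @param resolvable_e Camera-side resolvable distance in cm (Berek
#'   geometric term).
#' @param wavelength Imaging wavelength in cm (default 1100 nm).
#' @return A `detector_spec` object.
#' @export
detector_spec <- function(na = 0.25, n_medium = 1, half_angle_deg = NULL,
                          bin_width = 0.005, magnification = NA_real_,
                          resolvable_e = NA_real_, wavelength = 1100e-7) {
  stopifnot(bin_width > 0, wavelength > 0)
  structure(list(
    na = na, n_medium = n_medium,
    half_angle_deg = acceptance_half_angle(na, n_medium, half_angle_deg),
    bin_width = bin_width, magnification = magnification,
    resolvable_e = resolvable_e, wavelength = wavelength),
    class = "detector_spec")
}

#' @rdname detector_spec
#' @details `default_detector()` is the bundled preset for the NA 0.25
#'   epifluorescence macro zoom microscope with the acceptance cone pinned
#'   to exactly 15 degrees.
#' @export
default_detector <- function() detector_spec(na = 0.25, half_angle_deg = 15)

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("<detector_spec> NA %.3g (n = %g), half-angle %.4g deg, bins %g mm\n",
              x$na, x$n_medium, x$half_angle_deg, x$bin_width * 10))
  invisible(x)
}

#' Collect exit photons through the acceptance cone
#'
#' Keeps exit records whose polar exit angle (in the ambient medium, after
#' the final refraction) lies within the detector half-angle, and bins the
#' accepted records by exit radius.  Bin intensities are summed accepted
#' weights; fractions are relative to the first (on-axis) bin.
#'
#' @param x A `transport_result` from [run_emission()] /
#'   [run_transport()], or an exit-record data frame with columns `r_cm`,
#'   `angle_deg`, `weight`.
#' @param detector A [detector_spec()].
#' @param n_bins Number of radial bins (default 10, covering 0 to 0.5 mm
#'   at the default bin width).
#' @return Data frame of class `radial_profile` with columns `bin_lo_mm`,
#'   `bin_hi_mm`, `intensity`, `count`, `fraction_of_first`, and
#'   attributes `accepted_count` and `accepted_weight` (totals within the
#'   cone over all radii, including beyond the last bin).
#' @export
collect <- function(x, detector = default_detector(), n_bins = 10) {
  exits <- if (inherits(x, "transport_result")) x$exits else x
  stopifnot(is.data.frame(exits),
            all(c("r_cm", "angle_deg", "weight") %in% names(exits)),
            inherits(detector, "detector_spec"), n_bins >= 1)
  acc <- exits[exits$angle_deg <= detector$half_angle_deg, , drop = FALSE]
  bw <- detector$bin_width
  idx <- pmin(floor(acc$r_cm / bw), n_bins)  # n_bins + 1 slot = beyond-last
  intensity <- count <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    inb <- idx == (b - 1)
    intensity[b] <- sum(acc$weight[inb])
    count[b] <- sum(inb)
  }
  first <- intensity[1]
  prof <- data.frame(
    bin_lo_mm = (seq_len(n_bins) - 1) * bw * 10,
    bin_hi_mm = seq_len(n_bins) * bw * 10,
    intensity = intensity, count = count,
    fraction_of_first = if (first > 0) intensity / first else
      rep(NA_real_, n_bins))
  attr(prof, "accepted_count") <- nrow(acc)
  attr(prof, "accepted_weight") <- sum(acc$weight)
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

#' Depth of field by the Berek equation
#'
#' `DOF = n * lambda / (2 * NA^2) + n * e / (M * NA)`: a diffraction term
#' plus a geometric term set by the camera-side resolvable distance `e`
#' and total magnification `M`.  As `M` grows the geometric term vanishes
#' and the diffraction term alone remains.
#'
#' @param detector A [detector_spec()] with `wavelength`, `magnification`
#'   and `resolvable_e` set.
#' @return List with `diffraction_cm`, `geometric_cm`, `dof_cm`.
#' @examples
#' d <- detector_spec(na = 0.25, magnification = 1, resolvable_e = 20e-4)
#' berek_depth_of_field(d)
#' @export
berek_depth_of_field <- function(detector) {
  stopifnot(inherits(detector, "detector_spec"))
  if (!is.finite(detector$na) || detector$na == 0)
    stop("numerical aperture must be nonzero")
  if (!is.finite(detector$magnification) || detector$magnification == 0)
    stop("magnification must be set and nonzero for the Berek equation")
  if (!is.finite(detector$resolvable_e))
    stop("resolvable distance e must be set for the Berek equation")
  n <- detector$n_medium
  diffr <- n * detector$wavelength / (2 * detector$na^2)
  geom <- n * detector$resolvable_e / (detector$magnification * detector$na)
  list(diffraction_cm = diffr, geometric_cm = geom, dof_cm = diffr + geom)
}

#' Simulate the full focal-plane study
#'
#' The end-to-end experiment: one pencil-beam excitation run scores the
#' on-axis excitation dose at each candidate quantum-dot depth; each depth
#' then re-emits isotropically at 1100 nm with its inherited weight; exit
#' photons are filtered through the detector acceptance cone and binned
#' radially.  The recommended focal depth is the candidate with the
#' largest accepted (near-ballistic) weight.
#'
#' One global seed expands deterministically into per-stage child seeds
#' (excitation first, then one per emission depth), so each stage is
#' independently reproducible.
#'
#' @param depths_mm Candidate quantum-dot depths in mm below the scalp
#'   surface.
#' @param n_photons_excitation,n_photons_emission Photons per stage.
#' @param seed Global seed.
#' @param detector A [detector_spec()].
#' @param mode Boundary mode, see [run_transport()].
#' @param use_preset_weights Use the rounded preset inherited weights
#'   (default) instead of ratios recomputed from the excitation run.
#' @param bin_radius On-axis disc radius for excitation scoring (cm).
#' @param n_bins Radial bins in each emission profile.
#' @param excitation_stack,emission_stack The two wavelength stacks.
#' @return A `focus_study` object: `efficiency` (excitation table),
#'   `profiles` (named list of `radial_profile`s), `summary` (per-depth
#'   table), `dof` (Berek result or `NULL` when optics parameters are
#'   unset), `recommended_depth_mm`, and the `detector`.
#' @export
simulate_focus_study <- function(depths_mm = c(0.4, 0.8, 1.4, 2.0),
                                 n_photons_excitation = 1e6,
                                 n_photons_emission = 1e6,
                                 seed = 1,
                                 detector = default_detector(),
                                 mode = "fresnel_full",
                                 use_preset_weights = TRUE,
                                 bin_radius = 0.005, n_bins = 10,
                                 excitation_stack =
                                   default_stack("excitation_785"),
                                 emission_stack =
                                   default_stack("emission_1100")) {
  stopifnot(length(depths_mm) >= 1, all(depths_mm > 0))
  depths_cm <- depths_mm / 10
  seeds <- stage_seeds(seed, 1 + length(depths_cm))
  eff <- excitation_efficiency(excitation_stack, depths_cm,
                               n_photons = n_photons_excitation,
                               bin_radius = bin_radius, seed = seeds[1],
                               mode = mode)
  w0 <- if (use_preset_weights) inherited_weight(depths_cm)
        else inherited_weight(depths_cm, table = eff)
  profiles <- vector("list", length(depths_cm))
  names(profiles) <- format(depths_mm)
  acc_count <- acc_weight <- numeric(length(depths_cm))
  for (i in seq_along(depths_cm)) {
    em <- run_emission(
      fluor_source(depths_cm[i], weight = w0[i],
                   n_emit = n_photons_emission),
      stack = emission_stack, seed = seeds[1 + i], mode = mode)
    prof <- collect(em, detector, n_bins = n_bins)
    profiles[[i]] <- prof
    acc_count[i] <- attr(prof, "accepted_count")
    acc_weight[i] <- attr(prof, "accepted_weight")
  }
  summary <- data.frame(
    depth_mm = depths_mm,
    excitation_intensity = eff$intensity,
    relative_excitation = eff$relative_to_shallowest,
    inherited_weight = w0,
    accepted_count = acc_count,
    accepted_weight = acc_weight)
  dof <- tryCatch(berek_depth_of_field(detector), error = function(e) NULL)
  structure(list(
    efficiency = eff, profiles = profiles, summary = summary, dof = dof,
    recommended_depth_mm = depths_mm[which.max(acc_weight)],
    detector = detector, seed = seed,
    n_photons_excitation = n_photons_excitation,
    n_photons_emission = n_photons_emission), class = "focus_study")
}

# One global seed -> deterministic per-stage child seeds (all < 2^31 - 1).
stage_seeds <- function(seed, n) {
  ((seed %% 2147483647) * 100003 + 7919 * seq_len(n)) %% 2147483646 + 1
}

#' @export
print.focus_study <- function(x, ...) {
  cat("<focus_study> seed ", x$seed, ", ",
      format(x$n_photons_excitation, big.mark = ","), " excitation + ",
      format(x$n_photons_emission, big.mark = ","),
      " emission photons per depth\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$dof))
    cat(sprintf("depth of field (Berek): %.4g mm\n", x$dof$dof_cm * 10))
  cat("recommended focal depth:", x$recommended_depth_mm, "mm\n")
  invisible(x)
}
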