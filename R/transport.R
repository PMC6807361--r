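#' Specular (normal-incidence Fresnel) reflectance
#'
#' Fraction of intensity reflected when light crosses an index step at
#' normal incidence: `((n1 - n2) / (n1 + n2))^2`.  Symmetric in its
#' arguments and zero for matched indices.
#'
#' @param n1,n2 Refractive indices of the media on either side.
#' @return Reflected fraction in \[0, 1).
#' @examples
#' specular_reflectance(1, 1.37)  # air -> skin, about 0.0244
#' @export
specular_reflectance <- function(n1, n2) {
  stopifnot(is.numeric(n1), is.numeric(n2))
  mapply(cpp_specular_reflectance, n1, n2)
}

#' Critical angle for total internal reflection
#'
#' `asin(n2 / n1)`, defined only when passing into a lower-index medium
#' (`n2 < n1`); otherwise `NA` (total internal reflection impossible).
#'
#' @param n1 Index of the medium the ray travels in.
#' @param n2 Index of the medium beyond the boundary.
#' @param degrees Return degrees (default) or radians.
#' @return Critical angle, or `NA` when `n2 >= n1`.
#' @export
critical_angle <- function(n1, n2, degrees = TRUE) {
  stopifnot(n1 > 0, n2 > 0)
  th <- ifelse(n2 < n1, asin(n2 / n1), NA_real_)
  if (degrees) th * 180 / pi else th
}

#' Refraction angle across an index boundary
#'
#' Snell's law: `beta = asin((n1 / n2) * sin(alpha))`.  Incidence at or
#' beyond the critical angle is an error — the caller must reflect instead.
#'
#' @param n1,n2 Refractive indices before and after the boundary.
#' @param alpha Incidence angle from the boundary normal, in degrees.
#' @return Refraction angle in degrees.
#' @export
refraction_angle <- function(n1, n2, alpha) {
  stopifnot(n1 > 0, n2 > 0, alpha >= 0, alpha <= 90)
  s <- n1 / n2 * sin(alpha * pi / 180)
  if (any(s >= 1))
    stop("incidence at or beyond the critical angle: total internal reflection")
  asin(s) * 180 / pi
}

#' Unpolarized Fresnel reflectance at arbitrary incidence
#'
#' @param n1,n2 Refractive indices before and after the boundary.
#' @param alpha Incidence angle in degrees (default 0, where the value
#'   reduces to [specular_reflectance()]).
#' @return Reflected fraction in \[0, 1\]; 1 at or beyond the critical
#'   angle.
#' @export
fresnel_reflectance <- function(n1, n2, alpha = 0) {
  stopifnot(n1 > 0, n2 > 0, alpha >= 0, alpha <= 90)
  mapply(function(a, m1, m2)
    cpp_fresnel_unpolarized(m1, m2, cos(a * pi / 180)), alpha, n1, n2)
}

#' Sample free path lengths to the next interaction
#'
#' `s = -log(xi) / mu_t` with `xi` uniform on (0, 1]; the mean free path is
#' `1 / mu_t`.
#'
#' @param mu_t Total attenuation coefficient (cm^-1, > 0).
#' @param n Number of draws.
#' @param xi Optional uniform deviates (for deterministic evaluation).
#' @return Path lengths in cm.
#' @export
sample_step <- function(mu_t, n = 1, xi = runif(n)) {
  if (!is.numeric(mu_t) || mu_t <= 0)
    stop("mu_t must be > 0 (vacuum guard layers are traversed ballistically)")
  -log(xi) / mu_t
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function with
#' anisotropy `g`; `g = 0` is isotropic, `|g| = 1` deterministic
#' forward/backward.
#'
#' @param g Anisotropy factor in \[-1, 1\].
#' @param n Number of draws.
#' @param xi Optional uniform deviates (for deterministic evaluation).
#' @return Deflection cosines in \[-1, 1\].
#' @export
sample_hg <- function(g, n = 1, xi = runif(n)) {
  stopifnot(g >= -1, g <= 1)
  vapply(xi, function(u) cpp_hg_cos_theta(g, u), numeric(1))
}

#' Sample a full scattering event (azimuth and zenith)
#'
#' Draws the isotropic azimuth first, then the Henyey-Greenstein zenith
#' cosine — the same order the transport engine uses.
#'
#' @inheritParams sample_hg
#' @return Data frame with columns `psi` (azimuth, radians in \[0, 2*pi))
#'   and `cos_theta`.
#' @export
spin_hg <- function(g, n = 1) {
  psi <- numeric(n)
  ct <- numeric(n)
  for (i in seq_len(n)) {
    psi[i] <- 2 * pi * runif(1)
    ct[i] <- cpp_hg_cos_theta(g, runif(1))
  }
  data.frame(psi = psi, cos_theta = ct)
}

#' Russian-roulette termination of low-weight photons
#'
#' Weights below `threshold` survive with probability `1/m` (weight
#' multiplied by `m`) and are otherwise set to zero; expected weight is
#' preserved.
#'
#' @param weight Numeric vector of photon weights.
#' @param threshold Roulette threshold (default 1e-4).
#' @param m Survival multiplier (default 10).
#' @param xi Optional uniform deviates.
#' @return Updated weights (0 for killed photons).
#' @export
roulette <- function(weight, threshold = 1e-4, m = 10,
                     xi = runif(length(weight))) {
  stopifnot(m > 1)
  low <- weight < threshold
  out <- weight
  out[low] <- ifelse(xi[low] < 1 / m, weight[low] * m, 0)
  out
}

#' Photon sources
#'
#' `pencil_source()` describes an infinitely narrow beam entering the top
#' surface of the stack heading straight down; at launch the photon weight
#' is reduced by the specular reflectance of the ambient/top-layer
#' interface.  `fluor_source()` describes an isotropic point re-emitter (a
#' quantum dot) at depth `z_qd` below the scalp surface carrying the
#' inherited initial weight `weight` per photon.
#'
#' @param weight Initial photon weight in (0, 1].
#' @param z_qd Quantum-dot plane depth (cm) below the scalp surface.
#'   Presets: 0.04, 0.08, 0.14, 0.20.
#' @param n_emit Number of emission photons to launch.
#' @param r_qd Radial offset of the source from the light axis (cm).
#' @return A `photon_source` object.
#' @export
pencil_source <- function(weight = 1) {
  stopifnot(is.numeric(weight), weight > 0, weight <= 1)
  structure(list(type = "pencil", weight = weight, z = NA_real_, r = 0),
            class = "photon_source")
}

#' @rdname pencil_source
#' @export
fluor_source <- function(z_qd, weight = 1, n_emit = 1e6, r_qd = 0) {
  stopifnot(is.numeric(z_qd), length(z_qd) == 1, z_qd > 0,
            is.numeric(weight), weight > 0, weight <= 1,
            n_emit >= 1, r_qd >= 0)
  structure(list(type = "isotropic", weight = weight, z = z_qd, r = r_qd,
                 n_emit = n_emit),
            class = c("fluor_source", "photon_source"))
}

#' Launch state of a pencil-beam photon
#'
#' The photon starts at the origin of the top surface heading +z with
#' weight `weight * (1 - R_sp)`, where `R_sp` is the specular reflectance
#' of the ambient/top-layer interface.
#'
#' @param stack A [layer_stack()].
#' @param weight Initial weight before the specular loss.
#' @return A list with fields `x, y, z, ux, uy, uz, W, layer, alive`.
#' @export
launch_pencil_beam <- function(stack, weight = 1) {
  stopifnot(inherits(stack, "layer_stack"))
  rsp <- specular_reflectance(stack$ambient_above_n, stack$layers$n[1])
  list(x = 0, y = 0, z = stack$z_boundaries[1], ux = 0, uy = 0, uz = 1,
       W = weight * (1 - rsp), layer = 1L, alive = TRUE)
}

#' Fluence-grid geometry for a stack
#'
#' Cylindrical (r, z) scoring grid for absorbed weight.  Default bin width
#' 0.005 cm (0.05 mm) in both directions, 100 radial bins, and depth bins
#' spanning the stack down to at most `max_span` below its top surface;
#' absorption outside the grid accumulates in a scalar overflow.
#'
#' @param stack A [layer_stack()].
#' @param dr,dz Bin widths in cm.
#' @param nr Number of radial bins.
#' @param max_span Maximum gridded depth span in cm (caps the grid for
#'   semi-infinite stacks).
#' @return A list with fields `dr`, `dz`, `nr`, `nz`, `z_min`.
#' @export
fluence_grid_spec <- function(stack, dr = 0.005, dz = 0.005, nr = 100,
                              max_span = 1.2) {
  stopifnot(inherits(stack, "layer_stack"), dr > 0, dz > 0, nr >= 1)
  zb <- stack$z_boundaries
  z_min <- zb[1]
  z_max <- min(zb[length(zb)], z_min + max_span)
  list(dr = dr, dz = dz, nr = as.integer(nr),
       nz = as.integer(ceiling((z_max - z_min) / dz - 1e-9)), z_min = z_min)
}

resolve_mode <- function(mode) {
  mode <- match.arg(mode, c("fresnel_full", "paper_eq1"))
  list(name = mode, code = if (mode == "fresnel_full") 0L else 1L)
}

#' Run a Monte Carlo transport simulation
#'
#' Propagates `n_photons` weighted photons through the stack with the full
#' hop/drop/spin/boundary loop until each photon dies (absorption to zero
#' weight, roulette) or exits.  Photons leaving the top surface are
#' refracted into the ambient medium and recorded as exit records; photons
#' crossing the bottom boundary are terminated and tallied as transmitted.
#'
#' Two boundary modes are available.  `"fresnel_full"` (default) reflects
#' or transmits probabilistically with the unpolarized Fresnel reflectance
#' at the actual incidence angle.  `"paper_eq1"` is deterministic: total
#' internal reflection above the critical angle, otherwise transmission
#' with the weight stripped by the normal-incidence reflectance.  Both
#' modes agree in expectation at normal incidence.
#'
#' @param stack A [layer_stack()].
#' @param source A [pencil_source()] or [fluor_source()].
#' @param n_photons Number of photons to launch.
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @param mode Boundary mode, `"fresnel_full"` or `"paper_eq1"`.
#' @param roulette_threshold,roulette_m Russian-roulette parameters.
#' @param grid Scoring-grid geometry from [fluence_grid_spec()].
#' @param score_planes Depths (cm) at which downward plane crossings near
#'   the axis are scored.
#' @param plane_bin_radius Radius (cm) of the on-axis scoring disc.
#' @param plane_first_crossing_only Count only the first downward crossing
#'   per photon and plane instead of every crossing.
#' @param record_exits Keep per-photon top-surface exit records.
#' @param ambient_below_n Refractive index of the medium below the bottom
#'   boundary.  `NA` (default) makes the bottom a perfect sink standing in
#'   for a semi-infinite substrate; a finite value makes it a true optical
#'   interface with Fresnel reflection/refraction, as in a stack truncated
#'   at a plane of interest.
#' @param record_bottom_exits Keep exit records for photons transmitted
#'   through a refracting bottom boundary.
#' @return A `transport_result`: list with the weight `ledger`, the
#'   fluence `grid` (accumulator matrix plus geometry and overflow), the
#'   `planes` table (z, crossing weight, count, and on-axis intensity per
#'   launched photon per cm^2), and the `exits` data frame
#'   (`r_cm`, `angle_deg`, `weight`).
#' @examples
#' res <- run_transport(default_stack("excitation_785"),
#'                      n_photons = 1000, seed = 1)
#' res$ledger
#' @export
run_transport <- function(stack, source = pencil_source(),
                          n_photons = 1e6, seed = NULL,
                          mode = "fresnel_full",
                          roulette_threshold = 1e-4, roulette_m = 10,
                          grid = fluence_grid_spec(stack),
                          score_planes = numeric(0),
                          plane_bin_radius = 0.005,
                          plane_first_crossing_only = FALSE,
                          record_exits = TRUE,
                          ambient_below_n = NA_real_,
                          record_bottom_exits = FALSE) {
  stopifnot(inherits(stack, "layer_stack"), inherits(source, "photon_source"),
            n_photons >= 1, roulette_threshold >= 0, roulette_m > 1,
            plane_bin_radius > 0)
  md <- resolve_mode(mode)
  if (!is.null(seed)) set.seed(seed)
  zb <- stack$z_boundaries
  if (is.infinite(zb[length(zb)]))  # semi-infinite substrate: finite cap,
    zb[length(zb)] <- zb[length(zb) - 1] + 100  # never reached in practice
  src_type <- if (source$type == "pencil") 0L else 1L
  if (src_type == 1L) {
    if (source$z < zb[1] || source$z >= zb[length(zb)])
      stop("source depth lies outside the stack span")
  }
  lm <- as.matrix(stack$layers[, c("n", "mu_a", "mu_s", "g")])
  res <- cpp_run_transport(
    lm, zb, stack$ambient_above_n, src_type,
    if (is.na(source$z)) 0 else source$z, source$r, source$weight,
    as.numeric(n_photons), md$code, roulette_threshold, roulette_m,
    grid$dr, grid$dz, grid$nr, grid$nz, grid$z_min,
    as.numeric(score_planes), plane_bin_radius, plane_first_crossing_only,
    record_exits, as.numeric(ambient_below_n), record_bottom_exits)
  planes <- data.frame(
    z = as.numeric(score_planes),
    weight = res$plane_weight, count = res$plane_count,
    intensity = res$plane_weight / (pi * plane_bin_radius^2 * n_photons))
  exits <- data.frame(
    r_cm = res$exit_r,
    angle_deg = acos(pmin(pmax(res$exit_cos, 0), 1)) * 180 / pi,
    weight = res$exit_w)
  bottom_exits <- data.frame(
    r_cm = res$bottom_r,
    angle_deg = acos(pmin(pmax(res$bottom_cos, 0), 1)) * 180 / pi,
    weight = res$bottom_w)
  structure(list(
    ledger = unlist(res$ledger),
    grid = list(A = res$A, dr = grid$dr, dz = grid$dz, nr = grid$nr,
                nz = grid$nz, z_min = grid$z_min, overflow = res$overflow,
                n_launched = n_photons, initial_weight = source$weight),
    planes = planes, exits = exits, bottom_exits = bottom_exits,
    stack = stack, source = source, n_photons = n_photons, mode = md$name,
    roulette = list(threshold = roulette_threshold, m = roulette_m),
    plane_bin_radius = plane_bin_radius), class = "transport_result")
}

#' Relative weight-conservation error of a transport run
#'
#' The launched weight must partition into specular loss, absorbed weight,
#' top-surface escape, bottom transmission, net roulette loss (gross kills
#' minus survivor boosts — Russian roulette is unbiased only in
#' expectation, so the ledger tracks both sides) and, in `"paper_eq1"`
#' mode, boundary-stripped weight.
#'
#' @param result A `transport_result` (or a named ledger vector).
#' @return Absolute relative conservation error (dimensionless).
#' @export
ledger_conservation_error <- function(result) {
  ld <- if (inherits(result, "transport_result")) result$ledger else result
  launched <- ld[["launched_weight"]]
  accounted <- sum(ld[c("specular", "absorbed", "escaped_top",
                        "transmitted_bottom", "roulette_killed",
                        "boundary_stripped")]) - ld[["roulette_boost"]]
  abs(launched - accounted) / launched
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result> ", x$stack$wavelength_tag, ", ",
      format(x$n_photons, big.mark = ","), " photons, mode ", x$mode,
      "\n", sep = "")
  ld <- x$ledger
  frac <- ld / ld[["launched_weight"]]
  for (nm in names(ld)[-1])
    cat(sprintf("  %-20s %12.6g  (%.4f of launched)\n", nm, ld[[nm]],
                frac[[nm]]))
  cat(sprintf("  conservation error   %g\n", ledger_conservation_error(x)))
  if (nrow(x$planes)) {
    cat("  scored planes:\n")
    print(x$planes, row.names = FALSE)
  }
  invisible(x)
}

#' Normalized fluence map from a transport run
#'
#' Converts the absorbed-weight accumulator into a per-photon fluence
#' table.  `"per_area"` divides each cell by the launched photon count and
#' the annular cell area (weight per photon per cm^2); `"per_volume_mu_a"`
#' divides by cell volume and the local absorption coefficient, giving the
#' conventional fluence estimate `A / (N V mu_a)`.
#'
#' @param result A `transport_result`.
#' @param mode `"per_area"` (default) or `"per_volume_mu_a"`.
#' @return Data frame with columns `r_lo`, `r_hi`, `z_lo`, `z_hi`,
#'   `absorbed_weight`, `fluence`.  Logarithms are left to presentation
#'   time; empty cells carry fluence 0.
#' @export
fluence_map <- function(result, mode = c("per_area", "per_volume_mu_a")) {
  stopifnot(inherits(result, "transport_result"))
  mode <- match.arg(mode)
  g <- result$grid
  ir <- seq_len(g$nr) - 1L
  iz <- seq_len(g$nz) - 1L
  r_lo <- rep(ir * g$dr, times = g$nz)
  z_lo <- rep(g$z_min + iz * g$dz, each = g$nr)
  area <- pi * g$dr^2 * (2 * rep(ir, times = g$nz) + 1)  # annulus area
  w <- as.vector(g$A)
  if (mode == "per_area") {
    flu <- w / (g$n_launched * area)
  } else {
    zc <- z_lo + g$dz / 2
    zb <- result$stack$z_boundaries
    mu_a <- result$stack$layers$mu_a[
      vapply(pmin(zc, zb[length(zb)]),
             function(z) layer_at_depth(result$stack, z), integer(1))]
    vol <- area * g$dz
    flu <- ifelse(w > 0 & mu_a > 0, w / (g$n_launched * vol * mu_a), 0)
  }
  data.frame(r_lo = r_lo, r_hi = r_lo + g$dr, z_lo = z_lo,
             z_hi = z_lo + g$dz, absorbed_weight = w, fluence = flu)
}
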