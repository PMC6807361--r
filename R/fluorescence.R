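#' Uniform directions on the unit sphere
#'
#' `uz = 2*xi1 - 1`, azimuth `psi = 2*pi*xi2` — the launch distribution of
#' isotropic fluorescence emission.
#'
#' @param n Number of directions.
#' @param xi1,xi2 Optional uniform deviates (for deterministic evaluation).
#' @return An `n x 3` matrix with columns `ux`, `uy`, `uz`.
#' @export
isotropic_direction <- function(n = 1, xi1 = runif(n), xi2 = runif(n)) {
  uz <- 2 * xi1 - 1
  st <- sqrt(pmax(0, 1 - uz^2))
  psi <- 2 * pi * xi2
  cbind(ux = st * cos(psi), uy = st * sin(psi), uz = uz)
}

#' Excitation efficiency of quantum dots at depth
#'
#' Runs one pencil-beam excitation simulation and scores, at each candidate
#' quantum-dot depth, the summed weight of downward photon crossings of the
#' horizontal plane within `bin_radius` of the light axis, normalized per
#' launched photon and per cm^2 of the on-axis disc.  By default every
#' downward crossing contributes (a fluence-like excitation dose);
#' `first_crossing_only = TRUE` restricts each photon to its first crossing
#' of each plane.
#'
#' @param stack The 785 nm excitation stack.
#' @param depths Quantum-dot plane depths in cm (default the four preset
#'   depths 0.4, 0.8, 1.4, 2.0 mm below the scalp surface).
#' @param n_photons Number of excitation photons.
#' @param bin_radius On-axis disc radius in cm (default 0.005).
#' @param seed Optional seed.
#' @param mode Boundary mode, see [run_transport()].
#' @param first_crossing_only Count only first crossings.
#' @param ... Further arguments passed to [run_transport()].
#' @return A data frame of class `excitation_table` with columns `z_qd`
#'   (cm), `intensity` (weight per photon per cm^2) and
#'   `relative_to_shallowest`; the full `transport_result` is attached as
#'   attribute `"transport"`.
#' @export
excitation_efficiency <- function(stack = default_stack("excitation_785"),
                                  depths = c(0.04, 0.08, 0.14, 0.20),
                                  n_photons = 1e6, bin_radius = 0.005,
                                  seed = NULL, mode = "fresnel_full",
                                  first_crossing_only = FALSE, ...) {
  stopifnot(length(depths) >= 1, all(depths > 0), bin_radius > 0)
  res <- run_transport(stack, pencil_source(), n_photons = n_photons,
                       seed = seed, mode = mode, score_planes = depths,
                       plane_bin_radius = bin_radius,
                       plane_first_crossing_only = first_crossing_only,
                       record_exits = FALSE, ...)
  ref <- res$planes$intensity[which.min(depths)]
  tab <- data.frame(z_qd = depths, intensity = res$planes$intensity,
                    relative_to_shallowest =
                      if (ref > 0) res$planes$intensity / ref else NA_real_)
  attr(tab, "transport") <- res
  class(tab) <- c("excitation_table", "data.frame")
  tab
}

# Preset inherited weights: the excitation dose at each quantum-dot depth
# relative to the 0.4 mm (cortical surface) reference.
INHERITED_WEIGHT_PRESETS <- c("0.04" = 1, "0.08" = 0.011,
                              "0.14" = 0.0015, "0.2" = 0.0005)

#' Inherited initial weight of emission photons
#'
#' The initial weight carried by each isotropic emission photon is the
#' excitation efficiency at the quantum-dot depth relative to the
#' shallowest (0.4 mm) depth.  With `table = NULL` the rounded preset
#' constants are returned (1, 0.011, 0.0015 and 0.0005 at depths 0.4, 0.8,
#' 1.4 and 2.0 mm); with a computed [excitation_efficiency()] table the
#' ratio is taken from the simulation.
#'
#' @param z_qd Quantum-dot depth(s) in cm.
#' @param table Optional `excitation_table`.
#' @return Inherited weight(s) in (0, 1].
#' @examples
#' inherited_weight(0.08)  # 0.011
#' @export
inherited_weight <- function(z_qd, table = NULL) {
  if (is.null(table)) {
    key <- as.character(round(z_qd, 6))
    w <- unname(INHERITED_WEIGHT_PRESETS[key])
    if (any(is.na(w)))
      stop("no preset inherited weight for depth(s) ",
           paste(z_qd[is.na(w)], collapse = ", "),
           " cm; supply a computed excitation table")
    return(w)
  }
  stopifnot(inherits(table, "excitation_table"))
  iref <- which(abs(table$z_qd - min(table$z_qd)) < 1e-9)[1]
  ref <- table$intensity[iref]
  if (!is.finite(ref) || ref <= 0)
    stop("reference depth intensity is zero; cannot form inherited weights")
  vapply(z_qd, function(z) {
    i <- which(abs(table$z_qd - z) < 1e-9)
    if (!length(i)) stop("depth ", z, " cm not present in the table")
    table$intensity[i[1]] / ref
  }, numeric(1))
}

#' Run an isotropic fluorescence emission simulation
#'
#' Launches `source$n_emit` photons from the quantum-dot position with
#' isotropic directions and the inherited initial weight, and transports
#' them through the 1100 nm stack (upward through CSF, skull, skin and the
#' air guard layer; downward into the semi-infinite cortex, from which they
#' may backscatter).  Every photon leaving the top surface is recorded with
#' its exit radius, polar exit angle in the ambient medium, and residual
#' weight.
#'
#' @param source A [fluor_source()].
#' @param stack The 1100 nm emission stack (must include the air guard
#'   layer above the skin for the bundled preset geometry).
#' @param seed Optional seed.
#' @param ... Further arguments passed to [run_transport()].
#' @return A `transport_result` with populated `exits`.
#' @export
run_emission <- function(source, stack = default_stack("emission_1100"),
                         seed = NULL, ...) {
  stopifnot(inherits(source, "fluor_source"), inherits(stack, "layer_stack"))
  zb <- stack$z_boundaries
  if (source$z >= zb[length(zb)])
    stop("source depth ", source$z, " cm lies below the bottom of the stack")
  if (source$z < zb[1])
    stop("source depth ", source$z, " cm lies above the top of the stack")
  run_transport(stack, source, n_photons = source$n_emit, seed = seed,
                record_exits = TRUE, ...)
}

#' Sweep the initial photon weight
#'
#' Repeats a transport simulation over a set of initial photon weights
#' (e.g. 0.05 to 1), re-seeding identically before each run so that runs
#' differ only through the weight (and through weight-dependent roulette
#' decisions).
#'
#' @param weights Initial weights in (0, 1].
#' @param stack A [layer_stack()].
#' @param n_photons Photons per run.
#' @param seed Seed applied before every run.
#' @param source_depth `NULL` for a pencil beam entering the surface, or a
#'   depth in cm for an isotropic fluorescence source.
#' @param ... Further arguments passed to [run_transport()].
#' @return Named list of `transport_result`s, one per weight.
#' @export
weight_sweep <- function(weights = c(0.05, 0.25, 0.5, 1),
                         stack = default_stack("excitation_785"),
                         n_photons = 1e5, seed = 1, source_depth = NULL,
                         ...) {
  stopifnot(all(weights > 0), all(weights <= 1))
  out <- lapply(weights, function(w) {
    src <- if (is.null(source_depth)) pencil_source(weight = w)
           else fluor_source(source_depth, weight = w, n_emit = n_photons)
    run_transport(stack, src, n_photons = n_photons, seed = seed, ...)
  })
  names(out) <- as.character(weights)
  out
}
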