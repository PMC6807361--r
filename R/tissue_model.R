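#' Optical properties of one tissue layer
#'
#' A single plane-parallel layer of the head model, described by its
#' refractive index, absorption and scattering coefficients, scattering
#' anisotropy, and thickness.
#'
#' @param name Text label, e.g. `"skin"`.
#' @param n Refractive index (>= 1).
#' @param mu_a Absorption coefficient (cm^-1, >= 0).
#' @param mu_s Scattering coefficient (cm^-1, >= 0).
#' @param g Scattering anisotropy, the mean cosine of the single-scattering
#'   deflection angle (-1..1).  For a clear layer (`mu_s = 0`) the value is
#'   irrelevant; `g = 1` is the conventional no-op marker.
#' @param thickness Layer thickness in cm (> 0).  `Inf` is allowed for the
#'   bottom layer of a stack and marks a semi-infinite substrate.
#' @return A one-row data frame with columns `name`, `n`, `mu_a`, `mu_s`,
#'   `g`, `thickness`.
#' @examples
#' layer("skin", n = 1.37, mu_a = 1.62, mu_s = 238.9, g = 0.9, thickness = 0.02)
#' @export
layer <- function(name, n, mu_a, mu_s, g, thickness) {
  df <- data.frame(name = as.character(name), n = as.numeric(n),
                   mu_a = as.numeric(mu_a), mu_s = as.numeric(mu_s),
                   g = as.numeric(g), thickness = as.numeric(thickness),
                   stringsAsFactors = FALSE)
  validate_layers(df)
  df
}

validate_layers <- function(layers) {
  req <- c("name", "n", "mu_a", "mu_s", "g", "thickness")
  missing <- setdiff(req, names(layers))
  if (length(missing))
    stop("layer table is missing field(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(layers$n)) || any(layers$n < 1))
    stop("refractive index n must be finite and >= 1")
  if (any(!is.finite(layers$mu_a)) || any(layers$mu_a < 0))
    stop("absorption coefficient mu_a must be finite and >= 0")
  if (any(!is.finite(layers$mu_s)) || any(layers$mu_s < 0))
    stop("scattering coefficient mu_s must be finite and >= 0")
  if (any(!is.finite(layers$g)) || any(layers$g < -1) || any(layers$g > 1))
    stop("anisotropy g must lie in [-1, 1]")
  if (any(is.na(layers$thickness)) || any(layers$thickness <= 0))
    stop("layer thickness must be > 0 (Inf allowed only for the bottom layer)")
  if (nrow(layers) > 1 && any(is.infinite(layers$thickness[-nrow(layers)])))
    stop("only the bottom layer may have infinite thickness")
  invisible(layers)
}

#' Assemble a validated layered tissue stack
#'
#' @param layers A data frame of layers (top to bottom), e.g. built by
#'   [rbind()]-ing [layer()] rows.
#' @param wavelength_tag `"excitation_785"`, `"emission_1100"`, or
#'   `"custom"`.
#' @param ambient_above_n Refractive index of the medium above the top
#'   layer (default 1, air).
#' @param z_top Depth coordinate (cm) of the top surface of the first
#'   layer.  0 for a stack whose first layer is the scalp skin; negative
#'   when a guard layer (e.g. air) sits above the skin.
#' @return An object of class `layer_stack` with fields `wavelength_tag`,
#'   `ambient_above_n`, `layers`, and the derived `z_boundaries` (cm,
#'   strictly increasing, `z_top` first).
#' @seealso [default_stack()] for the bundled mouse-head presets.
#' @export
layer_stack <- function(layers,
                        wavelength_tag = c("custom", "excitation_785",
                                           "emission_1100"),
                        ambient_above_n = 1, z_top = 0) {
  wavelength_tag <- match.arg(wavelength_tag)
  layers <- as.data.frame(layers, stringsAsFactors = FALSE)
  validate_layers(layers)
  if (!is.finite(ambient_above_n) || ambient_above_n < 1)
    stop("ambient_above_n must be finite and >= 1")
  if (!is.finite(z_top)) stop("z_top must be finite")
  zb <- z_top + cumsum(c(0, layers$thickness))
  if (any(diff(zb) <= 0)) stop("z boundaries must be strictly increasing")
  structure(list(wavelength_tag = wavelength_tag,
                 ambient_above_n = ambient_above_n,
                 layers = layers, z_boundaries = zb),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack> ", x$wavelength_tag,
      "  (ambient n above = ", x$ambient_above_n, ")\n", sep = "")
  df <- x$layers
  df$z_from <- utils::head(x$z_boundaries, -1)
  df$z_to <- utils::tail(x$z_boundaries, -1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bundled four-layer mouse-head stacks
#'
#' Optical properties of the hairless-mouse head model at the 785 nm
#' excitation and 1100 nm emission wavelengths: refractive index,
#' absorption and scattering coefficients (cm^-1), anisotropy, and
#' anatomical thicknesses of 0.2 mm scalp skin, 0.1 mm skull and 0.1 mm
#' cerebrospinal fluid.  The emission stack carries a 0.1 mm air layer
#' above the skin, so its top surface sits at z = -0.01 cm.
#'
#' The cortex below the CSF is treated as an effectively semi-infinite
#' substrate: whatever `cortex_thickness` is requested, the modeled slab is
#' at least 1 cm deep, and photons crossing its bottom are terminated and
#' tallied as transmitted.  Quantum-dot source depths (0.4, 0.8, 1.4,
#' 2.0 mm from the scalp surface) are properties of the fluorophore source,
#' not of the stack; see [fluor_source()].
#'
#' @param wavelength_tag `"excitation_785"` or `"emission_1100"`.
#' @param cortex_thickness Requested cortex slab thickness in cm (>= 0);
#'   values below 1 cm are padded to 1 cm so the slab behaves as a
#'   semi-infinite substrate.
#' @return A [layer_stack()].
#' @examples
#' default_stack("excitation_785")$layers
#' @export
default_stack <- function(wavelength_tag = c("excitation_785",
                                             "emission_1100"),
                          cortex_thickness = 1.0) {
  wavelength_tag <- match.arg(wavelength_tag)
  if (!is.finite(cortex_thickness) || cortex_thickness < 0)
    stop("cortex_thickness must be >= 0")
  cortex_cm <- max(cortex_thickness, 1.0)
  if (wavelength_tag == "excitation_785") {
    layers <- rbind(
      layer("skin",   n = 1.37,  mu_a = 1.62,  mu_s = 238.9, g = 0.9,
            thickness = 0.02),
      layer("skull",  n = 1.454, mu_a = 0.087, mu_s = 162.7, g = 0.9,
            thickness = 0.01),
      layer("csf",    n = 1.33,  mu_a = 0.1,   mu_s = 0,     g = 1,
            thickness = 0.01),
      layer("cortex", n = 1.368, mu_a = 0.087, mu_s = 76.2,  g = 0.9,
            thickness = cortex_cm))
    layer_stack(layers, wavelength_tag, ambient_above_n = 1, z_top = 0)
  } else {
    layers <- rbind(
      layer("air",    n = 1,     mu_a = 0.001, mu_s = 0,     g = 1,
            thickness = 0.01),
      layer("skin",   n = 1.37,  mu_a = 0.35,  mu_s = 171.5, g = 0.9,
            thickness = 0.02),
      layer("skull",  n = 1.45,  mu_a = 0.4,   mu_s = 135.6, g = 0.9,
            thickness = 0.01),
      layer("csf",    n = 1.33,  mu_a = 1,     mu_s = 0,     g = 1,
            thickness = 0.01),
      layer("cortex", n = 1.368, mu_a = 0.5,   mu_s = 71.4,  g = 0.9,
            thickness = cortex_cm))
    layer_stack(layers, wavelength_tag, ambient_above_n = 1, z_top = -0.01)
  }
}

#' Index of the layer containing a depth
#'
#' A depth lying exactly on an interior boundary resolves to the layer
#' below it (the z-increasing convention); the bottom boundary itself still
#' belongs to the last layer.
#'
#' @param stack A [layer_stack()].
#' @param z Depth in cm; must lie within the stack span.
#' @return Integer layer index (1-based, top layer = 1).
#' @export
layer_at_depth <- function(stack, z) {
  stopifnot(inherits(stack, "layer_stack"), is.numeric(z), length(z) == 1)
  zb <- stack$z_boundaries
  nlay <- nrow(stack$layers)
  if (!is.finite(z) || z < zb[1] || z > zb[length(zb)])
    stop("depth z = ", z, " cm lies outside the stack span [",
         zb[1], ", ", zb[length(zb)], "] cm")
  min(findInterval(z, zb), nlay)
}

#' Write a layer stack to a YAML configuration file
#'
#' @param stack A [layer_stack()].
#' @param path Output file path.
#' @param units `"cm"` or `"mm"`; lengths (thickness, z_top) are written in
#'   this unit.  Attenuation coefficients are always cm^-1.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path, units = c("cm", "mm")) {
  stopifnot(inherits(stack, "layer_stack"))
  units <- match.arg(units)
  f <- if (units == "mm") 10 else 1
  cfg <- list(
    wavelength_tag = stack$wavelength_tag,
    units = units,
    ambient_above_n = stack$ambient_above_n,
    z_top = stack$z_boundaries[1] * f,
    layers = lapply(seq_len(nrow(stack$layers)), function(i) {
      L <- stack$layers[i, ]
      list(name = L$name, n = L$n, mu_a = L$mu_a, mu_s = L$mu_s, g = L$g,
           thickness = L$thickness * f)
    }))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a layer stack from a YAML configuration file or bundled preset
#'
#' The configuration must declare its length unit (`units: cm` or
#' `units: mm`); lengths in mm are converted to cm internally.  The bundled
#' presets `"mousehead_785"` and `"mousehead_1100"` carry the default
#' mouse-head optical parameters in mm, exactly as tabulated.
#'
#' @param path Path to a YAML stack file, or a bundled preset name.
#' @return A validated [layer_stack()].
#' @examples
#' identical_stack <- load_stack("mousehead_785")
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("extdata", paste0(path, ".yaml"), package = "nirmc")
    if (nzchar(preset)) path <- preset
    else stop("no such stack file or preset: ", path)
  }
  cfg <- yaml::read_yaml(path)
  req <- c("units", "layers")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("stack config is missing field(s): ", paste(missing, collapse = ", "))
  if (!cfg$units %in% c("cm", "mm"))
    stop("units must be 'cm' or 'mm', got: ", cfg$units)
  f <- if (cfg$units == "mm") 0.1 else 1
  rows <- lapply(cfg$layers, function(L) {
    # YAML 1.1 parses a bare key `n` as boolean FALSE; map it back
    names(L)[names(L) == "FALSE"] <- "n"
    miss <- setdiff(c("name", "n", "mu_a", "mu_s", "g", "thickness"), names(L))
    if (length(miss))
      stop("layer entry is missing field(s): ", paste(miss, collapse = ", "))
    th <- L$thickness
    if (identical(th, "infinite")) th <- Inf
    layer(L$name, L$n, L$mu_a, L$mu_s, L$g, as.numeric(th) * f)
  })
  layer_stack(do.call(rbind, rows),
              wavelength_tag = if (is.null(cfg$wavelength_tag)) "custom"
                               else cfg$wavelength_tag,
              ambient_above_n = if (is.null(cfg$ambient_above_n)) 1
                                else cfg$ambient_above_n,
              z_top = if (is.null(cfg$z_top)) 0 else cfg$z_top * f)
}
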