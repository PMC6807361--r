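# CSV writer serializing doubles with 17 significant digits, so that a
# write/read round trip is bit-exact.
write_csv_full_precision <- function(df, con) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
}

#' Write and read a fluence grid as CSV
#'
#' The grid is written in long format (`r_lo, r_hi, z_lo, z_hi,
#' absorbed_weight, fluence`), one row per cell including empty cells, with
#' the grid geometry, overflow and normalization metadata in `#`-prefixed
#' header lines.  Numbers are serialized at full double precision, so a
#' write/read round trip preserves the accumulators exactly.
#'
#' @param result A `transport_result`.
#' @param path Output CSV path.
#' @param mode Normalization mode passed to [fluence_map()].
#' @return `path`, invisibly.
#' @export
write_fluence_csv <- function(result, path, mode = "per_area") {
  stopifnot(inherits(result, "transport_result"))
  g <- result$grid
  meta <- c(
    "# nirmc fluence grid",
    sprintf("# dr=%.17g dz=%.17g nr=%d nz=%d z_min=%.17g", g$dr, g$dz,
            g$nr, g$nz, g$z_min),
    sprintf("# overflow=%.17g n_launched=%.17g initial_weight=%.17g mode=%s",
            g$overflow, g$n_launched, g$initial_weight, mode))
  df <- fluence_map(result, mode = mode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write_csv_full_precision(df, con)
  invisible(path)
}

#' @rdname write_fluence_csv
#' @return For `read_fluence_csv()`: a list with the cell data frame
#'   (`cells`) and the parsed `meta` fields.
#' @export
read_fluence_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- unlist(regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr)))
  meta <- list()
  for (pair in kv) {
    k <- sub("=.*", "", pair)
    v <- sub("^[a-z_]+=", "", pair)
    meta[[k]] <- if (k == "mode") v else as.numeric(v)
  }
  cells <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  list(cells = cells, meta = meta)
}

#' Reconstruct the accumulator matrix from a fluence CSV
#'
#' @param path Path written by [write_fluence_csv()].
#' @return Numeric `nr x nz` matrix of absorbed weight.
#' @export
read_fluence_matrix <- function(path) {
  x <- read_fluence_csv(path)
  matrix(x$cells$absorbed_weight, nrow = x$meta$nr, ncol = x$meta$nz)
}

#' Write and read a radial emission profile as CSV
#'
#' Columns `bin_lo_mm, bin_hi_mm, intensity, fraction_of_first, count`;
#' accepted totals ride along in `#`-prefixed header lines.  Empty bins
#' are preserved as zeros.
#'
#' @param profile A `radial_profile` from [collect()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# accepted_count=%.17g accepted_weight=%.17g",
                     attr(profile, "accepted_count"),
                     attr(profile, "accepted_weight")), con)
  write_csv_full_precision(
    profile[, c("bin_lo_mm", "bin_hi_mm", "intensity", "fraction_of_first",
                "count")], con)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  prof <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  get_meta <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    as.numeric(sub(".*=", "", m[1]))
  }
  attr(prof, "accepted_count") <- get_meta("accepted_count")
  attr(prof, "accepted_weight") <- get_meta("accepted_weight")
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

#' Write exit records as CSV
#'
#' Columns `exit_r_mm, exit_angle_deg, weight`, one row per photon that
#' left the top surface.
#'
#' @param result A `transport_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exits_csv <- function(result, path) {
  stopifnot(inherits(result, "transport_result"))
  df <- data.frame(exit_r_mm = result$exits$r_cm * 10,
                   exit_angle_deg = result$exits$angle_deg,
                   weight = result$exits$weight)
  con <- file(path, "w")
  on.exit(close(con))
  write_csv_full_precision(df, con)
  invisible(path)
}

#' Write and read the weight ledger as JSON
#'
#' On read the conservation identity (launched weight = specular +
#' absorbed + escaped + transmitted + net roulette loss +
#' boundary-stripped) is re-validated to 1e-6 relative error.
#'
#' @param result A `transport_result` (or a named ledger vector).
#' @param path JSON path.
#' @return `path`, invisibly; `read_ledger_json()` returns the named
#'   ledger vector.
#' @export
write_ledger_json <- function(result, path) {
  ledger <- if (inherits(result, "transport_result")) result$ledger
            else result
  jsonlite::write_json(as.list(ledger), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
read_ledger_json <- function(path) {
  ledger <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  err <- ledger_conservation_error(ledger)
  if (err > 1e-6)
    stop("ledger read from ", path, " violates weight conservation (",
         err, " relative)")
  ledger
}

#' Run-configuration objects
#'
#' A run configuration is a plain named list (subcommand, stack preset or
#' path, photon count, seed, boundary mode, roulette, grid and detector
#' parameters, output directory).  It serializes to YAML, and its MD5 hash
#' — computed on a canonical serialization with names sorted, so equal
#' configurations hash equally — names the provenance of every output
#' file.
#'
#' @param ... Named configuration fields.
#' @return For `run_config()`: the classed list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration fields must be named")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config` (or plain named list).
#' @param path YAML path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' @rdname run_config
#' @return For `config_hash()`: the 32-character MD5 hex digest.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp, precision = 15)
  unname(tools::md5sum(tmp))
}
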