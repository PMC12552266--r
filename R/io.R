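## CSV dialects: long-format property tables and AUC scan sets with
## comment-line metadata headers.  All writers/readers are lossless round
## trips at full double precision.

#' Read and write property tables
#'
#' Long-format CSV with header `species,property,value,unit,sigma` (the
#' `unit` and `sigma` columns are optional).  Property names must be among
#' `D`, `s`, `f`, `eta_intr`, `Rg`, `M`, `vbar`, `delta`; malformed rows and
#' unknown properties are rejected with their line numbers.  On reading,
#' recognised units are converted to the package's CGS conventions (for
#' example `dL_per_g` intrinsic viscosities become cm^3/g, `S` becomes
#' seconds).
#'
#' @param path File path.
#' @param props Tibble with columns `species`, `property`, `value` and
#'   optionally `unit`, `sigma`.
#' @return `read_property_table()` returns the tibble (values in CGS,
#'   `unit` column dropped after conversion); `write_property_table()`
#'   returns `path` invisibly.
#' @export
read_property_table <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("species", "property", "value")
  if (!all(need %in% names(raw))) {
    abort("Property CSV must have columns species, property, value.")
  }
  known <- c("D", "s", "f", "eta_intr", "Rg", "M", "vbar", "delta")
  bad <- which(!(raw$property %in% known) | !is.finite(raw$value))
  if (length(bad) > 0) {
    abort(sprintf("Malformed or unknown property rows at line(s): %s.",
                  paste(bad + 1, collapse = ", ")))
  }
  out <- .normalize_props(raw)
  out$unit <- NULL
  out
}

#' @rdname read_property_table
#' @export
write_property_table <- function(props, path) {
  props <- tibble::as_tibble(props)
  cols <- intersect(c("species", "property", "value", "unit", "sigma"),
                    names(props))
  readr::write_csv(props[cols], path)
  invisible(path)
}

#' Read and write AUC scan sets
#'
#' CSV with `# key=value` metadata lines (`omega_rpm`, `meniscus_cm`,
#' `bottom_cm`, `temperature_K`, `viscosity_poise`, and optionally `seed`,
#' `noise_sd`, `engine`) followed by rows `scan_id,time_s,radius_cm,signal`.
#' Scans are sorted by time on load; radii outside the cell raise a
#' validation error; missing metadata keys are named in the error.
#'
#' @param path File path.
#' @param ss A `scan_set`.
#' @return `read_scanset()` returns a `scan_set`; `write_scanset()` returns
#'   `path` invisibly.
#' @export
read_scanset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- c("omega_rpm", "meniscus_cm", "bottom_cm", "temperature_K",
            "viscosity_poise")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(sprintf("Scan CSV is missing metadata key(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  num <- function(k, default = NA_real_) {
    if (k %in% names(meta)) as.numeric(meta[[k]]) else default
  }
  scans <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE) |>
    dplyr::arrange(.data$time_s, .data$radius_cm)
  geom <- cell_geometry(num("meniscus_cm"), num("bottom_cm"))
  if (any(scans$radius_cm < geom$r_m - 1e-12) ||
      any(scans$radius_cm > geom$r_b + 1e-12)) {
    abort("Scan radii outside the cell [meniscus, bottom].")
  }
  run <- rotor_run(rpm = num("omega_rpm"),
                   scan_times_s = sort(unique(scans$time_s)))
  ctx <- solvent_context(num("temperature_K"), num("viscosity_poise"))
  .new_scan_set(scans, geom, run, ctx,
                engine = meta[["engine"]] %||% "file",
                noise_sigma = num("noise_sd", 0),
                seed = if ("seed" %in% names(meta))
                  as.integer(meta[["seed"]]) else NA_integer_)
}

#' @rdname read_scanset
#' @export
write_scanset <- function(ss, path) {
  stopifnot(inherits(ss, "scan_set"))
  hdr <- c(
    sprintf("# omega_rpm=%.15g", ss$run$omega * 60 / (2 * pi)),
    sprintf("# meniscus_cm=%.17g", ss$geometry$r_m),
    sprintf("# bottom_cm=%.17g", ss$geometry$r_b),
    sprintf("# temperature_K=%.17g", ss$temperature_K),
    sprintf("# viscosity_poise=%.17g", ss$viscosity_poise),
    sprintf("# engine=%s", ss$engine),
    sprintf("# noise_sd=%.17g", ss$noise_sigma %||% 0))
  if (!is.na(ss$seed %||% NA_integer_)) {
    hdr <- c(hdr, sprintf("# seed=%d", ss$seed))
  }
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  readr::write_csv(
    ss$scans[c("scan_id", "time_s", "radius_cm", "signal")],
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}
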