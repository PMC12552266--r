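## Synthetic-data generators.  These define the study conditions of every
## closed-loop test: a shape model generates equivalent radii, radii
## generate observables, and the forward AUC engines generate scan sets;
## multiplicative (property) or additive (scan) noise is applied on top.
## The generating truth is always stored alongside for recovery checks.

#' Synthetic multi-property reference dataset
#'
#' Generates per-species equivalent radii from a shape-model truth, applies
#' independent multiplicative log-normal-free noise (value * (1 +
#' noise_rel * z), z standard normal) per radius, and returns the long
#' reference tibble used by [hydfit()], with the truth in the
#' `truth` attribute.
#'
#' @param truth Named list: `model` (`"sphere"`, `"spheroid"` or
#'   `"wlc_rg"`) plus its parameters (`aV`; `p` and `aV`; or `L_nm`, `P_nm`
#'   for the Rg-only wormlike chain).
#' @param n_species Number of replicate species (default 1).  For the
#'   wormlike chain, species are a mass series: `L_nm` is scaled by
#'   1, 2, ..., n_species.
#' @param properties Which radii to report (default `c("aT","aI","aG")`).
#' @param noise_rel Relative noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return Long tibble (`species`, `radius`, `value`) with attribute
#'   `truth`.
#' @export
synthetic_property_dataset <- function(truth = list(model = "spheroid",
                                                    p = 4, aV = 3e-7),
                                       n_species = 1L,
                                       properties = c("aT", "aI", "aG"),
                                       noise_rel = 0, seed = 1L) {
  set.seed(seed)
  base <- switch(
    truth$model,
    sphere = tibble::tibble(radius = c("aT", "aI", "aG", "aV"),
                            value = truth$aV),
    spheroid = {
      r <- spheroid_radii(spheroid(p = truth$p, aV = truth$aV))
      tibble::tibble(radius = c("aT", "aI", "aG", "aV"),
                     value = c(r$aT, r$aI, r$aG, r$aV))
    },
    wlc_rg = NULL,
    abort("Unknown truth model."))
  rows <- purrr::map_dfr(seq_len(n_species), function(i) {
    if (truth$model == "wlc_rg") {
      Rg_nm <- wlc_gyration_radius(truth$L_nm * i, truth$P_nm)
      tb <- tibble::tibble(radius = "aG",
                           value = sqrt(5 / 3) * Rg_nm * 1e-7)
    } else {
      tb <- base
    }
    tb |>
      dplyr::filter(.data$radius %in% properties) |>
      dplyr::mutate(species = sprintf("sp%02d", i), .before = 1)
  })
  rows$value <- rows$value * (1 + noise_rel * rnorm(nrow(rows)))
  attr(rows, "truth") <- truth
  attr(rows, "seed") <- seed
  attr(rows, "noise_rel") <- noise_rel
  rows
}

#' Synthetic AUC scan set
#'
#' Runs one of the forward engines on a species list and adds independent
#' Gaussian signal noise of constant standard deviation.  Everything needed
#' to regenerate the set (engine, seed, noise) is stored in the scan-set
#' metadata.
#'
#' @param species [sedimenting_species()] or list of them.
#' @param run A [rotor_run()].
#' @param geometry A [cell_geometry()].
#' @param ctx A [solvent_context()].
#' @param engine `"lamm"` or `"bd"`.
#' @param noise_sd Additive signal noise standard deviation (default 0).
#' @param seed Integer seed (drives both the BD engine and the noise).
#' @param ... Passed to the engine ([lamm_solve()] or [bd_simulate()]).
#' @return A `scan_set`.
#' @export
synthetic_auc_dataset <- function(species, run, geometry, ctx,
                                  engine = c("lamm", "bd"),
                                  noise_sd = 0, seed = 1L, ...) {
  engine <- match.arg(engine)
  fun <- if (engine == "lamm") lamm_solve else bd_simulate
  dots <- list(...)
  dots <- dots[names(dots) %in% names(formals(fun))]
  args <- c(list(species, run, geometry, ctx), dots)
  if (engine == "bd") args$seed <- seed
  ss <- do.call(fun, args)
  if (noise_sd > 0) {
    set.seed(seed + 1L)
    ss$scans$signal <- ss$scans$signal + rnorm(nrow(ss$scans), sd = noise_sd)
  }
  ss$noise_sigma <- noise_sd
  ss$seed <- as.integer(seed)
  ss
}
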