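## Inversion of sedimentation-velocity scans into a non-negative
## distribution on a grid of (hydrodynamic radius, buoyant particle mass).
## These two coordinates determine the full time course of sedimentation
## without any knowledge of the partial specific volume; vbar enters only
## when converting the recovered distribution to (s, f/f0) or (s, D).

#' Two-dimensional analysis grid in (R_H, m_b)
#'
#' @param rh_range Range `c(lo, hi)` of hydrodynamic radii (cm).
#' @param mb_range Range `c(lo, hi)` of buoyant particle masses (g).
#' @param n Nodes per axis, length-2 integer (default `c(20, 20)`).
#' @param spacing `"log"` (default; s and D span decades) or `"linear"`.
#' @return A tibble of grid nodes with columns `node`, `RH_cm`, `Mb_g`,
#'   classed `rh_mb_grid`; axis values kept as attributes.
#' @export
rh_mb_grid <- function(rh_range, mb_range, n = c(20L, 20L),
                       spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(length(rh_range) == 2, length(mb_range) == 2,
            all(rh_range > 0), all(mb_range > 0),
            rh_range[1] < rh_range[2], mb_range[1] < mb_range[2],
            all(n >= 2))
  ax <- function(rng, k) {
    if (spacing == "log") exp(seq(log(rng[1]), log(rng[2]), length.out = k))
    else seq(rng[1], rng[2], length.out = k)
  }
  rh <- ax(rh_range, n[1]); mb <- ax(mb_range, n[2])
  g <- tidyr::expand_grid(RH_cm = rh, Mb_g = mb) |>
    dplyr::mutate(node = dplyr::row_number(), .before = 1)
  attr(g, "rh_values") <- rh
  attr(g, "mb_values") <- mb
  attr(g, "spacing") <- spacing
  class(g) <- c("rh_mb_grid", class(g))
  g
}

#' Design matrix of unit-species scan signals
#'
#' Column j holds the stacked scan signal of a unit-concentration species at
#' grid node j, computed with the Lamm solver on the geometry, rotor run and
#' radial grid of the data.  Rows can be subsampled (every k-th radius) to
#' keep the matrix at desk scale.
#'
#' @param grid A [rh_mb_grid()].
#' @param ss The `scan_set` to be analysed (supplies geometry, run, solvent
#'   and the radius/time sampling).
#' @param subsample_radii Keep every k-th radial point (default 1 = all).
#' @param radial_points Radial cells for the forward solves; `NULL`
#'   (default) matches the radial sampling of the data so that forward
#'   discretisation error largely cancels between data and design.
#' @param courant Courant target for the forward solves (see
#'   [lamm_solve()]).
#' @return A list with `A` (matrix, observations x nodes), `obs` (tibble of
#'   the retained observation rows) and `grid`.
#' @export
design_matrix <- function(grid, ss, subsample_radii = 1L,
                          radial_points = NULL, courant = 0.5) {
  stopifnot(inherits(grid, "rh_mb_grid"))
  ctx <- solvent_context(ss$temperature_K, ss$viscosity_poise)
  times <- sort(unique(ss$scans$time_s))
  run <- rotor_run(omega = ss$run$omega, scan_times_s = times)
  data_r <- sort(unique(ss$scans$radius_cm))
  radial_points <- radial_points %||% max(50L, length(data_r))
  keep_r <- data_r[seq(1, length(data_r), by = subsample_radii)]
  obs <- ss$scans |>
    dplyr::filter(.data$radius_cm %in% keep_r) |>
    dplyr::arrange(.data$time_s, .data$radius_cm)
  A <- matrix(0, nrow(obs), nrow(grid))
  for (j in seq_len(nrow(grid))) {
    sp <- sedimenting_species(RH_cm = grid$RH_cm[j], mb_g = grid$Mb_g[j],
                              c0 = 1)
    sol <- tryCatch(
      lamm_solve(sp, run, ss$geometry, ctx, radial_points = radial_points,
                 courant = courant),
      error = function(e) {
        abort(sprintf("Forward solve failed at node %d (RH = %.3g cm, mb = %.3g g): %s",
                      j, grid$RH_cm[j], grid$Mb_g[j], conditionMessage(e)))
      })
    ## interpolate the solver grid onto the data radii, per scan
    sig <- sol$scans |>
      dplyr::group_by(.data$time_s) |>
      dplyr::group_map(function(tbl, key) {
        approx(tbl$radius_cm, tbl$signal, xout = keep_r, rule = 2)$y
      })
    A[, j] <- unlist(sig)
  }
  list(A = A, obs = obs, grid = grid,
       subsample_radii = subsample_radii)
}

#' Recover a c(R_H, m_b) distribution from sedimentation scans
#'
#' Solves the regularised non-negative least-squares problem
#' \deqn{\min_{w \ge 0} \|A w - z\|^2 + \lambda^2 \|w\|^2}
#' with `A` the design matrix of unit-species signals and `z` the stacked
#' scan data, using the Lawson--Hanson active-set algorithm
#' (`pracma::lsqnonneg`) on the ridge-augmented system.  No partial
#' specific volume is needed at this stage.
#'
#' With `lambda = "auto"` the ridge weight is chosen by the discrepancy
#' principle: the smallest of a short log-spaced ladder whose residual RMS
#' does not exceed the recorded scan noise (falls back to 0 when the scan
#' set carries no noise).
#'
#' @param ss A `scan_set`.
#' @param grid A [rh_mb_grid()].
#' @param lambda Ridge weight (>= 0), or `"auto"`.
#' @param subsample_radii,radial_points Passed to [design_matrix()].
#' @param design Optional precomputed [design_matrix()] result (cache).
#' @return An object of class `distribution2d`: the grid tibble with a
#'   `weight` column plus fields `residual_rms`, `lambda`, `total_signal`.
#' @export
solve_distribution <- function(ss, grid, lambda = "auto",
                               subsample_radii = 1L, radial_points = NULL,
                               design = NULL) {
  dm <- design %||% design_matrix(grid, ss, subsample_radii, radial_points)
  z <- dm$obs$signal
  nnls_at <- function(lam) {
    Aaug <- if (lam > 0) rbind(dm$A, diag(lam, ncol(dm$A))) else dm$A
    zaug <- if (lam > 0) c(z, rep(0, ncol(dm$A))) else z
    w <- pracma::lsqnonneg(Aaug, zaug)$x
    list(w = w, rms = sqrt(mean((dm$A %*% w - z)^2)), lam = lam)
  }
  if (all(z == 0)) {
    warn("All-zero signal: returning the zero distribution.")
    w <- rep(0, ncol(dm$A)); rms <- 0; lam <- 0
  } else if (identical(lambda, "auto")) {
    noise <- ss$noise_sigma %||% 0
    best <- nnls_at(0)
    if (!is.na(noise) && noise > 0 && best$rms < noise) {
      ## discrepancy principle: largest lambda whose misfit stays at or
      ## below the recorded noise level
      for (lam in 10^seq(-3, 0, length.out = 7) * sqrt(mean(z^2))) {
        cand <- nnls_at(lam)
        if (cand$rms <= noise) best <- cand else break
      }
    }
    w <- best$w; rms <- best$rms; lam <- best$lam
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    best <- nnls_at(lambda)
    w <- best$w; rms <- best$rms; lam <- best$lam
  }
  out <- dm$grid |> dplyr::mutate(weight = w)
  attr(out, "residual_rms") <- rms
  attr(out, "lambda") <- lam
  attr(out, "total_signal") <- sum(w)
  attr(out, "rh_values") <- attr(dm$grid, "rh_values")
  attr(out, "mb_values") <- attr(dm$grid, "mb_values")
  class(out) <- unique(c("distribution2d", "rh_mb_grid",
                         class(tibble::tibble())))
  out
}

#' Convert a (R_H, m_b) distribution to conventional coordinates
#'
#' Maps every node to \eqn{s = m_b/(6\pi\eta_0 R_H)},
#' \eqn{D = k_B T/(6\pi\eta_0 R_H)}, \eqn{M = N_A m_b/(1-\bar v\rho)} and
#' the frictional ratio \eqn{f/f_0 = R_H/a_V(M,\bar v')}, carrying the
#' weights over unchanged.  A single \eqn{\bar v} must apply to all
#' components — the standard caveat of (s, f/f0) or (s, D) presentations,
#' and exactly the information the (R_H, m_b) parameterisation avoids
#' needing during the fit.
#'
#' @param dist A `distribution2d`.
#' @param solute A [solute_spec()] whose `vbar` (and `delta`) apply to all
#'   nodes; its `M` field is ignored.
#' @param ctx A [solvent_context()].
#' @return A tibble with `RH_cm`, `Mb_g`, `weight`, `s_s`, `s_S`,
#'   `D_cm2_s`, `M_Da`, `ff0`.
#' @export
convert_distribution <- function(dist, solute, ctx) {
  ctx <- .as_ctx(ctx); solute <- .as_solute(solute)
  b <- .buoyancy(solute, ctx)
  f <- 6 * pi * ctx$eta0 * dist$RH_cm
  M <- .NA * dist$Mb_g / b
  vbar_h <- solute$vbar + solute$delta / ctx$rho
  aV <- (3 * M * vbar_h / (4 * pi * .NA))^(1 / 3)
  tibble::tibble(
    RH_cm = dist$RH_cm, Mb_g = dist$Mb_g, weight = dist$weight,
    s_s = dist$Mb_g / f, s_S = dist$Mb_g / f / 1e-13,
    D_cm2_s = .kB * ctx$T / f, M_Da = M, ff0 = dist$RH_cm / aV)
}

#' Extract peaks from a 2D distribution
#'
#' Connected components of nodes whose weight exceeds a relative threshold,
#' reported as weight-weighted centroids in log coordinates.  Adjacency is
#' Chebyshev distance `gap` on the grid (default 2): non-negative
#' least-squares solutions are spiky, and a species just off a grid node is
#' typically represented by a small cluster of near-adjacent spikes that
#' belong to one physical component.
#'
#' @param dist A `distribution2d`.
#' @param threshold Relative threshold as a fraction of the maximum weight
#'   (default 0.05).
#' @param gap Chebyshev adjacency radius in grid cells (default 2; 1 gives
#'   strict 8-neighbour components).
#' @return Tibble with one row per peak: `peak`, `RH_cm`, `Mb_g`, `weight`
#'   (total), `n_nodes`.
#' @export
find_peaks <- function(dist, threshold = 0.05, gap = 2L) {
  rh <- attr(dist, "rh_values"); mb <- attr(dist, "mb_values")
  W <- matrix(0, length(rh), length(mb))
  ir <- match(dist$RH_cm, rh); im <- match(dist$Mb_g, mb)
  W[cbind(ir, im)] <- dist$weight
  if (max(W) <= 0) {
    return(tibble::tibble(peak = integer(), RH_cm = numeric(),
                          Mb_g = numeric(), weight = numeric(),
                          n_nodes = integer()))
  }
  keep <- W > threshold * max(W)
  nbr <- expand.grid(da = -gap:gap, db = -gap:gap)
  nbr <- nbr[!(nbr$da == 0 & nbr$db == 0), ]
  lab <- matrix(0L, nrow(W), ncol(W)); cur <- 0L
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    if (keep[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        a <- ij[1]; b2 <- ij[2]
        if (a < 1 || b2 < 1 || a > nrow(W) || b2 > ncol(W)) next
        if (!keep[a, b2] || lab[a, b2] != 0L) next
        lab[a, b2] <- cur
        for (q in seq_len(nrow(nbr))) {
          stack <- c(stack, list(c(a + nbr$da[q], b2 + nbr$db[q])))
        }
      }
    }
  }
  if (cur == 0L) return(tibble::tibble(
    peak = integer(), RH_cm = numeric(), Mb_g = numeric(),
    weight = numeric(), n_nodes = integer()))
  purrr::map_dfr(seq_len(cur), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    wts <- W[idx]
    tibble::tibble(
      peak = k,
      RH_cm = exp(sum(wts * log(rh[idx[, 1]])) / sum(wts)),
      Mb_g = exp(sum(wts * log(mb[idx[, 2]])) / sum(wts)),
      weight = sum(wts), n_nodes = nrow(idx))
  }) |>
    dplyr::arrange(dplyr::desc(.data$weight))
}
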