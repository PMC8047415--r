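#' PSD cycle length rule
#'
#' The phase-singularity-distribution initialization assigns the re-entrant
#' wave a cycle length 5% longer than the effective refractory period,
#' rounded to the nearest ms (e.g. ERP 300 ms -> 315 ms, ERP 160 ms ->
#' 168 ms).
#'
#' @param erp effective refractory period, ms (>= 0).
#' @return cycle length in ms.
#' @export
psd_cycle_length <- function(erp) {
  if (any(erp < 0)) .stopf("erp must be non-negative")
  round(1.05 * erp)
}

#' Spiral activation-time map around a seeded phase singularity
#'
#' Constructs an Archimedean-spiral-like activation map
#' `T(x) = mod(s * CL * theta(x) / 2pi + D(x) / v, CL)` where `theta` is the
#' angle around the core (sign `s` set by the chirality), `D` the geodesic
#' (eikonal) distance from the core through conductive tissue, and `v` the
#' conduction speed. The map is CL-periodic and carries exactly one phase
#' singularity at the core. Chirality convention: `"anticlockwise"` means
#' positive winding (topological charge +1) in the standard planar
#' orientation of the sheet.
#'
#' @param geom a `tissue_geometry` (sheet).
#' @param ps_location core position `c(x, y)` mm, on conductive tissue.
#' @param cl cycle length, ms.
#' @param speed eikonal conduction speed, m/s.
#' @param chirality rotation direction.
#' @return object of class `activation_map`: per-node activation times in
#'   `[0, CL)` (ms; `NA` on non-conductive or unreachable nodes).
#' @export
spiral_activation_map <- function(geom, ps_location, cl, speed,
                                  chirality = c("anticlockwise",
                                                "clockwise")) {
  chirality <- match.arg(chirality)
  stopifnot(inherits(geom, "tissue_geometry"))
  if (speed <= 0) .stopf("speed must be positive")
  if (cl <= 0) .stopf("cycle length must be positive")
  core <- .nearest_node(geom, ps_location)
  cond <- .conductive_nodes(geom)
  if (!cond[core]) .stopf("core lies on non-conductive tissue")
  xy <- .node_xy(geom)
  cpos <- .node_pos(geom, core)
  theta <- atan2(xy[, 2] - cpos[2], xy[, 1] - cpos[1])
  s <- if (chirality == "anticlockwise") 1 else -1
  d <- .geodesic_map(geom, core)
  tmap <- (s * cl * theta / (2 * pi) + d / speed) %% cl
  tmap[!cond | !is.finite(d)] <- NA_real_
  structure(list(tmap = tmap, cl = cl, core = core, speed = speed,
                 chirality = chirality, nx = geom$nx, ny = geom$ny,
                 h = geom$h),
            class = "activation_map")
}

#' Convert an activation map into a tissue state
#'
#' Each node is assigned the limit-cycle template state at phase
#' `mod(-T(x), CL)` (a node activating later is earlier in its cycle), so
#' continuing the monodomain simulation from the returned state produces
#' the mapped wave pattern. Non-conductive and unreachable nodes are set to
#' the resting state.
#'
#' @param geom a `tissue_geometry`.
#' @param model the [membrane_model()] the template was built with.
#' @param amap an [spiral_activation_map()] (or any `activation_map`).
#' @param template a [limit_cycle_template()] whose period equals the map
#'   cycle length (within 1 ms).
#' @return state matrix (nstate x nnodes) for [run_monodomain()].
#' @export
map_to_state <- function(geom, model, amap, template) {
  stopifnot(inherits(amap, "activation_map"),
            inherits(template, "limit_cycle"))
  if (abs(template$period - amap$cl) > 1)
    .stopf("template period (%g ms) does not match map cycle length (%g ms)",
           template$period, amap$cl)
  nt <- ncol(template$states)
  nn <- .n_nodes(geom)
  state <- matrix(model$rest, model$nstate, nn)
  phase <- (-amap$tmap) %% amap$cl
  idx <- pmin(nt, floor(phase / template$sample_dt) + 1L)
  ok <- which(!is.na(idx))
  state[, ok] <- template$states[, idx[ok]]
  state
}

#' Seed and simulate a phase-singularity-distribution episode
#'
#' Convenience wrapper: builds the limit-cycle template at the given cycle
#' length, constructs the spiral activation map around the seeded core,
#' maps it to a tissue state and continues with the monodomain model.
#'
#' @inheritParams spiral_activation_map
#' @param model a [membrane_model()].
#' @param t_end continued simulation time, ms.
#' @param n_prepace pre-pacing beats for the template.
#' @param dt,dt_out,beta,cm solver settings.
#' @return a `sim_result` (the seeded state is at `t = 0`).
#' @export
run_psd <- function(geom, model, ps_location, cl, speed, t_end,
                    chirality = "anticlockwise", n_prepace = 20,
                    dt = 0.02, dt_out = 1, beta = 140, cm = 1) {
  template <- limit_cycle_template(model, cl, n_prepace = n_prepace,
                                   dt = dt)
  amap <- spiral_activation_map(geom, ps_location, cl, speed, chirality)
  state <- map_to_state(geom, model, amap, template)
  run_monodomain(geom, model, list(), t_end = t_end, dt = dt,
                 dt_out = dt_out, state = state, beta = beta, cm = cm)
}
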