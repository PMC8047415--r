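#' Stimulus specification
#'
#' A transmembrane current stimulus delivered over a square footprint
#' (default 2 x 2 mm) centered at a position. The default amplitude of 30
#' mV/ms corresponds to 30 uA/cm^2 on a 1 uF/cm^2 membrane.
#'
#' @param center position `c(x, y)` in mm, or a node index (integer).
#' @param onset stimulus onset, ms.
#' @param duration stimulus duration, ms.
#' @param amplitude stimulus amplitude, mV/ms.
#' @param edge footprint edge length, mm.
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(center, onset = 0, duration = 2, amplitude = 30,
                          edge = 2) {
  if (amplitude <= 0) .stopf("stimulus amplitude must be positive")
  if (duration <= 0) .stopf("stimulus duration must be positive")
  structure(list(center = center, onset = onset, duration = duration,
                 amplitude = amplitude, edge = edge),
            class = "stimulus_spec")
}

# nodes covered by a stimulus footprint (clipped to the domain), conductive
# nodes only; 1-based indices
.stim_nodes <- function(geom, spec) {
  center <- spec$center
  if (length(center) == 1L) center <- as.vector(.node_pos(geom, center))
  xy <- .node_xy(geom)
  half <- spec$edge / 2
  inside <- abs(xy[, 1] - center[1]) <= half + 1e-9
  if (geom$ny > 1L)
    inside <- inside & abs(xy[, 2] - center[2]) <= half + 1e-9
  nodes <- which(inside & .conductive_nodes(geom))
  if (!length(nodes))
    .stopf("stimulus footprint covers no conductive node")
  nodes
}

# per-face diffusivities (mm^2/ms) from element conductivities (S/m)
# D = 100 * sigma / (beta * cm): sigma S/m, beta 1/mm, cm uF/cm^2
.face_diffusivities <- function(geom, beta, cm) {
  k <- 100 / (beta * cm)
  sig <- geom$sigma
  enx <- nrow(sig)
  eny <- ncol(sig)
  nx <- geom$nx
  ny <- geom$ny
  hmean <- function(a, b) 2 * a * b / (a + b)
  if (geom$kind == "strand" || ny == 1L) {
    return(list(dfx = k * sig[, 1], dfy = numeric(0)))
  }
  # x-faces: between nodes (i,j),(i+1,j); adjacent elements (i, j-1), (i, j)
  dfx <- matrix(0, enx, ny)
  dfx[, 1] <- k * sig[, 1]
  dfx[, ny] <- k * sig[, eny]
  if (ny > 2)
    for (j in 2:(ny - 1)) dfx[, j] <- k * hmean(sig[, j - 1], sig[, j])
  # y-faces: between nodes (i,j),(i,j+1); adjacent elements (i-1, j), (i, j)
  dfy <- matrix(0, nx, eny)
  ka <- k / geom$anisotropy
  dfy[1, ] <- ka * sig[1, ]
  dfy[nx, ] <- ka * sig[enx, ]
  if (nx > 2)
    for (i in 2:(nx - 1)) dfy[i, ] <- ka * hmean(sig[i - 1, ], sig[i, ])
  list(dfx = as.vector(dfx), dfy = as.vector(dfy))
}

# per-node membrane group: 1 where adjacent to a fibrotic_remodeled element
.node_groups <- function(geom) {
  fib <- geom$label == .LAB_FIBROTIC
  if (!any(fib)) return(integer(.n_nodes(geom)))
  nx <- geom$nx
  ny <- geom$ny
  g <- matrix(FALSE, nx, ny)
  enx <- nrow(fib)
  if (ny == 1L) {
    g[seq_len(enx), 1] <- fib[, 1]
    g[2:nx, 1] <- g[2:nx, 1] | fib[, 1]
  } else {
    eny <- ncol(fib)
    g[seq_len(enx), seq_len(eny)] <- fib
    g[2:nx, seq_len(eny)] <- g[2:nx, seq_len(eny)] | fib
    g[seq_len(enx), 2:ny] <- g[seq_len(enx), 2:ny] | fib
    g[2:nx, 2:ny] <- g[2:nx, 2:ny] | fib
  }
  as.integer(as.vector(g))
}

#' Run a monodomain tissue simulation
#'
#' Explicit operator-split monodomain solve on a strand or sheet: diffusion
#' with a 5-point (3-point in 1D) stencil and harmonic-mean face
#' conductivities, no-flux boundaries, then one ionic step per node.
#' Non-conductive elements stay in the diffusion operator with their
#' conductivity of 1e-7 S/m (passive barriers, not removed). Elements
#' labeled `fibrotic_remodeled` give their adjacent nodes the
#' cytokine-remodeled membrane phenotype (-50% g_K1, -40% g_Na, -50% g_CaL
#' on top of the supplied model).
#'
#' @param geom a `tissue_geometry`.
#' @param model a [membrane_model()].
#' @param stimuli list of [stimulus_spec()] objects.
#' @param t_end simulated duration, ms.
#' @param dt time step, ms (default 0.02). A stability bound
#'   `dt <= h^2 / (4 Dmax)` is enforced.
#' @param dt_out output frame interval, ms (default 1).
#' @param state initial state matrix (nstate x nnodes); defaults to the
#'   model resting state everywhere.
#' @param beta surface-to-volume ratio, 1/mm (default 140, i.e. 1400 1/cm).
#' @param cm specific membrane capacitance, uF/cm^2 (default 1).
#' @param t0 time stamp of the initial state, ms (frames and activation
#'   times are reported as `t0 + ...`).
#' @return object of class `sim_result`: `movie` (a `vm_movie`),
#'   `activation` (per-node first rising crossing of -40 mV, ms; `NA` if
#'   never activated), `final_state`, and the solver settings.
#' @export
run_monodomain <- function(geom, model, stimuli = list(), t_end,
                           dt = 0.02, dt_out = 1, state = NULL,
                           beta = 140, cm = 1, t0 = 0) {
  stopifnot(inherits(geom, "tissue_geometry"),
            inherits(model, "membrane_model"))
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (model$id == 0L && dt > 0.05)
    .stopf("dt = %g ms exceeds the ionic stability bound (0.05 ms)", dt)
  faces <- .face_diffusivities(geom, beta, cm)
  dmax <- max(faces$dfx, if (length(faces$dfy)) faces$dfy else 0)
  ndim <- if (geom$ny > 1L) 2 else 1
  if (dt > geom$h^2 / (2 * ndim * dmax))
    .stopf("dt = %g ms violates the diffusion stability bound %.4g ms",
           dt, geom$h^2 / (2 * ndim * dmax))
  nn <- .n_nodes(geom)
  if (is.null(state)) {
    state <- matrix(model$rest, model$nstate, nn)
  } else {
    stopifnot(nrow(state) == model$nstate, ncol(state) == nn)
  }
  sc_ctrl <- .scale_vec(model)
  remod <- apply_remodeling(model, remodeling_preset("cytokine_fibrotic"))
  sc_remod <- .scale_vec(remod)

  onset <- vapply(stimuli, function(s) s$onset, 0)
  dur <- vapply(stimuli, function(s) s$duration, 0)
  amp <- vapply(stimuli, function(s) s$amplitude, 0)
  nodes <- lapply(stimuli, function(s) as.integer(.stim_nodes(geom, s) - 1L))

  out <- .monodomain_run_cpp(model$id, sc_ctrl, sc_remod, unname(model$fk),
                             .node_groups(geom), state,
                             geom$nx, geom$ny, faces$dfx, faces$dfy,
                             geom$h, dt, t_end, dt_out,
                             onset, dur, amp, nodes, -40, t0)
  movie <- structure(list(vm = out$frames, times = out$times,
                          nx = geom$nx, ny = geom$ny, h = geom$h,
                          dt_out = dt_out),
                     class = "vm_movie")
  structure(list(movie = movie, activation = out$activation,
                 final_state = out$final_state, dt = dt, dt_out = dt_out,
                 t0 = t0, t_end = t0 + t_end,
                 stimuli = stimuli, beta = beta, cm = cm),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g..%g ms, %d frames, %d nodes\n",
              x$t0, x$t_end, nrow(x$movie$vm), ncol(x$movie$vm)))
  invisible(x)
}

#' Measure conduction velocity from an activation map
#'
#' Fits position against activation time over a window of nodes along the
#' propagation axis of a planar wave and returns the slope magnitude in m/s
#' (mm/ms). Non-monotone activation inside the window (re-entry, strong
#' curvature) is rejected.
#'
#' @param result a `sim_result` from a strand (or sheet, with `row`
#'   selecting the node row to use).
#' @param window node index range `c(first, last)` along x; default the
#'   central 60% of the strand.
#' @param row node row for sheets (default middle row).
#' @return conduction velocity in m/s.
#' @export
measure_cv <- function(result, window = NULL, row = NULL) {
  stopifnot(inherits(result, "sim_result"))
  nx <- result$movie$nx
  ny <- result$movie$ny
  h <- result$movie$h
  if (is.null(row)) row <- (ny + 1L) %/% 2L
  if (is.null(window)) window <- c(ceiling(nx * 0.2), floor(nx * 0.8))
  window <- sort(as.integer(window))
  idx <- (row - 1L) * nx + seq(window[1], window[2])
  at <- result$activation[idx]
  if (anyNA(at)) .stopf("not all window nodes activated")
  dirs <- sign(diff(at))
  if (any(dirs > 0) && any(dirs < 0))
    .stopf("non-monotone activation in window (re-entry or curvature?)")
  pos <- (seq(window[1], window[2]) - 1) * h
  fit <- lm(pos ~ at)
  abs(unname(coef(fit)[2]))  # mm/ms == m/s
}

#' Tune conductivity to a target conduction velocity
#'
#' Bisects on the working-myocardium conductivity of a 1D strand until the
#' measured planar conduction velocity matches `target_cv` within `tol`.
#' The strand is stimulated at one end; CV is measured by activation-time
#' regression over the central window.
#'
#' @param target_cv target conduction velocity, m/s.
#' @param model a [membrane_model()].
#' @param geom optional strand geometry template (default: 5 cm strand at
#'   0.25 mm spacing).
#' @param tol CV tolerance, m/s (default 0.01).
#' @param sigma_bracket initial conductivity bracket, S/m; expanded up to
#'   8x in each direction if it does not bracket the target.
#' @param dt,beta,cm solver settings as in [run_monodomain()].
#' @param max_iter bisection iteration cap.
#' @return list with `sigma` (S/m), `cv` (m/s achieved), `n_iter`, and the
#'   evaluated `history` data frame.
#' @export
tune_conductivity <- function(target_cv, model, geom = NULL, tol = 0.01,
                              sigma_bracket = c(0.05, 1.5), dt = 0.02,
                              beta = 140, cm = 1, max_iter = 40) {
  if (is.null(geom)) geom <- make_strand(201, 0.25)
  stopifnot(geom$kind == "strand")
  eval_cv <- function(sigma) {
    g <- geom
    g$sigma[] <- sigma
    # long enough for the slowest plausible wave to cross the window
    t_end <- max(200, 1.5 * dim_mm(g)[1] / 0.1)
    tryCatch({
      res <- run_monodomain(g, model,
                            list(stimulus_spec(c(0, 0), onset = 1)),
                            t_end = t_end, dt = dt, dt_out = 0.5,
                            beta = beta, cm = cm)
      measure_cv(res)
    }, error = function(e) NA_real_)
  }
  lo <- sigma_bracket[1]
  hi <- sigma_bracket[2]
  cv_lo <- eval_cv(lo)
  cv_hi <- eval_cv(hi)
  hist <- data.frame(sigma = c(lo, hi), cv = c(cv_lo, cv_hi))
  expand <- 0
  while ((is.na(cv_lo) || cv_lo > target_cv) && expand < 4) {
    lo <- lo / 2
    cv_lo <- eval_cv(lo)
    hist <- rbind(hist, data.frame(sigma = lo, cv = cv_lo))
    expand <- expand + 1
  }
  expand <- 0
  while (!is.na(cv_hi) && cv_hi < target_cv && expand < 4) {
    hi <- hi * 2
    cv_hi <- eval_cv(hi)
    hist <- rbind(hist, data.frame(sigma = hi, cv = cv_hi))
    expand <- expand + 1
  }
  if (is.na(cv_hi) || cv_hi < target_cv || (!is.na(cv_lo) && cv_lo > target_cv))
    .stopf("target CV %g m/s not bracketable (achieved %.3g..%.3g m/s)",
           target_cv, if (is.na(cv_lo)) 0 else cv_lo,
           if (is.na(cv_hi)) 0 else cv_hi)
  sigma <- NA_real_
  cv <- NA_real_
  for (it in seq_len(max_iter)) {
    sigma <- sqrt(lo * hi)  # geometric midpoint: CV ~ sqrt(sigma)
    cv <- eval_cv(sigma)
    hist <- rbind(hist, data.frame(sigma = sigma, cv = cv))
    if (!is.na(cv) && abs(cv - target_cv) <= tol) break
    if (is.na(cv) || cv < target_cv) lo <- sigma else hi <- sigma
  }
  if (is.na(cv) || abs(cv - target_cv) > tol)
    .stopf("bisection did not converge to %g m/s (best %.4g)", target_cv, cv)
  list(sigma = sigma, cv = cv, n_iter = it, history = hist)
}
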