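#' Phase movie from a voltage movie
#'
#' Time-delay-embedding phase: `phi(t) = atan2(Vm(t) - V*, Vm(t - tau) -
#' V*)` per node, with `V*` defaulting to the per-node mean of the movie.
#' Nodes whose voltage never varies (resting or non-conductive tissue) are
#' masked as `NA`.
#'
#' @param movie a `vm_movie` (or `sim_result`).
#' @param tau embedding delay, ms; must be a multiple of the movie frame
#'   interval.
#' @param v_star phase origin, mV: a scalar, a per-node vector, or `NULL`
#'   for the per-node temporal mean.
#' @param mask_range nodes with peak-to-peak voltage below this (mV) are
#'   masked.
#' @return object of class `phase_movie`: `phase` (frames x nodes, radians
#'   in (-pi, pi]), `times`, grid metadata, and the node `mask`.
#' @export
compute_phase <- function(movie, tau = 10, v_star = NULL, mask_range = 1) {
  if (inherits(movie, "sim_result")) movie <- movie$movie
  stopifnot(inherits(movie, "vm_movie"))
  dt <- movie$dt_out
  k <- tau / dt
  if (abs(k - round(k)) > 1e-9)
    .stopf("tau = %g ms is not a multiple of the frame interval %g ms",
           tau, dt)
  k <- as.integer(round(k))
  nf <- nrow(movie$vm)
  if (nf <= k) .stopf("movie shorter than the embedding delay")
  if (is.null(v_star)) v_star <- colMeans(movie$vm)
  vc <- sweep(movie$vm, 2, v_star)
  ph <- atan2(vc[(k + 1):nf, , drop = FALSE],
              vc[1:(nf - k), , drop = FALSE])
  rng <- apply(movie$vm, 2, function(v) diff(range(v)))
  mask <- rng < mask_range
  ph[, mask] <- NA_real_
  structure(list(phase = ph, times = movie$times[(k + 1):nf],
                 nx = movie$nx, ny = movie$ny, h = movie$h,
                 dt_out = dt, tau = tau, mask = mask),
            class = "phase_movie")
}

.wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Detect phase singularities in a phase field
#'
#' Computes the topological charge of every elementary grid plaquette as
#' the winding of the wrapped phase differences around it; plaquettes with
#' charge +/-1 are reported with their center position. Boundary plaquettes
#' are excluded, as are plaquettes touching masked nodes.
#'
#' @param phase a `phase_movie`, or a single phase field as an `nx x ny`
#'   matrix.
#' @param frame frame index when `phase` is a `phase_movie` (`NULL` =
#'   detect in every frame and return a list of data frames).
#' @param h grid spacing, mm (taken from the movie when available).
#' @return data frame with columns `x`, `y` (mm) and `charge` (+1/-1); or a
#'   list of such data frames (one per frame).
#' @export
detect_ps <- function(phase, frame = NULL, h = NULL) {
  if (inherits(phase, "phase_movie")) {
    if (is.null(h)) h <- phase$h
    nx <- phase$nx
    ny <- phase$ny
    if (is.null(frame)) {
      return(lapply(seq_len(nrow(phase$phase)), function(f)
        .detect_ps_frame(matrix(phase$phase[f, ], nx, ny), h)))
    }
    return(.detect_ps_frame(matrix(phase$phase[frame, ], nx, ny), h))
  }
  if (is.null(h)) .stopf("h is required for a raw phase matrix")
  .detect_ps_frame(phase, h)
}

.detect_ps_frame <- function(p, h) {
  nx <- nrow(p)
  ny <- ncol(p)
  ix <- seq_len(nx - 1L)
  iy <- seq_len(ny - 1L)
  s <- .wrap_pi(p[ix + 1L, iy, drop = FALSE] - p[ix, iy, drop = FALSE]) +
       .wrap_pi(p[ix + 1L, iy + 1L, drop = FALSE] - p[ix + 1L, iy, drop = FALSE]) +
       .wrap_pi(p[ix, iy + 1L, drop = FALSE] - p[ix + 1L, iy + 1L, drop = FALSE]) +
       .wrap_pi(p[ix, iy, drop = FALSE] - p[ix, iy + 1L, drop = FALSE])
  charge <- round(s / (2 * pi))
  charge[is.na(charge)] <- 0L
  # exclude boundary plaquettes
  if (nx > 2) charge[c(1L, nx - 1L), ] <- 0L
  if (ny > 2) charge[, c(1L, ny - 1L)] <- 0L
  hit <- which(abs(charge) == 1L, arr.ind = TRUE)
  data.frame(x = (hit[, 1] - 0.5) * h, y = (hit[, 2] - 0.5) * h,
             charge = as.integer(charge[hit]))
}

#' Track phase singularities across frames
#'
#' Greedy nearest-neighbour association of same-charge detections between
#' consecutive frames, with a displacement gate `v_max * dt` and
#' deterministic distance-then-index tie-breaking. Unmatched detections
#' start new trajectories; trajectories unmatched for more than
#' `bridge_frames` frames are closed.
#'
#' @param detections list of per-frame detection data frames (from
#'   [detect_ps()] on a `phase_movie`), or a `phase_movie` itself.
#' @param times frame times, ms (taken from the movie when available).
#' @param v_max tracking gate speed, mm/ms (default 1, i.e. 1 m/s).
#' @param bridge_frames allowed dropout frames (default 0: a one-frame
#'   dropout splits the trajectory).
#' @return list of `ps_trajectory` objects: `charge`, `t`, `x`, `y`,
#'   `lifetime` (ms).
#' @export
track_ps <- function(detections, times = NULL, v_max = 1,
                     bridge_frames = 0) {
  if (inherits(detections, "phase_movie")) {
    times <- detections$times
    detections <- detect_ps(detections)
  }
  stopifnot(length(detections) == length(times))
  active <- list()   # each: list(charge, t, x, y, last_frame)
  done <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    dt_gap <- if (f > 1) times[f] - times[f - 1] else 0
    gate <- v_max * dt_gap * (1 + bridge_frames)
    used_det <- rep(FALSE, nrow(det))
    matched <- rep(FALSE, length(active))
    if (length(active) && nrow(det)) {
      cand <- expand.grid(a = seq_along(active), d = seq_len(nrow(det)))
      cand$dist <- vapply(seq_len(nrow(cand)), function(r) {
        a <- active[[cand$a[r]]]
        if (a$charge != det$charge[cand$d[r]]) return(Inf)
        sqrt((a$x[length(a$x)] - det$x[cand$d[r]])^2 +
             (a$y[length(a$y)] - det$y[cand$d[r]])^2)
      }, 0)
      cand <- cand[is.finite(cand$dist) & cand$dist <= gate, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$a, cand$d), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        a <- cand$a[r]
        d <- cand$d[r]
        if (matched[a] || used_det[d]) next
        matched[a] <- TRUE
        used_det[d] <- TRUE
        tr <- active[[a]]
        tr$t <- c(tr$t, times[f])
        tr$x <- c(tr$x, det$x[d])
        tr$y <- c(tr$y, det$y[d])
        tr$last_frame <- f
        active[[a]] <- tr
      }
    }
    # close stale trajectories
    keep <- logical(length(active))
    for (a in seq_along(active)) {
      if (matched[a] || f - active[[a]]$last_frame <= bridge_frames) {
        keep[a] <- TRUE
      } else {
        done[[length(done) + 1L]] <- active[[a]]
      }
    }
    active <- active[keep]
    # new trajectories from unmatched detections
    for (d in which(!used_det)) {
      active[[length(active) + 1L]] <-
        list(charge = det$charge[d], t = times[f], x = det$x[d],
             y = det$y[d], last_frame = f)
    }
  }
  done <- c(done, active)
  lapply(done, function(tr) {
    structure(list(charge = tr$charge, t = tr$t, x = tr$x, y = tr$y,
                   lifetime = tr$t[length(tr$t)] - tr$t[1]),
              class = "ps_trajectory")
  })
}

#' @export
print.ps_trajectory <- function(x, ...) {
  cat(sprintf("<ps_trajectory> charge %+d, %d samples, lifetime %g ms\n",
              x$charge, length(x$t), x$lifetime))
  invisible(x)
}

#' Classify a phase-singularity trajectory
#'
#' A trajectory is a long-living phase singularity (llPS) if its lifetime
#' is at least `lifetime_min` (500 ms). An llPS is *stable* if it is
#' present throughout the final `stable_window` ms (up to one frame
#' interval of slack at each end) and its positions in that window fit in
#' an axis-aligned square of edge at most `bbox_edge` mm.
#'
#' @param traj a `ps_trajectory`.
#' @param now end of the analysis window, ms.
#' @param lifetime_min llPS lifetime threshold, ms.
#' @param stable_window final window for the stability test, ms.
#' @param bbox_edge bounding-box edge threshold, mm.
#' @param frame_dt frame interval used for the coverage slack, ms
#'   (estimated from the trajectory if omitted).
#' @return one of `"not_llPS"`, `"nonstable_llPS"`, `"stable_llPS"`.
#' @export
classify_llps <- function(traj, now, lifetime_min = 500,
                          stable_window = 1500, bbox_edge = 50,
                          frame_dt = NULL) {
  stopifnot(inherits(traj, "ps_trajectory"))
  if (traj$lifetime < lifetime_min) return("not_llPS")
  if (is.null(frame_dt))
    frame_dt <- if (length(traj$t) > 1) max(diff(traj$t)) else Inf
  w0 <- now - stable_window
  covered <- traj$t[1] <= w0 + frame_dt &&
             traj$t[length(traj$t)] >= now - frame_dt
  if (covered) {
    sel <- traj$t >= w0
    edge <- max(diff(range(traj$x[sel])), diff(range(traj$y[sel])))
    if (edge <= bbox_edge) return("stable_llPS")
  }
  "nonstable_llPS"
}

#' Classify an arrhythmic episode
#'
#' Applies the four-class taxonomy to an induced episode: `stable_llPS` if
#' any trajectory is a stable long-living phase singularity over the final
#' window, else `nonstable_llPS` if any llPS exists, else `Fl` (flutter:
#' periodic macro-re-entry) if the activation is periodic — coefficient of
#' variation of per-node cycle lengths below `cl_cv_max` and mean
#' simultaneous wavefront count at most `max_wavefronts` — else `Multi`
#' (disorganized multiple wavefronts). Returns `"none"` for non-induced
#' episodes.
#'
#' @param movie a `vm_movie` (or `sim_result`) covering the final window.
#' @param trajectories list of `ps_trajectory` (from [track_ps()]).
#' @param induced was the episode induced? (`FALSE` short-circuits to
#'   `"none"`.)
#' @param now end of the analysis window, ms (default: last frame).
#' @param geom optional `tissue_geometry` for the conductive mask.
#' @param window analysis window, ms.
#' @param lifetime_min,stable_window,bbox_edge llPS thresholds (see
#'   [classify_llps()]).
#' @param cl_cv_max,max_wavefronts flutter-vs-multi heuristic thresholds.
#' @return object of class `episode_class`: list with `class` and the
#'   supporting `metrics`.
#' @export
classify_episode <- function(movie, trajectories, induced = TRUE,
                             now = NULL, geom = NULL, window = 1500,
                             lifetime_min = 500, stable_window = 1500,
                             bbox_edge = 50, cl_cv_max = 0.1,
                             max_wavefronts = 2) {
  if (inherits(movie, "sim_result")) movie <- movie$movie
  if (!induced)
    return(structure(list(class = "none", metrics = list()),
                     class = "episode_class"))
  if (is.null(now)) now <- movie$times[length(movie$times)]
  kinds <- vapply(trajectories, classify_llps, "", now = now,
                  lifetime_min = lifetime_min,
                  stable_window = stable_window, bbox_edge = bbox_edge)
  n_llps <- sum(kinds != "not_llPS")
  metrics <- list(n_llps = n_llps,
                  n_stable = sum(kinds == "stable_llPS"))
  if (any(kinds == "stable_llPS"))
    cls <- "stable_llPS"
  else if (n_llps > 0)
    cls <- "nonstable_llPS"
  else {
    per <- .periodicity_metrics(movie, geom, now = now, window = window)
    metrics <- c(metrics, per)
    cls <- if (!is.na(per$cl_cv) && per$cl_cv < cl_cv_max &&
               per$mean_wavefronts <= max_wavefronts) "Fl" else "Multi"
  }
  structure(list(class = cls, metrics = metrics), class = "episode_class")
}

#' @export
print.episode_class <- function(x, ...) {
  cat(sprintf("<episode_class> %s\n", x$class))
  invisible(x)
}

# periodicity heuristics: coefficient of variation of per-node cycle
# lengths (upstroke-to-upstroke) and mean simultaneous wavefront count
.periodicity_metrics <- function(movie, geom, now, window, thr = -40,
                                 wf_thr = -50) {
  sel <- which(movie$times > now - window - 1e-9 & movie$times <= now + 1e-9)
  v <- movie$vm[sel, , drop = FALSE]
  tt <- movie$times[sel]
  cond <- if (is.null(geom)) rep(TRUE, ncol(v)) else .conductive_nodes(geom)
  nf <- nrow(v)
  up <- (v[-1, , drop = FALSE] >= thr) & (v[-nf, , drop = FALSE] < thr)
  cls <- numeric(0)
  for (n in which(cond)) {
    et <- tt[-1][up[, n]]
    if (length(et) >= 3) cls <- c(cls, diff(et))
  }
  cl_cv <- if (length(cls) >= 4) sd(cls) / mean(cls) else NA_real_
  # wavefront count on a subsample of frames
  fsel <- unique(round(seq(2, nf, length.out = min(nf - 1, 40))))
  wf <- vapply(fsel, function(f) {
    mask <- v[f, ] >= wf_thr & (v[f, ] - v[f - 1, ]) > 0 & cond
    lab <- .label_components_cpp(mask, movie$nx, movie$ny)
    max(lab)
  }, 0L)
  list(cl_cv = cl_cv, mean_wavefronts = mean(wf),
       dominant_cl = if (length(cls)) stats::median(cls) else NA_real_)
}
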