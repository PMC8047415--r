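#' Protocol simulation context
#'
#' A mutable wrapper around a tissue simulation that the induction protocols
#' drive through a small verb set: deliver a beat, wait, checkpoint/restore,
#' probe a coupling interval, and run the induction check. The protocol
#' functions ([run_rp()], [run_peerp()], [find_erp()]) only use these verbs,
#' so alternative backends (e.g. scripted stubs in unit tests) can implement
#' the same generics.
#'
#' The context keeps the full tissue state, the current time, and a rolling
#' buffer of output frames (`keep_ms` of history) used by the propagation
#' and induction checks.
#'
#' @param geom a `tissue_geometry`.
#' @param model a [membrane_model()].
#' @param dt,dt_out,beta,cm solver settings (see [run_monodomain()]).
#' @param stim_amplitude,stim_duration,stim_edge stimulus shape delivered by
#'   [ctx_deliver_beat()] (mV/ms, ms, mm).
#' @param prop_ring geodesic ring (inner, outer) around the stimulation site
#'   used by the propagation check, mm.
#' @param prop_threshold propagation-check voltage threshold, mV.
#' @param prop_window time window after stimulus onset in which propagation
#'   must be observed, ms (80 ms covers 6 mm at 0.1 m/s with margin).
#' @param induction_window continuation time for the induction check, ms.
#' @param keep_ms length of the retained frame history, ms.
#' @return an environment of class `sim_context`.
#' @export
sim_context <- function(geom, model, dt = 0.02, dt_out = 1, beta = 140,
                        cm = 1, stim_amplitude = 30, stim_duration = 2,
                        stim_edge = 2, prop_ring = c(4, 6),
                        prop_threshold = -50, prop_window = 80,
                        induction_window = 1500, keep_ms = 4000) {
  stopifnot(inherits(geom, "tissue_geometry"),
            inherits(model, "membrane_model"))
  ctx <- new.env(parent = emptyenv())
  ctx$geom <- geom
  ctx$model <- model
  ctx$dt <- dt
  ctx$dt_out <- dt_out
  ctx$beta <- beta
  ctx$cm <- cm
  ctx$stim_amplitude <- stim_amplitude
  ctx$stim_duration <- stim_duration
  ctx$stim_edge <- stim_edge
  ctx$prop_ring <- prop_ring
  ctx$prop_threshold <- prop_threshold
  ctx$prop_window <- prop_window
  ctx$induction_window <- induction_window
  ctx$keep_ms <- keep_ms
  ctx$state <- matrix(model$rest, model$nstate, .n_nodes(geom))
  ctx$t <- 0
  ctx$chunks <- list()  # frame history as chunks: list(times, vm)
  ctx$beats <- 0L
  ctx$induced <- FALSE
  ctx$cond <- .conductive_nodes(geom)
  ctx$rings <- list()
  class(ctx) <- c("sim_context", "environment")
  ctx
}

#' @export
print.sim_context <- function(x, ...) {
  cat(sprintf("<sim_context> t = %g ms, %d beats, induced = %s\n",
              x$t, x$beats, x$induced))
  invisible(x)
}

.ctx_site_node <- function(ctx, site) {
  if (length(site) == 1L && is.numeric(site) && site == round(site) &&
      site >= 1 && site <= .n_nodes(ctx$geom)) return(as.integer(site))
  .nearest_node(ctx$geom, site)
}

.ctx_ring_nodes <- function(ctx, site) {
  node <- .ctx_site_node(ctx, site)
  key <- as.character(node)
  if (!is.null(ctx$rings[[key]])) return(ctx$rings[[key]])
  dmap <- .geodesic_map(ctx$geom, node)
  ring <- which(dmap >= ctx$prop_ring[1] & dmap <= ctx$prop_ring[2])
  if (!length(ring))
    .stopf("propagation ring %g-%g mm around node %d contains no conductive node",
           ctx$prop_ring[1], ctx$prop_ring[2], node)
  ctx$rings[[key]] <- ring
  ring
}

.ctx_append <- function(ctx, res) {
  m <- res$movie
  keep <- m$times > ctx$t + 1e-9
  if (any(keep)) {
    ctx$chunks[[length(ctx$chunks) + 1L]] <-
      list(times = m$times[keep], vm = m$vm[keep, , drop = FALSE])
  }
  ctx$state <- res$final_state
  ctx$t <- res$t_end
  # drop whole chunks that fell out of the retained history
  while (length(ctx$chunks) > 1L) {
    tmax1 <- ctx$chunks[[1]]$times[length(ctx$chunks[[1]]$times)]
    if (tmax1 < ctx$t - ctx$keep_ms) ctx$chunks[[1]] <- NULL else break
  }
  invisible(ctx)
}

# concatenated frames with times in [from, to] (1e-9 slack at both ends)
.ctx_window <- function(ctx, from, to) {
  parts <- lapply(ctx$chunks, function(ch) {
    sel <- ch$times >= from - 1e-9 & ch$times <= to + 1e-9
    if (!any(sel)) return(NULL)
    list(times = ch$times[sel], vm = ch$vm[sel, , drop = FALSE])
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    return(list(times = numeric(0),
                vm = matrix(numeric(0), 0, .n_nodes(ctx$geom))))
  list(times = unlist(lapply(parts, `[[`, "times")),
       vm = do.call(rbind, lapply(parts, `[[`, "vm")))
}

# the retained history as a vm_movie (used for episode classification)
.ctx_movie <- function(ctx, from = -Inf, to = Inf) {
  w <- .ctx_window(ctx, from, to)
  structure(list(vm = w$vm, times = w$times, nx = ctx$geom$nx,
                 ny = ctx$geom$ny, h = ctx$geom$h, dt_out = ctx$dt_out),
            class = "vm_movie")
}

#' Context verbs used by the induction protocols
#'
#' `ctx_wait()` advances the simulation; `ctx_deliver_beat()` delivers one
#' stimulus at the site and advances through its duration;
#' `ctx_checkpoint()`/`ctx_restore()` save and restore the full context
#' state (used for ERP trial beats and per-beat induction checks, so probing
#' does not perturb the protocol history); `ctx_trial_coupling()` tests
#' whether a beat delivered at the given coupling interval after the
#' previous beat propagates (the ERP predicate); `ctx_check_induction()`
#' continues the simulation for the induction window, evaluates the
#' sustained-activity criterion, and rolls back unless the episode is
#' sustained.
#'
#' @param ctx a [sim_context()] (or a test double implementing the verbs).
#' @param duration time to advance, ms.
#' @param site stimulation site: position `c(x, y)` mm or node index.
#' @param coupling trial coupling interval (onset to onset), ms.
#' @param token a checkpoint token from `ctx_checkpoint()`.
#' @name context-verbs
NULL

#' @rdname context-verbs
#' @export
ctx_wait <- function(ctx, duration) UseMethod("ctx_wait")

#' @rdname context-verbs
#' @export
ctx_deliver_beat <- function(ctx, site) UseMethod("ctx_deliver_beat")

#' @rdname context-verbs
#' @export
ctx_checkpoint <- function(ctx) UseMethod("ctx_checkpoint")

#' @rdname context-verbs
#' @export
ctx_restore <- function(ctx, token) UseMethod("ctx_restore")

#' @rdname context-verbs
#' @export
ctx_trial_coupling <- function(ctx, site, coupling)
  UseMethod("ctx_trial_coupling")

#' @rdname context-verbs
#' @export
ctx_check_induction <- function(ctx) UseMethod("ctx_check_induction")

#' @export
ctx_wait.sim_context <- function(ctx, duration) {
  if (duration <= 0) return(invisible(ctx))
  res <- run_monodomain(ctx$geom, ctx$model, list(), t_end = duration,
                        dt = ctx$dt, dt_out = ctx$dt_out, state = ctx$state,
                        beta = ctx$beta, cm = ctx$cm, t0 = ctx$t)
  .ctx_append(ctx, res)
}

#' @export
ctx_deliver_beat.sim_context <- function(ctx, site) {
  stim <- stimulus_spec(if (length(site) == 1L)
    .ctx_site_node(ctx, site) else site,
    onset = 0, duration = ctx$stim_duration,
    amplitude = ctx$stim_amplitude, edge = ctx$stim_edge)
  res <- run_monodomain(ctx$geom, ctx$model, list(stim),
                        t_end = ctx$stim_duration, dt = ctx$dt,
                        dt_out = ctx$dt_out, state = ctx$state,
                        beta = ctx$beta, cm = ctx$cm, t0 = ctx$t)
  ctx$beats <- ctx$beats + 1L
  .ctx_append(ctx, res)
}

#' @export
ctx_checkpoint.sim_context <- function(ctx) {
  list(state = ctx$state, t = ctx$t, chunks = ctx$chunks,
       beats = ctx$beats, induced = ctx$induced)
}

#' @export
ctx_restore.sim_context <- function(ctx, token) {
  ctx$state <- token$state
  ctx$t <- token$t
  ctx$chunks <- token$chunks
  ctx$beats <- token$beats
  ctx$induced <- token$induced
  invisible(ctx)
}

#' @export
ctx_trial_coupling.sim_context <- function(ctx, site, coupling) {
  if (coupling <= ctx$stim_duration)
    .stopf("coupling %g ms not longer than the stimulus duration", coupling)
  token <- ctx_checkpoint(ctx)
  on.exit(ctx_restore(ctx, token), add = TRUE)
  onset <- ctx$t + coupling - ctx$stim_duration
  ctx_wait(ctx, coupling - ctx$stim_duration)
  ctx_deliver_beat(ctx, site)
  ctx_wait(ctx, ctx$prop_window)
  .ring_propagated(ctx, site, onset)
}

# propagation criterion: an upward crossing of the threshold at >= 1 ring
# node in (onset, onset + window]
.ring_propagated <- function(ctx, site, onset) {
  ring <- .ctx_ring_nodes(ctx, site)
  w <- .ctx_window(ctx, onset, onset + ctx$prop_window)
  if (length(w$times) < 2) .stopf("no frames available for propagation check")
  v <- w$vm[, ring, drop = FALSE]
  nf <- nrow(v)
  any(v[-1, , drop = FALSE] >= ctx$prop_threshold &
      v[-nf, , drop = FALSE] < ctx$prop_threshold)
}

#' @export
ctx_check_induction.sim_context <- function(ctx) {
  token <- ctx_checkpoint(ctx)
  t_end <- ctx$t
  ctx_wait(ctx, ctx$induction_window)
  w <- .ctx_window(ctx, t_end - ctx$dt_out, ctx$t)
  ok <- .induction_criterion(w$vm, w$times, ctx$cond, t_end,
                             window = ctx$induction_window)
  if (!ok) {
    ctx_restore(ctx, token)
  } else {
    ctx$induced <- TRUE
  }
  ok
}

# Sustained-activity criterion: in (t_end, t_end + window], every frame has
# >= 1 conductive node at or above `thr`, and a new activation (upward
# crossing of `thr`) occurs somewhere in every rolling `upstroke_gap` ms.
.induction_criterion <- function(frames, times, cond, t_end, window = 1500,
                                 thr = -50, upstroke_gap = 500) {
  sel <- which(times > t_end + 1e-9 & times <= t_end + window + 1e-9)
  if (length(sel) < 2 || max(times) < t_end + window - 1e-9)
    .stopf("insufficient continuation time for induction check")
  v <- frames[sel, cond, drop = FALSE]
  if (!all(apply(v, 1, max) >= thr)) return(FALSE)
  # include the frame just before the window so crossings at the first
  # frame are visible
  pre <- if (sel[1] > 1) sel[1] - 1L else sel[1]
  vv <- frames[c(pre, sel), cond, drop = FALSE]
  nf <- nrow(vv)
  crossing <- (vv[-1, , drop = FALSE] >= thr) & (vv[-nf, , drop = FALSE] < thr)
  ev <- times[c(pre, sel)][-1][rowSums(crossing) > 0]
  gaps <- diff(c(t_end, ev, t_end + window))
  all(gaps <= upstroke_gap)
}
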