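#' Rapid-pacing protocol parameters
#'
#' A decremental train of stimuli: the coupling interval (CI) is decremented
#' from `s` to `l` in steps of `step` ms, with `N` beats per CI, and the
#' arrhythmia check either after every beat (`"B"`) or once at the end of
#' the train (`"E"`). Defaults for `s`/`l` follow the membrane phenotype:
#' 300/200 ms for control, 200/130 ms for AF-remodeled tissue.
#'
#' @param s starting CI, ms.
#' @param l last CI, ms (`s >= l`; `s - l` must be divisible by `step`).
#' @param step CI decrement, ms.
#' @param N beats per CI (1-4 in the study design; any >= 1 accepted).
#' @param check `"B"` (after every beat) or `"E"` (at the end).
#' @return object of class `rp_params`.
#' @export
rp_params <- function(s = 300, l = 200, step = 10, N = 1,
                      check = c("B", "E")) {
  check <- match.arg(check)
  if (s < l) .stopf("starting CI s must be >= last CI l")
  if (step <= 0) .stopf("step must be positive")
  if (N < 1) .stopf("N must be >= 1")
  if ((s - l) %% step != 0)
    .stopf("s - l = %g is not divisible by step = %g", s - l, step)
  structure(list(s = s, l = l, step = step, N = as.integer(N),
                 check = check), class = "rp_params")
}

#' Build the rapid-pacing coupling-interval train
#'
#' Returns the deterministic CI list `[s x N, (s-step) x N, ..., l x N]`,
#' e.g. `(s=200, l=130, step=10, N=1)` gives
#' `200, 190, 180, 170, 160, 150, 140, 130`.
#'
#' @param params an [rp_params()] (or `s` given directly).
#' @param l,step,N,check used when `params` is numeric `s`.
#' @return numeric vector of CIs, ms; length `N * ((s - l) / step + 1)`.
#' @export
build_rp_train <- function(params, l = NULL, step = 10, N = 1, check = "B") {
  if (!inherits(params, "rp_params"))
    params <- rp_params(params, l, step, N, check)
  rep(seq(params$s, params$l, by = -params$step), each = params$N)
}

#' PEERP protocol parameters
#'
#' Pacing at the end of the effective refractory period: each stimulus is
#' delivered as soon as the tissue at the site has recovered, i.e. at the
#' smallest propagating coupling interval found by a run-time binary search
#' (see [find_erp()]).
#'
#' @param max_beats maximum number of stimuli per site, including the first
#'   beat (default 4).
#' @param erp_resolution temporal resolution of the ERP search, ms.
#' @param erp_first_guess first guess of the ERP, ms; defaults to the APD94
#'   of the paced single cell (computed on demand).
#' @return object of class `peerp_params`.
#' @export
peerp_params <- function(max_beats = 4, erp_resolution = 1,
                         erp_first_guess = NULL) {
  if (max_beats < 0) .stopf("max_beats must be >= 0")
  if (erp_resolution < 0) .stopf("erp_resolution must be positive")
  structure(list(max_beats = as.integer(max_beats),
                 erp_resolution = erp_resolution,
                 erp_first_guess = erp_first_guess),
            class = "peerp_params")
}

.protocol_result <- function(protocol, induced, beats, inducing_ci,
                             intervals, per_beat, t_start, t_end) {
  structure(list(protocol = protocol, induced = induced,
                 beats_delivered = beats, inducing_ci = inducing_ci,
                 intervals = intervals, per_beat = per_beat,
                 t_protocol_end = t_end,
                 sim_time_ms = t_end - t_start),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s: induced = %s, beats = %d",
              x$protocol, x$induced, x$beats_delivered))
  if (!is.na(x$inducing_ci))
    cat(sprintf(", inducing CI = %g ms", x$inducing_ci))
  cat(sprintf(", simulated %g ms\n", x$sim_time_ms))
  invisible(x)
}

#' Run the rapid-pacing protocol at one site
#'
#' Delivers an initial beat followed by the decremental CI train of
#' `params`; each train pulse is delivered at its CI after the previous
#' pulse. In check mode `"B"` the induction check (a rolled-back
#' continuation of `induction_window` ms, see [ctx_check_induction()]) runs
#' after every pulse and the protocol stops at the first success; in mode
#' `"E"` the whole train is delivered and a single check runs at the end.
#'
#' @param ctx a [sim_context()] (or compatible backend).
#' @param site stimulation site: position `c(x, y)` mm or node index.
#' @param params an [rp_params()].
#' @return a `protocol_result`; `beats_delivered` counts the train pulses
#'   (the priming beat is not counted), `inducing_ci` is the CI of the last
#'   pulse before a successful check.
#' @export
run_rp <- function(ctx, site, params) {
  stopifnot(inherits(params, "rp_params"))
  train <- build_rp_train(params)
  t_start <- ctx$t
  ctx_deliver_beat(ctx, site)  # priming beat: CI reference for the train
  beats <- 0L
  induced <- FALSE
  inducing_ci <- NA_real_
  per_beat <- data.frame(beat = integer(0), ci = numeric(0),
                         onset = numeric(0), induced = logical(0))
  for (i in seq_along(train)) {
    wait <- train[i] - ctx$stim_duration
    if (wait > 0) ctx_wait(ctx, wait)
    onset <- ctx$t
    ctx_deliver_beat(ctx, site)
    beats <- beats + 1L
    checked <- FALSE
    if (params$check == "B") {
      checked <- TRUE
      if (ctx_check_induction(ctx)) {
        induced <- TRUE
        inducing_ci <- train[i]
      }
    }
    per_beat <- rbind(per_beat, data.frame(beat = beats, ci = train[i],
                                           onset = onset,
                                           induced = induced))
    if (induced) break
  }
  t_end <- if (induced) per_beat$onset[nrow(per_beat)] + ctx$stim_duration
           else ctx$t
  if (!induced && params$check == "E") {
    induced <- ctx_check_induction(ctx)
    if (induced) inducing_ci <- train[length(train)]
    t_end <- per_beat$onset[nrow(per_beat)] + ctx$stim_duration
  }
  .protocol_result("RP", induced, beats, inducing_ci,
                   intervals = train[seq_len(beats)], per_beat = per_beat,
                   t_start = t_start, t_end = t_end)
}

#' Find the tissue-level effective refractory period at a site
#'
#' Run-time binary search on the coupling interval after the previous beat,
#' using the local propagation check as predicate (threshold crossing in a
#' 4-6 mm geodesic ring around the site within the check window). Trial
#' beats run from a checkpointed state, so failed probes do not alter the
#' tissue history. The initial bracket is `[guess/2, guess]`, expanded
#' upward by x1.5 while the upper end fails (up to `3 * guess`, then a
#' non-capture error); it is never expanded downward, since far below the
#' refractory period the previous activation itself crosses the ring and
#' would alias as capture. If the
#' evaluated probes violate monotonicity (capture at a shorter coupling but
#' not a longer one) a warning is raised and the search falls back to a
#' linear scan.
#'
#' @param ctx a [sim_context()] (or compatible backend).
#' @param site stimulation site.
#' @param guess initial ERP guess, ms (typically the APD94).
#' @param resolution temporal resolution, ms.
#' @param method `"binary"` (default) or `"linear"` (the exhaustive-scan
#'   oracle: smallest propagating coupling on a `resolution` grid).
#' @return the ERP estimate in ms (smallest propagating coupling, within
#'   `resolution`), with attribute `trials` (data frame of evaluated
#'   couplings).
#' @export
find_erp <- function(ctx, site, guess, resolution = 1,
                     method = c("binary", "linear")) {
  method <- match.arg(method)
  if (guess <= 0) .stopf("guess must be positive")
  trials <- data.frame(coupling = numeric(0), propagated = logical(0))
  probe <- function(cc) {
    ok <- ctx_trial_coupling(ctx, site, cc)
    trials <<- rbind(trials, data.frame(coupling = cc, propagated = ok))
    ok
  }
  c_floor <- ctx$stim_duration + resolution

  if (method == "linear") {
    # same lower bound as the binary-search bracket: far below it the
    # previous beat's own wavefront is still crossing the ring and would
    # alias as capture
    cc <- max(c_floor, guess / 2)
    while (cc <= 3 * guess) {
      if (probe(cc)) return(structure(cc, trials = trials))
      cc <- cc + resolution
    }
    .stopf("no propagation at any coupling up to %g ms", 3 * guess)
  }

  hi <- guess
  lo <- max(guess / 2, c_floor)
  while (!probe(hi)) {
    lo <- hi
    hi <- hi * 1.5
    if (hi > 3 * guess)
      .stopf("no propagation at any coupling up to %g ms", 3 * guess)
  }
  # the bracket is never expanded downward: far below guess/2 the previous
  # beat's own wavefront would alias as capture in the ring check
  if (lo <= guess / 2 + 1e-9 && probe(lo))
    return(structure(lo, trials = trials))
  while (hi - lo > resolution) {
    mid <- (hi + lo) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  # monotonicity guard over everything evaluated
  cap <- trials$coupling[trials$propagated]
  noc <- trials$coupling[!trials$propagated]
  if (length(cap) && length(noc) && min(cap) < max(noc)) {
    warning("non-monotone capture detected (supernormality?); falling back to linear scan",
            call. = FALSE)
    return(find_erp(ctx, site, guess, resolution, method = "linear"))
  }
  structure(hi, trials = trials)
}

#' Run the PEERP protocol at one site
#'
#' Delivers the first beat into resting tissue, then repeatedly finds the
#' local ERP from the post-beat state ([find_erp()]) and delivers the next
#' beat at that coupling, until an arrhythmia is initiated (per-beat
#' induction check) or `max_beats` stimuli have been delivered. The running
#' ERP estimate seeds the next search.
#'
#' @param ctx a [sim_context()] (or compatible backend).
#' @param site stimulation site.
#' @param params a [peerp_params()].
#' @return a `protocol_result`; `intervals` holds the inter-beat coupling
#'   intervals actually used (one per extra stimulus).
#' @export
run_peerp <- function(ctx, site, params = peerp_params()) {
  stopifnot(inherits(params, "peerp_params"))
  t_start <- ctx$t
  if (params$max_beats == 0L)
    return(.protocol_result("PEERP", FALSE, 0L, NA_real_, numeric(0),
                            data.frame(), t_start, t_start))
  guess <- params$erp_first_guess
  if (is.null(guess)) guess <- .peerp_default_guess(ctx)
  intervals <- numeric(0)
  per_beat <- data.frame(beat = integer(0), interval = numeric(0),
                         onset = numeric(0), induced = logical(0))
  induced <- FALSE
  onset <- ctx$t
  ctx_deliver_beat(ctx, site)
  per_beat <- rbind(per_beat, data.frame(beat = 1L, interval = NA_real_,
                                         onset = onset, induced = FALSE))
  induced <- ctx_check_induction(ctx)
  per_beat$induced[1] <- induced
  beats <- 1L
  while (!induced && beats < params$max_beats) {
    erp <- tryCatch(
      find_erp(ctx, site, guess, resolution = params$erp_resolution),
      error = function(e) e)
    if (inherits(erp, "error")) {
      res <- .protocol_result("PEERP", FALSE, beats, NA_real_, intervals,
                              per_beat, t_start, ctx$t)
      res$status <- conditionMessage(erp)
      return(res)
    }
    wait <- as.numeric(erp) - ctx$stim_duration
    if (wait > 0) ctx_wait(ctx, wait)
    onset <- ctx$t
    ctx_deliver_beat(ctx, site)
    beats <- beats + 1L
    intervals <- c(intervals, as.numeric(erp))
    induced <- ctx_check_induction(ctx)
    per_beat <- rbind(per_beat, data.frame(beat = beats,
                                           interval = as.numeric(erp),
                                           onset = onset,
                                           induced = induced))
    guess <- as.numeric(erp)
  }
  t_end <- per_beat$onset[nrow(per_beat)] + ctx$stim_duration
  .protocol_result("PEERP", induced, beats,
                   if (induced && length(intervals))
                     intervals[length(intervals)] else NA_real_,
                   intervals, per_beat, t_start, t_end)
}

# APD94 of the paced single cell as the ERP first guess ("sinus rhythm"
# rendered as steady 1,000 ms pacing)
.peerp_default_guess <- function(ctx) {
  tr <- cell_simulate(ctx$model, 3000, stim_onsets = c(0, 1000, 2000),
                      dt = min(ctx$dt, 0.02), record_dt = 0.5)
  apd94(tr)
}

#' Sustained-arrhythmia criterion on a finished simulation
#'
#' Evaluates the induction criterion on a recorded movie: in the interval
#' `(t_protocol_end, t_protocol_end + window]` every output frame must have
#' at least one conductive node at or above `thr` mV, and a new activation
#' (upward crossing of `thr`) must occur somewhere in every rolling
#' `upstroke_gap` ms (this distinguishes sustained propagation from a hung
#' depolarized plateau).
#'
#' @param movie a `vm_movie` (or `sim_result`).
#' @param t_protocol_end end of the protocol, ms.
#' @param geom the `tissue_geometry` (for the conductive-node mask); if
#'   omitted all nodes count as conductive.
#' @param window continuation window, ms (default 1500).
#' @param thr activity threshold, mV.
#' @param upstroke_gap maximum allowed gap between successive new
#'   activations, ms.
#' @return logical flag.
#' @export
check_induction <- function(movie, t_protocol_end, geom = NULL,
                            window = 1500, thr = -50, upstroke_gap = 500) {
  if (inherits(movie, "sim_result")) movie <- movie$movie
  stopifnot(inherits(movie, "vm_movie"))
  cond <- if (is.null(geom)) rep(TRUE, ncol(movie$vm))
          else .conductive_nodes(geom)
  .induction_criterion(movie$vm, movie$times, cond, t_protocol_end,
                       window = window, thr = thr,
                       upstroke_gap = upstroke_gap)
}

#' Standalone propagation check
#'
#' True iff at least one node in the geodesic ring `ring` (mm) around the
#' site crosses `threshold` upward within `window` ms after `onset`.
#'
#' @param movie a `vm_movie` (or `sim_result`).
#' @param geom the `tissue_geometry`.
#' @param site stimulation site (position mm or node index).
#' @param onset stimulus onset time, ms.
#' @param ring inner and outer geodesic radii, mm.
#' @param threshold voltage threshold, mV.
#' @param window check window after onset, ms.
#' @return logical flag.
#' @export
propagation_check <- function(movie, geom, site, onset = 0, ring = c(4, 6),
                              threshold = -50, window = 80) {
  if (inherits(movie, "sim_result")) movie <- movie$movie
  stopifnot(inherits(movie, "vm_movie"))
  node <- if (length(site) == 1L) as.integer(site)
          else .nearest_node(geom, site)
  dmap <- .geodesic_map(geom, node)
  rn <- which(dmap >= ring[1] & dmap <= ring[2])
  if (!length(rn)) .stopf("empty propagation ring")
  sel <- which(movie$times >= onset - 1e-9 &
               movie$times <= onset + window + 1e-9)
  if (length(sel) < 2) .stopf("no frames in the check window")
  v <- movie$vm[sel, rn, drop = FALSE]
  nf <- nrow(v)
  any(v[-1, , drop = FALSE] >= threshold &
      v[-nf, , drop = FALSE] < threshold)
}
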