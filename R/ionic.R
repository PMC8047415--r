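#' Membrane models
#'
#' Two membrane kinetics are available:
#'
#' * `"courtemanche"` — the Courtemanche et al. (1998) human atrial ionic
#'   model (21 state variables: transmembrane voltage, 15 gating variables,
#'   and intracellular Na+, K+, Ca2+ plus SR Ca2+ pools). Gates are advanced
#'   with Rush-Larsen, everything else with forward Euler; the default time
#'   step is 0.02 ms.
#' * `"fast_test"` — a 3-variable phenomenological model (fast inward, slow
#'   inward and outward current surrogates with two recovery gates) used
#'   where full ionic detail is not required: it produces propagating pulses
#'   and spiral re-entry on desk-scale sheets at a fraction of the cost. Its
#'   default parameters are a shortened-action-potential variant of the
#'   classic 3-current formulation, chosen so that a few-centimetre sheet can
#'   host a rotor.
#'
#' Maximal conductances can be rescaled through a named scale map (see
#' [remodeling_preset()]). For the fast model the scales act on the
#' corresponding current surrogates: `g_Na` on the fast inward, `g_CaL` on
#' the slow inward, `g_K1` on the outward current.
#'
#' @param name model name.
#' @param scales named numeric vector of conductance multipliers; defaults to
#'   all 1 (control).
#' @param fk_params optional named overrides of the fast-model parameters
#'   (time constants in ms, thresholds dimensionless).
#' @return object of class `membrane_model`.
#' @export
membrane_model <- function(name = c("courtemanche", "fast_test"),
                           scales = NULL, fk_params = NULL) {
  name <- match.arg(name)
  sc <- .default_scales()
  if (!is.null(scales)) {
    unknown <- setdiff(names(scales), names(sc))
    if (length(unknown))
      .stopf("unknown conductance key(s): %s", paste(unknown, collapse = ", "))
    if (any(scales <= 0)) .stopf("scale factors must be positive")
    sc[names(scales)] <- scales
  }
  fk <- .default_fk_params()
  if (!is.null(fk_params)) {
    unknown <- setdiff(names(fk_params), names(fk))
    if (length(unknown))
      .stopf("unknown fast-model parameter(s): %s",
             paste(unknown, collapse = ", "))
    fk[names(fk_params)] <- fk_params
  }
  id <- if (name == "courtemanche") 0L else 1L
  structure(list(name = name, id = id, scales = sc, fk = fk,
                 nstate = if (id == 0L) 21L else 3L,
                 rest = .rest_state_cpp(id)),
            class = "membrane_model")
}

.default_scales <- function() {
  setNames(rep(1, 9),
           c("g_Na", "g_K1", "g_to", "g_Kur", "g_Kr", "g_Ks", "g_CaL",
             "g_NaCa", "g_NaK"))
}

# fast_test defaults: a short-APD variant of the 3-current phenomenological
# model (time constants in ms). tau_r/tau_si/tau_wp shortened relative to
# the classic ventricular fit so APD94 ~ 130 ms (ERP ~ 110 ms) and spirals
# fit on ~6 cm sheets.
.default_fk_params <- function() {
  c(tau_d = 0.25, tau_r = 20, tau_si = 18, tau_o = 12.5,
    tau_vp = 3.33, tau_v1m = 1250, tau_v2m = 19.6,
    tau_wp = 600, tau_wm = 41,
    u_c = 0.13, u_v = 0.04, u_csi = 0.85, k = 10)
}

# scale vector in the order expected by the C++ kernels
.scale_vec <- function(model) unname(model$scales[names(.default_scales())])

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> %s (%d states)\n", x$name, x$nstate))
  ns <- x$scales[x$scales != 1]
  if (length(ns))
    cat("  rescaled:", paste(sprintf("%s = %g", names(ns), ns),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Remodeling presets
#'
#' Named conductance-scale maps:
#'
#' * `"control"` — every conductance at 1.0 (identity).
#' * `"AF"` — a representative chronic-AF electrical-remodeling variant of
#'   the atrial model (IK1 up, Ito/ICaL/IKur down, IKs up); the exact factor
#'   set is configurable via `scales` since published AF variants differ.
#' * `"cytokine_fibrotic"` — the cytokine-related remodeling applied to
#'   fibrotic-but-conducting tissue: exactly -50% g_K1, -40% g_Na, -50%
#'   g_CaL.
#' * `"custom"` — caller-supplied `scales`.
#'
#' @param name preset name.
#' @param scales named multipliers for `"custom"` (or overrides for `"AF"`).
#' @return object of class `remodeling_preset`.
#' @export
remodeling_preset <- function(name = c("control", "AF", "cytokine_fibrotic",
                                       "custom"), scales = NULL) {
  name <- match.arg(name)
  sc <- switch(name,
    control = .default_scales(),
    AF = {
      s <- .default_scales()
      s[c("g_K1", "g_to", "g_CaL", "g_Kur", "g_Ks")] <-
        c(2.0, 0.35, 0.35, 0.5, 2.0)
      s
    },
    cytokine_fibrotic = {
      s <- .default_scales()
      s[c("g_K1", "g_Na", "g_CaL")] <- c(0.5, 0.6, 0.5)
      s
    },
    custom = {
      if (is.null(scales)) .stopf("custom preset requires scales")
      .default_scales()
    })
  if (!is.null(scales)) {
    unknown <- setdiff(names(scales), names(sc))
    if (length(unknown))
      .stopf("unknown conductance key(s): %s", paste(unknown, collapse = ", "))
    sc[names(scales)] <- scales
  }
  structure(list(name = name, scales = sc), class = "remodeling_preset")
}

#' Apply a remodeling preset to a membrane model
#'
#' Multiplies the model's maximal-conductance scales by the preset factors;
#' all other parameters are untouched.
#'
#' @param model a [membrane_model()].
#' @param preset a [remodeling_preset()].
#' @return the rescaled `membrane_model`.
#' @export
apply_remodeling <- function(model, preset) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(preset, "remodeling_preset"))
  if (any(preset$scales <= 0)) .stopf("scale factors must be positive")
  model$scales <- model$scales * preset$scales[names(model$scales)]
  model
}

#' Advance a single cell by one time step
#'
#' One forward step of the membrane kinetics (Rush-Larsen for gates, forward
#' Euler otherwise). Mostly useful for inspection; bulk integration should
#' use [cell_simulate()].
#'
#' @param model a [membrane_model()].
#' @param state state vector (defaults to the resting state).
#' @param i_stim stimulus as dV/dt in mV/ms (equivalently uA/cm^2 for a
#'   1 uF/cm^2 membrane).
#' @param dt time step, ms; must be <= 0.05 for the Courtemanche model.
#' @return the advanced state vector.
#' @export
step_cell <- function(model, state = model$rest, i_stim = 0, dt = 0.02) {
  stopifnot(inherits(model, "membrane_model"))
  if (model$id == 0L && dt > 0.05)
    .stopf("dt = %g ms exceeds the stability bound (0.05 ms)", dt)
  out <- .cell_run_cpp(model$id, .scale_vec(model), unname(model$fk),
                       state, dt, dt,
                       if (i_stim != 0) 0 else numeric(0), dt, i_stim,
                       dt, Inf)
  out$final
}

#' Single-cell simulation
#'
#' Integrates one cell for `t_end` ms with stimuli of `stim_dur` ms and
#' amplitude `stim_amp` (mV/ms) at the given onset times.
#'
#' @param model a [membrane_model()].
#' @param t_end total simulated time, ms.
#' @param stim_onsets stimulus onset times, ms.
#' @param stim_dur,stim_amp stimulus duration (ms) and amplitude (mV/ms).
#' @param dt integration step, ms.
#' @param record_dt sampling interval of the returned voltage trace, ms.
#' @param state initial state (defaults to rest).
#' @return object of class `cell_trace`: list with `time`, `vm`, `final`.
#' @export
cell_simulate <- function(model, t_end, stim_onsets = numeric(0),
                          stim_dur = 2, stim_amp = 30, dt = 0.02,
                          record_dt = 0.1, state = model$rest) {
  stopifnot(inherits(model, "membrane_model"))
  if (model$id == 0L && dt > 0.05)
    .stopf("dt = %g ms exceeds the stability bound (0.05 ms)", dt)
  out <- .cell_run_cpp(model$id, .scale_vec(model), unname(model$fk),
                       state, t_end, dt, stim_onsets, stim_dur, stim_amp,
                       record_dt, Inf)
  structure(list(time = out$time, vm = out$vm, final = out$final,
                 dt = record_dt, model = model$name),
            class = "cell_trace")
}

#' Action potential duration at 94% repolarization
#'
#' Measures the duration of the last complete action potential in a voltage
#' trace, from the time of maximum upstroke velocity to 94% repolarization
#' toward the pre-stimulus diastolic level, with linear interpolation between
#' samples.
#'
#' @param vm voltage trace (mV) or a `cell_trace`.
#' @param dt sampling interval of `vm`, ms (taken from the trace if omitted).
#' @return APD94 in ms.
#' @export
apd94 <- function(vm, dt = NULL) {
  if (inherits(vm, "cell_trace")) {
    if (is.null(dt)) dt <- vm$dt
    vm <- vm$vm
  }
  if (is.null(dt)) .stopf("dt is required")
  n <- length(vm)
  if (n < 3) .stopf("trace too short")
  dv <- diff(vm)
  # upstroke candidates: rising crossings of -40 mV
  ups <- which(vm[-n] < -40 & vm[-1] >= -40)
  if (!length(ups)) .stopf("no depolarization found in trace")
  # last upstroke whose AP repolarizes within the trace
  for (u in rev(ups)) {
    # max dV/dt in the 10 ms around the crossing
    w0 <- max(1L, u - round(5 / dt))
    w1 <- min(n - 1L, u + round(5 / dt))
    iup <- w0 - 1L + which.max(dv[w0:w1])
    t_up <- iup * dt  # time of max upstroke velocity (end of the step)
    base_w0 <- max(1L, u - round(50 / dt))
    v_base <- min(vm[base_w0:u])
    seg <- vm[iup:n]
    v_peak <- max(seg)
    v94 <- v_peak - 0.94 * (v_peak - v_base)
    ipk <- iup - 1L + which.max(seg)
    below <- which(vm[(ipk + 1L):n] <= v94)
    if (!length(below)) next
    ib <- ipk + below[1]
    # linear interpolation between samples ib-1 and ib
    frac <- (vm[ib - 1L] - v94) / (vm[ib - 1L] - vm[ib])
    t94 <- (ib - 2L + frac) * dt
    return(t94 - t_up)
  }
  .stopf("no complete action potential (repolarization not reached)")
}

#' Cell-level effective refractory period by exhaustive S1-S2 scan
#'
#' Paces the cell to (approximate) steady state at cycle length `cl`, then
#' scans S2 coupling intervals at the given resolution from `c_min` upward;
#' returns the smallest coupling whose S2 elicits an action potential (peak
#' Vm >= 0 mV). Serves as the slow-but-simple oracle for the tissue-level
#' ERP search.
#'
#' @param model a [membrane_model()].
#' @param cl S1 pacing cycle length, ms.
#' @param resolution scan resolution, ms (>= 0.5).
#' @param n_s1 number of S1 beats before the scan.
#' @param c_min smallest coupling tested, ms.
#' @param stim_dur,stim_amp S1/S2 stimulus shape.
#' @param dt integration step, ms.
#' @return ERP in ms.
#' @export
cell_erp_scan <- function(model, cl = 1000, resolution = 1, n_s1 = 6,
                          c_min = 20, stim_dur = 2, stim_amp = 30,
                          dt = 0.02) {
  stopifnot(inherits(model, "membrane_model"))
  if (resolution < 0.5) .stopf("resolution must be >= 0.5 ms")
  # pre-pace up to (but not including) the last S1, so trials measure the
  # S1-S2 coupling from the final S1 onset
  pre <- cell_simulate(model, (n_s1 - 1) * cl,
                       stim_onsets = (0:(n_s1 - 2)) * cl,
                       stim_dur = stim_dur, stim_amp = stim_amp, dt = dt,
                       record_dt = 1)
  s0 <- pre$final
  couplings <- seq(c_min, cl, by = resolution)
  for (cc in couplings) {
    tr <- .cell_run_cpp(model$id, .scale_vec(model), unname(model$fk),
                        s0, cc + 300, dt, c(0, cc), stim_dur, stim_amp,
                        1, Inf)
    # capture = a new upward crossing of 0 mV after the S2 onset (so the
    # still-depolarized S1 plateau does not count)
    post <- tr$vm[tr$time > cc]
    np <- length(post)
    if (np > 1 && any(post[-1] >= 0 & post[-np] < 0)) return(cc)
  }
  .stopf("no capture at any coupling up to %g ms", cl)
}

#' Limit-cycle template of a paced cell
#'
#' Pre-paces the cell for `n_prepace` beats at cycle length `cl`, then
#' records the full state trajectory over one further cycle. The trajectory
#' is rotated so its first sample is at the maximum upstroke velocity, and is
#' used to seed tissue states from activation-time maps (see
#' [map_to_state()]). Beat-to-beat APD94 alternans above 5 ms triggers a
#' warning (the last beat is used regardless).
#'
#' @param model a [membrane_model()].
#' @param cl cycle length, ms (must exceed the cell ERP for 1:1 capture).
#' @param n_prepace pre-pacing beats (>= 1; 20 recommended for the full
#'   atrial model).
#' @param dt integration step, ms; the template is sampled every `sample_dt`.
#' @param sample_dt template sampling interval, ms.
#' @param stim_dur,stim_amp stimulus shape.
#' @return object of class `limit_cycle`: `states` (nstate x nt matrix),
#'   `period`, `sample_dt`, `model`.
#' @export
limit_cycle_template <- function(model, cl, n_prepace = 20, dt = 0.02,
                                 sample_dt = 0.2, stim_dur = 2,
                                 stim_amp = 30) {
  stopifnot(inherits(model, "membrane_model"))
  if (cl <= 0) .stopf("cycle length must be positive")
  t_end <- (n_prepace + 1) * cl
  out <- .cell_run_cpp(model$id, .scale_vec(model), unname(model$fk),
                       model$rest, t_end, dt,
                       (0:n_prepace) * cl, stim_dur, stim_amp,
                       sample_dt, n_prepace * cl)
  nrec <- as.integer(out$n_state_rec)
  states <- out$states[, seq_len(nrec), drop = FALSE]
  # drop the final sample if it duplicates the period boundary
  nt <- round(cl / sample_dt)
  states <- states[, seq_len(min(nt, ncol(states))), drop = FALSE]

  # alternans check on the last two beats of the recorded Vm trace
  tr_dt <- out$time[2] - out$time[1]
  last2 <- out$vm[out$time >= (n_prepace - 1) * cl]
  a1 <- tryCatch(apd94(out$vm[out$time >= (n_prepace - 1) * cl &
                              out$time < n_prepace * cl + cl * 0.98],
                       dt = tr_dt), error = function(e) NA_real_)
  a2 <- tryCatch(apd94(last2, dt = tr_dt), error = function(e) NA_real_)
  if (is.finite(a1) && is.finite(a2) && abs(a1 - a2) > 5)
    warning(sprintf("alternans detected (beat-to-beat APD94 differs by %.1f ms); using last beat",
                    abs(a1 - a2)), call. = FALSE)

  # rotate so the first sample has maximum dVm/dt over the cycle
  vm_c <- states[1, ]
  dvm <- diff(c(vm_c, vm_c[1]))
  i0 <- which.max(dvm)
  idx <- c(i0:ncol(states), seq_len(i0 - 1L))
  structure(list(states = states[, idx, drop = FALSE], period = cl,
                 sample_dt = sample_dt, model = model$name),
            class = "limit_cycle")
}
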