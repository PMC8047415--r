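#' Per-site vulnerability map
#'
#' Runs one induction protocol independently from every pacing site (each
#' from the identical rested initial tissue state), evaluates the
#' sustained-arrhythmia criterion, classifies induced episodes by their
#' phase-singularity content, and aggregates the outcomes per spatial
#' segment.
#'
#' @param geom a `tissue_geometry` (with segments, see
#'   [partition_segments()]).
#' @param model a [membrane_model()].
#' @param sites a [make_pacing_sites()] site set.
#' @param protocol `"peerp"`, `"rp"` or `"psd"`.
#' @param params an [rp_params()] or [peerp_params()] matching the
#'   protocol (ignored for `"psd"`).
#' @param psd_cl,psd_speed cycle length (ms) and eikonal speed (m/s) for
#'   the PSD protocol.
#' @param analysis_window final window used for classification, ms.
#' @param tau phase embedding delay, ms.
#' @param ctx_args named list of extra arguments for [sim_context()]
#'   (solver settings, check windows, ...).
#' @return object of class `vulnerability_report`: per-site data frame
#'   (`sites`), the episode trajectories, and run metadata.
#' @export
run_vulnerability_map <- function(geom, model, sites,
                                  protocol = c("peerp", "rp", "psd"),
                                  params = NULL, psd_cl = NULL,
                                  psd_speed = NULL,
                                  analysis_window = 1500, tau = 10,
                                  ctx_args = list()) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(sites, "pacing_site_set"))
  if (protocol == "rp" && !inherits(params, "rp_params"))
    .stopf("protocol 'rp' requires rp_params")
  if (protocol == "peerp" && is.null(params)) params <- peerp_params()
  rows <- vector("list", nrow(sites))
  episodes <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    node <- sites$node[i]
    pos <- c(sites$x[i], sites$y[i])
    out <- tryCatch(
      .run_one_site(geom, model, node, pos, protocol, params, psd_cl,
                    psd_speed, analysis_window, tau, ctx_args),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(out$error)) {
      rows[[i]] <- data.frame(site = i, x = pos[1], y = pos[2],
                              node = node,
                              segment = .segment_of(geom, pos),
                              induced = NA, beats = NA_integer_,
                              inducing_ci = NA_real_, class = "error",
                              maintained_segment = NA_integer_,
                              distance_mm = NA_real_,
                              status = out$error)
      next
    }
    episodes[[i]] <- out$trajectories
    rows[[i]] <- data.frame(site = i, x = pos[1], y = pos[2], node = node,
                            segment = .segment_of(geom, pos),
                            induced = out$induced, beats = out$beats,
                            inducing_ci = out$inducing_ci,
                            class = out$class,
                            maintained_segment = out$maintained_segment,
                            distance_mm = out$distance_mm,
                            status = "ok")
  }
  structure(list(sites = do.call(rbind, rows), episodes = episodes,
                 protocol = protocol, params = params,
                 site_set = sites, analysis_window = analysis_window,
                 geom = geom),
            class = "vulnerability_report")
}

#' @export
print.vulnerability_report <- function(x, ...) {
  s <- x$sites
  cat(sprintf("<vulnerability_report> %s: %d sites, %d inducing\n",
              x$protocol, nrow(s), sum(s$induced %in% TRUE)))
  if (any(s$induced %in% TRUE))
    print(table(s$class[s$induced %in% TRUE]))
  invisible(x)
}

.segment_of <- function(geom, pos) {
  enx <- nrow(geom$segments)
  eny <- ncol(geom$segments)
  i <- min(enx, max(1L, floor(pos[1] / geom$h) + 1L))
  j <- if (eny > 1L) min(eny, max(1L, floor(pos[2] / geom$h) + 1L)) else 1L
  geom$segments[i, j]
}

.run_one_site <- function(geom, model, node, pos, protocol, params,
                          psd_cl, psd_speed, analysis_window, tau,
                          ctx_args) {
  if (protocol == "psd") {
    if (is.null(psd_cl) || is.null(psd_speed))
      .stopf("psd protocol requires psd_cl and psd_speed")
    res <- run_psd(geom, model, pos, cl = psd_cl, speed = psd_speed,
                   t_end = analysis_window,
                   dt = ctx_args$dt %||% 0.02,
                   dt_out = ctx_args$dt_out %||% 1)
    movie <- res$movie
    induced <- check_induction(movie, t_protocol_end = 0, geom = geom,
                               window = analysis_window)
    beats <- 0L
    inducing_ci <- NA_real_
    t_now <- movie$times[length(movie$times)]
  } else {
    ctx <- do.call(sim_context, c(list(geom = geom, model = model),
                                  ctx_args))
    pr <- if (protocol == "rp") run_rp(ctx, node, params)
          else run_peerp(ctx, node, params)
    induced <- pr$induced
    beats <- pr$beats_delivered
    inducing_ci <- pr$inducing_ci
    movie <- .ctx_movie(ctx)
    t_now <- ctx$t
  }
  cls <- "none"
  maintained_segment <- NA_integer_
  distance_mm <- NA_real_
  trajectories <- list()
  if (isTRUE(induced)) {
    ph <- compute_phase(movie, tau = tau)
    trajectories <- track_ps(ph)
    ec <- classify_episode(movie, trajectories, induced = TRUE,
                           now = t_now, geom = geom,
                           window = analysis_window,
                           stable_window = analysis_window)
    cls <- ec$class
    if (cls == "stable_llPS") {
      stab <- Filter(function(tr)
        classify_llps(tr, now = t_now,
                      stable_window = analysis_window) == "stable_llPS",
        trajectories)
      ctr <- .path_center(stab[[1]], t_now, analysis_window)
      maintained_segment <- .segment_of(geom, ctr)
      distance_mm <- suppressWarnings(geodesic_distance(geom, pos, ctr))
    }
  }
  list(induced = induced, beats = beats, inducing_ci = inducing_ci,
       class = cls, maintained_segment = maintained_segment,
       distance_mm = distance_mm, trajectories = trajectories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean position of a trajectory over the final window
.path_center <- function(traj, now, window) {
  sel <- traj$t >= now - window
  c(mean(traj$x[sel]), mean(traj$y[sel]))
}

#' Pacing-density sensitivity
#'
#' Given a vulnerability map computed on the full pacing grid, extracts the
#' site subsets lying on coarser grids (inter-point distances `spacings`)
#' and reports, for each, the percentage of stable-llPS-maintaining
#' segments of the full map that the subset recovers.
#'
#' @param report a `vulnerability_report` computed on the full site set.
#' @param spacings coarser inter-point distances, mm.
#' @return data frame with `d_mm`, `n_sites`, `recovered`, `total`,
#'   `percent`.
#' @export
spacing_sensitivity <- function(report, spacings = c(15, 20, 25, 30)) {
  stopifnot(inherits(report, "vulnerability_report"))
  s <- report$sites
  ss <- report$site_set
  margin <- attr(ss, "margin")
  stable <- s$class %in% "stable_llPS"
  base_segs <- unique(s$maintained_segment[stable])
  base_segs <- base_segs[!is.na(base_segs)]
  if (!length(base_segs))
    .stopf("the base map contains no stable-llPS-maintaining segment")
  out <- lapply(spacings, function(d) {
    on_grid <- abs(((ss$cx - margin) / d) -
                   round((ss$cx - margin) / d)) < 1e-6 &
               abs(((ss$cy - margin) / d) -
                   round((ss$cy - margin) / d)) < 1e-6
    sub <- s[s$site %in% which(on_grid), , drop = FALSE]
    rec <- unique(sub$maintained_segment[sub$class %in% "stable_llPS"])
    rec <- rec[!is.na(rec)]
    data.frame(d_mm = d, n_sites = sum(on_grid),
               recovered = length(intersect(rec, base_segs)),
               total = length(base_segs),
               percent = 100 * length(intersect(rec, base_segs)) /
                 length(base_segs))
  })
  do.call(rbind, out)
}

#' ERP-resolution sensitivity of the PEERP map
#'
#' Re-runs the PEERP vulnerability map with the ERP binary search at each
#' temporal resolution in `tolerances` and reports the inducing-point count
#' per resolution; a stable count indicates robustness to ERP measurement
#' uncertainty.
#'
#' @param geom,model,sites,ctx_args as in [run_vulnerability_map()].
#' @param tolerances ERP resolutions to test, ms.
#' @param params base [peerp_params()] (its resolution is overridden).
#' @return data frame with `tolerance_ms` and `n_inducing`, plus the list
#'   of reports as attribute `reports`.
#' @export
erp_tolerance_sweep <- function(geom, model, sites, tolerances = 1:8,
                                params = peerp_params(),
                                ctx_args = list()) {
  dt_out <- ctx_args$dt_out %||% 1
  if (any(tolerances < dt_out))
    .stopf("tolerances below the solver output interval (%g ms)", dt_out)
  reports <- lapply(tolerances, function(tol) {
    p <- params
    p$erp_resolution <- tol
    run_vulnerability_map(geom, model, sites, protocol = "peerp",
                          params = p, ctx_args = ctx_args)
  })
  counts <- vapply(reports, function(r) sum(r$sites$induced %in% TRUE), 0L)
  structure(data.frame(tolerance_ms = tolerances, n_inducing = counts),
            reports = reports)
}

#' Maintenance summary
#'
#' Aggregates one or more vulnerability reports into a per-segment table
#' (inducing-point count, stable-llPS maintenance flag) and the list of
#' geodesic distances between inducing sites and the centers of the paths
#' covered by their stable llPSs.
#'
#' @param reports a `vulnerability_report` or list of them.
#' @return list with `segment_table` (data frame) and `distances`
#'   (data frame: protocol, site, distance_mm).
#' @export
maintenance_summary <- function(reports) {
  if (inherits(reports, "vulnerability_report")) reports <- list(reports)
  segs <- sort(unique(unlist(lapply(reports, function(r)
    as.vector(r$geom$segments)))))
  tab <- lapply(reports, function(r) {
    s <- r$sites
    data.frame(protocol = r$protocol, segment = segs,
               n_inducing = vapply(segs, function(k)
                 sum(s$induced %in% TRUE & s$segment == k), 0L),
               maintains_stable = vapply(segs, function(k)
                 any(s$maintained_segment %in% k), FALSE))
  })
  dist <- lapply(reports, function(r) {
    s <- r$sites
    sel <- s$class %in% "stable_llPS" & is.finite(s$distance_mm)
    if (!any(sel)) return(NULL)
    data.frame(protocol = r$protocol, site = s$site[sel],
               distance_mm = s$distance_mm[sel])
  })
  dist <- dist[!vapply(dist, is.null, TRUE)]
  list(segment_table = do.call(rbind, tab),
       distances = if (length(dist)) do.call(rbind, dist)
                   else data.frame(protocol = character(0),
                                   site = integer(0),
                                   distance_mm = numeric(0)))
}
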