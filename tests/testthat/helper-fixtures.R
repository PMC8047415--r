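# shared fixtures, all generated in code

fast_model <- function(...) membrane_model("fast_test", ...)

# small conductive strand used by ERP / propagation tests
test_strand <- function(nx = 101, h = 0.5, sigma = 0.06) {
  make_strand(nx, h, sigma)
}

# two-region sheet with percolated fibrosis in the LAW half
fibrotic_sheet <- function(nx = 101, ny = 101, h = 0.5, sigma = 0.05,
                           fraction = 0.8, seed = 42) {
  g <- make_sheet(nx, ny, h, sigma, regions = "law_raw")
  apply_fibrosis(g, fibrosis_preset("custom",
                                    fractions = c(LAW = fraction),
                                    seed = seed))
}

# re-entry-supporting sheet: a long-APD (cytokine-remodeled) band creates
# dispersion of refractoriness so premature beats from the south break on
# it, and a nonconductive disc at the band's western flank anchors the
# re-entrant wave (isthmus between disc and band edges)
reentry_sheet <- function(sigma = 0.045) {
  g <- make_sheet(121, 121, 0.5, sigma = sigma)
  ex <- (row(g$label) - 0.5) * g$h
  ey <- (col(g$label) - 0.5) * g$h
  g$label[ex >= 15 & ex <= 45 & ey >= 32 & ey <= 44] <- 2L
  d <- sqrt((ex - 22)^2 + (ey - 38)^2)
  g$label[d <= 6] <- 3L
  g$sigma[d <= 6] <- 1e-7
  g
}

# analytic single-spiral phase field phi = theta around a core, as an
# nx x ny matrix (radians)
analytic_spiral_phase <- function(nx, ny, h, core, charge = 1L) {
  x <- (seq_len(nx) - 1) * h
  y <- (seq_len(ny) - 1) * h
  outer(x, y, function(xx, yy) charge * atan2(yy - core[2], xx - core[1]))
}

# synthetic rotating phase movie: uniform rotation of the spiral pattern
synthetic_phase_movie <- function(nx = 31, ny = 31, h = 1, core = c(15, 15),
                                  nframes = 20, dt_out = 1, omega = 0.3) {
  ph <- vapply(seq_len(nframes), function(f) {
    p <- analytic_spiral_phase(nx, ny, h, core) + omega * (f - 1) * dt_out
    as.vector((p + pi) %% (2 * pi) - pi)
  }, numeric(nx * ny))
  structure(list(phase = t(ph), times = (seq_len(nframes) - 1) * dt_out,
                 nx = nx, ny = ny, h = h, dt_out = dt_out, tau = 10,
                 mask = rep(FALSE, nx * ny)),
            class = "phase_movie")
}

# scripted protocol backend: propagation/induction outcomes are
# predetermined, used to unit-test protocol control flow
mock_context <- function(erp = 150, induce_after_beat = Inf,
                         stim_duration = 2) {
  ctx <- new.env(parent = emptyenv())
  ctx$t <- 0
  ctx$beats <- 0L
  ctx$induced <- FALSE
  ctx$erp <- erp
  ctx$induce_after_beat <- induce_after_beat
  ctx$stim_duration <- stim_duration
  ctx$checks <- 0L
  class(ctx) <- c("mock_context", "environment")
  ctx
}

ctx_wait.mock_context <- function(ctx, duration) {
  ctx$t <- ctx$t + duration
  invisible(ctx)
}
ctx_deliver_beat.mock_context <- function(ctx, site) {
  ctx$t <- ctx$t + ctx$stim_duration
  ctx$beats <- ctx$beats + 1L
  invisible(ctx)
}
ctx_checkpoint.mock_context <- function(ctx) {
  list(t = ctx$t, beats = ctx$beats, induced = ctx$induced)
}
ctx_restore.mock_context <- function(ctx, token) {
  ctx$t <- token$t
  ctx$beats <- token$beats
  ctx$induced <- token$induced
  invisible(ctx)
}
ctx_trial_coupling.mock_context <- function(ctx, site, coupling) {
  coupling >= ctx$erp
}
ctx_check_induction.mock_context <- function(ctx) {
  ctx$checks <- ctx$checks + 1L
  ok <- ctx$beats >= ctx$induce_after_beat
  if (ok) ctx$induced <- TRUE
  ok
}

registerS3method("ctx_wait", "mock_context", ctx_wait.mock_context)
registerS3method("ctx_deliver_beat", "mock_context",
                 ctx_deliver_beat.mock_context)
registerS3method("ctx_checkpoint", "mock_context",
                 ctx_checkpoint.mock_context)
registerS3method("ctx_restore", "mock_context", ctx_restore.mock_context)
registerS3method("ctx_trial_coupling", "mock_context",
                 ctx_trial_coupling.mock_context)
registerS3method("ctx_check_induction", "mock_context",
                 ctx_check_induction.mock_context)
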