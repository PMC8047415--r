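# vulnerability-map tests run on deliberately small domains and shortened
# analysis windows so the full pipeline stays cheap; the window length is
# passed explicitly everywhere, so the 1.5 s study default is exercised by
# the protocol-level tests instead

test_that("a homogeneous sheet yields no inducing points under PEERP", {
  f <- fast_model()
  g <- partition_segments(make_sheet(61, 61, 0.5, sigma = 0.06), 2)
  sites <- make_pacing_sites(g, d = 20, margin = 10)
  rep <- run_vulnerability_map(g, f, sites, protocol = "peerp",
                               params = peerp_params(max_beats = 2,
                                                     erp_first_guess = 150),
                               analysis_window = 500,
                               ctx_args = list(dt = 0.05,
                                               induction_window = 500))
  expect_true(all(rep$sites$induced == FALSE))
  expect_true(all(rep$sites$class == "none"))
  expect_equal(nrow(rep$sites), nrow(sites))
})

test_that("PSD seeding maps sustained rotors and their segments", {
  f <- fast_model()
  g <- partition_segments(make_sheet(101, 101, 0.5, sigma = 0.05), 2)
  sites <- make_pacing_sites(g, d = 15, margin = 17.5)
  expect_equal(nrow(sites), 4)
  rep <- run_vulnerability_map(g, f, sites, protocol = "psd",
                               psd_cl = 130, psd_speed = 0.18,
                               analysis_window = 600,
                               ctx_args = list(dt = 0.05))
  s <- rep$sites
  expect_true(any(s$induced))
  ind <- s[s$induced %in% TRUE, ]
  expect_true(all(ind$class %in% c("stable_llPS", "nonstable_llPS",
                                   "Fl", "Multi")))
  # segment bookkeeping: every site segment is a valid segment id
  expect_true(all(s$segment %in% unique(as.vector(g$segments))))
  # distances only reported for stable episodes
  expect_true(all(is.na(s$distance_mm[!(s$class %in% "stable_llPS")])))
  if (any(s$class %in% "stable_llPS")) {
    st <- s[s$class %in% "stable_llPS", ]
    expect_true(all(is.finite(st$distance_mm)))
    expect_true(all(st$maintained_segment %in%
                    unique(as.vector(g$segments))))
    # spacing sensitivity: the full set recovers 100% of itself
    sens <- spacing_sensitivity(rep, spacings = c(15))
    expect_equal(sens$percent, 100)
    ms <- maintenance_summary(rep)
    expect_true(any(ms$segment_table$maintains_stable))
    expect_equal(nrow(ms$distances), nrow(st))
  }
})

test_that("site order does not affect per-site outcomes", {
  f <- fast_model()
  g <- partition_segments(make_sheet(41, 41, 0.5, sigma = 0.06), 1)
  sites <- make_pacing_sites(g, d = 8, margin = 6)
  sites2 <- sites[rev(seq_len(nrow(sites))), ]
  attr(sites2, "d") <- attr(sites, "d")
  attr(sites2, "margin") <- attr(sites, "margin")
  class(sites2) <- class(sites)
  p <- peerp_params(max_beats = 1, erp_first_guess = 150)
  r1 <- run_vulnerability_map(g, f, sites, protocol = "peerp", params = p,
                              analysis_window = 400,
                              ctx_args = list(dt = 0.05,
                                              induction_window = 400))
  r2 <- run_vulnerability_map(g, f, sites2, protocol = "peerp", params = p,
                              analysis_window = 400,
                              ctx_args = list(dt = 0.05,
                                              induction_window = 400))
  a <- r1$sites[order(r1$sites$node), c("node", "induced", "beats", "class")]
  b <- r2$sites[order(r2$sites$node), c("node", "induced", "beats", "class")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("spacing_sensitivity arithmetic and subset rules", {
  # synthetic report: 6 sites on a 10 mm grid, 3 stable segments
  g <- partition_segments(make_sheet(61, 61, 0.5), 4)
  fake <- structure(list(
    sites = data.frame(site = 1:6,
                       x = c(10, 20, 30, 10, 20, 30),
                       y = c(10, 10, 10, 20, 20, 20),
                       node = 1:6,
                       segment = 1L,
                       induced = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                       beats = 1L, inducing_ci = NA_real_,
                       class = c("stable_llPS", "stable_llPS", "none",
                                 "stable_llPS", "none", "stable_llPS"),
                       maintained_segment = c(1L, 2L, NA, 3L, NA, 2L),
                       distance_mm = 0, status = "ok"),
    episodes = list(), protocol = "peerp", params = NULL,
    site_set = structure(data.frame(x = c(10, 20, 30, 10, 20, 30),
                                    y = c(10, 10, 10, 20, 20, 20),
                                    node = 1:6,
                                    cx = c(10, 20, 30, 10, 20, 30),
                                    cy = c(10, 10, 10, 20, 20, 20)),
                         d = 10, margin = 10,
                         class = c("pacing_site_set", "data.frame")),
    analysis_window = 1500, geom = g),
    class = "vulnerability_report")
  sens <- spacing_sensitivity(fake, spacings = c(10, 20))
  expect_equal(sens$percent[sens$d_mm == 10], 100)
  # d = 20 keeps sites with cx, cy on the 20 mm grid from the margin:
  # (10,10), (30,10), (10,20)... cy-margin must also be divisible: rows
  # with cy = 10 and cx in {10, 30} -> stable segments {1} recovered of 3
  expect_equal(sens$recovered[sens$d_mm == 20], 1)
  expect_equal(sens$percent[sens$d_mm == 20], 100 / 3)
  # nested subsets: percentage non-increasing as d grows
  expect_true(all(diff(sens$percent) <= 0))
})

test_that("erp_tolerance_sweep reports stable counts within bounds", {
  f <- fast_model()
  g <- partition_segments(make_sheet(41, 41, 0.5, sigma = 0.06), 1)
  sites <- make_pacing_sites(g, d = 10, margin = 10)
  expect_error(erp_tolerance_sweep(g, f, sites, tolerances = 0.5),
               "output interval")
  sw <- erp_tolerance_sweep(g, f, sites[1, ], tolerances = c(1, 8),
                            params = peerp_params(max_beats = 2,
                                                  erp_first_guess = 150),
                            ctx_args = list(dt = 0.05,
                                            induction_window = 400))
  expect_equal(sw$tolerance_ms, c(1, 8))
  # no re-entry on this homogeneous sheet at any tolerance
  expect_equal(sw$n_inducing, c(0L, 0L))
  # the per-beat intervals at the two tolerances differ by at most 8 ms
  reps <- attr(sw, "reports")
  expect_s3_class(reps[[1]], "vulnerability_report")
})
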