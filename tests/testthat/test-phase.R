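test_that("phase of a periodic train advances 2 pi per cycle and rests are masked", {
  f <- fast_model()
  g <- test_strand(nx = 51)
  res <- run_monodomain(g, f,
                        list(stimulus_spec(c(0, 0), onset = 5),
                             stimulus_spec(c(0, 0), onset = 205),
                             stimulus_spec(c(0, 0), onset = 405)),
                        t_end = 650, dt = 0.05)
  ph <- compute_phase(res, tau = 10)
  node <- 25
  p <- ph$phase[, node]
  # unwrapped phase winds twice over two full cycles (the embedding
  # convention makes the winding negative; only the magnitude matters)
  dp <- atriavuln:::.wrap_pi(diff(p))
  sel <- ph$times[-1] > 100 & ph$times[-1] <= 500
  expect_lt(abs(abs(sum(dp[sel])) - 2 * 2 * pi), 0.8)

  # a resting (never stimulated) movie is fully masked
  res0 <- run_monodomain(g, f, list(), t_end = 60, dt = 0.05)
  ph0 <- compute_phase(res0, tau = 10)
  expect_true(all(ph0$mask))
  expect_true(all(is.na(ph0$phase)))

  expect_error(compute_phase(res, tau = 10.5), "multiple")
})

test_that("phase recovery on a synthetic rotating field is accurate", {
  # V(t) = V* + A sin(omega t + theta(x)): delay embedding with tau = a
  # quarter period recovers phase up to a constant offset
  nx <- 21; ny <- 21; h <- 1
  period <- 40; omega <- 2 * pi / period; tau <- 10  # quarter period
  th <- as.vector(analytic_spiral_phase(nx, ny, h, c(10, 10)))
  times <- seq(0, 200, by = 1)
  vm <- vapply(seq_along(th), function(n)
    -60 + 20 * sin(omega * times + th[n]), numeric(length(times)))
  movie <- structure(list(vm = vm, times = times, nx = nx, ny = ny, h = h,
                          dt_out = 1), class = "vm_movie")
  ph <- compute_phase(movie, tau = tau, v_star = -60)
  # with V - V* = A sin(omega t + theta) and a quarter-period delay,
  # atan2(sin a, -cos a) = pi - a: the recovered phase is -theta up to a
  # spatially constant offset
  f0 <- 50
  got <- ph$phase[f0, ]
  dif <- atriavuln:::.wrap_pi(got + th)
  # constant offset across nodes (away from the core where theta jumps)
  r <- sqrt((as.vector(row(matrix(0, nx, ny))) - 1 - 10)^2 +
            (as.vector(col(matrix(0, nx, ny))) - 1 - 10)^2)
  ok <- r > 3
  expect_lt(max(abs(dif[ok] - atriavuln:::.wrap_pi(mean(dif[ok])))), 0.15)
})

test_that("detect_ps finds seeded cores with the right charge", {
  nx <- 41; ny <- 41; h <- 0.5
  p1 <- analytic_spiral_phase(nx, ny, h, c(10.25, 10.25), charge = 1L)
  d1 <- detect_ps(p1, h = h)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$charge, 1L)
  expect_lt(max(abs(c(d1$x, d1$y) - 10.25)), h)  # < one grid cell

  # figure-of-eight: two opposite cores, total charge 0
  p2 <- analytic_spiral_phase(nx, ny, h, c(6.25, 10.25), charge = 1L) +
        analytic_spiral_phase(nx, ny, h, c(14.25, 10.25), charge = -1L)
  p2 <- atriavuln:::.wrap_pi(p2)
  d2 <- detect_ps(p2, h = h)
  expect_equal(nrow(d2), 2)
  expect_equal(sum(d2$charge), 0)

  # uniform plane wave: no singularities
  x <- (seq_len(nx) - 1) * h
  p3 <- matrix(rep(atriavuln:::.wrap_pi(x), ny), nx, ny)
  expect_equal(nrow(detect_ps(p3, h = h)), 0)
})

test_that("tracking associates, splits and respects charge", {
  # single stationary detection over 100 frames
  det <- replicate(100, data.frame(x = 5, y = 5, charge = 1L),
                   simplify = FALSE)
  times <- seq(0, by = 2, length.out = 100)
  tr <- track_ps(det, times)
  expect_equal(length(tr), 1)
  expect_equal(tr[[1]]$lifetime, 99 * 2)

  # two crossing tracks of opposite charge are never merged
  n <- 30
  det2 <- lapply(seq_len(n), function(f)
    data.frame(x = c(f * 0.5, 15 - f * 0.5), y = c(5, 5),
               charge = c(1L, -1L)))
  tr2 <- track_ps(det2, seq_len(n))
  expect_equal(length(tr2), 2)
  expect_true(all(vapply(tr2, function(t) length(t$t), 0L) == n))
  expect_setequal(vapply(tr2, `[[`, 0L, "charge"), c(1L, -1L))

  # one-frame dropout: split without bridging, joined with bridging
  det3 <- replicate(21, data.frame(x = 5, y = 5, charge = 1L),
                    simplify = FALSE)
  det3[[11]] <- data.frame(x = numeric(0), y = numeric(0),
                           charge = integer(0))
  t3 <- seq_len(21)
  split <- track_ps(det3, t3)
  expect_equal(length(split), 2)
  joined <- track_ps(det3, t3, bridge_frames = 1)
  expect_equal(length(joined), 1)
  expect_equal(joined[[1]]$lifetime, 20)
})

test_that("tracking gate forbids super-speed jumps", {
  det <- list(data.frame(x = 5, y = 5, charge = 1L),
              data.frame(x = 25, y = 5, charge = 1L))  # 20 mm in 2 ms
  tr <- track_ps(det, c(0, 2), v_max = 1)
  expect_equal(length(tr), 2)  # not associated
})

test_that("llPS classification boundaries at 500 ms and 50 mm", {
  mk <- function(t, x, y) structure(list(charge = 1L, t = t, x = x, y = y,
                                         lifetime = t[length(t)] - t[1]),
                                    class = "ps_trajectory")
  now <- 2000
  # lifetime 499 vs 500
  t499 <- mk(seq(1501, 2000, by = 1), rep(5, 500), rep(5, 500))
  t499$lifetime <- 499
  t499$t <- seq(1501, 2000, length.out = 500)
  expect_equal(classify_llps(t499, now), "not_llPS")
  t500 <- mk(seq(1500, 2000, by = 1), rep(5, 501), rep(5, 501))
  # an llPS, but alive for only the last 500 ms: it does not cover the
  # full 1.5 s stability window...
  expect_equal(classify_llps(t500, now), "nonstable_llPS")
  # ...though it is stable over a matching 500 ms window
  expect_equal(classify_llps(t500, now, stable_window = 500),
               "stable_llPS")

  # covering the final 1.5 s but drifting 60 mm -> nonstable
  tt <- seq(500, 2000, by = 1)
  drift <- mk(tt, seq(0, 60, length.out = length(tt)),
              rep(5, length(tt)))
  expect_equal(classify_llps(drift, now), "nonstable_llPS")
  # the same drift compressed into 49 mm -> stable
  tight <- mk(tt, seq(0, 49, length.out = length(tt)),
              rep(5, length(tt)))
  expect_equal(classify_llps(tight, now), "stable_llPS")

  # long-living but not covering the final window -> nonstable
  early <- mk(seq(0, 700, by = 1), rep(5, 701), rep(5, 701))
  expect_equal(classify_llps(early, now), "nonstable_llPS")
})

test_that("raising the lifetime threshold never increases the llPS count", {
  mk <- function(t) structure(list(charge = 1L, t = t,
                                   x = rep(1, length(t)),
                                   y = rep(1, length(t)),
                                   lifetime = t[length(t)] - t[1]),
                              class = "ps_trajectory")
  trajs <- list(mk(seq(0, 300, 10)), mk(seq(0, 600, 10)),
                mk(seq(0, 900, 10)), mk(seq(0, 1500, 10)))
  counts <- vapply(c(200, 500, 800, 1200), function(thr)
    sum(vapply(trajs, function(tr)
      classify_llps(tr, now = 1500, lifetime_min = thr) != "not_llPS",
      TRUE)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("episode classification covers the four classes and none", {
  ec0 <- classify_episode(structure(list(), class = "vm_movie"),
                          list(), induced = FALSE)
  expect_equal(ec0$class, "none")

  # flutter fixture: periodic macro-re-entry around a nonconductive
  # obstacle has no PS on conductive tissue and periodic activation
  f <- fast_model()
  g <- make_sheet(81, 81, 0.5, sigma = 0.04)
  # central nonconductive block 10 x 10 mm: circuit period ~ perimeter /
  # CV fits ~3 rotations into the analysis window
  ex <- (row(g$label) - 0.5) * g$h
  ey <- (col(g$label) - 0.5) * g$h
  blk <- ex > 15 & ex < 25 & ey > 15 & ey < 25
  g$label[blk] <- 3L
  g$sigma[blk] <- 1e-7
  # seed a wave circulating the obstacle: activation times wind once
  # around the obstacle center, which lies on nonconductive tissue, so
  # the phase field has no singularity on tissue (pure macro-re-entry)
  cl <- 190
  xy <- atriavuln:::.node_xy(g)
  theta <- atan2(xy[, 2] - 20, xy[, 1] - 20)
  tmap <- (cl * theta / (2 * pi)) %% cl
  tmap[!atriavuln:::.conductive_nodes(g)] <- NA
  amap <- structure(list(tmap = tmap, cl = cl, core = NA,
                         speed = NA, chirality = "anticlockwise",
                         nx = g$nx, ny = g$ny, h = g$h),
                    class = "activation_map")
  tpl <- limit_cycle_template(f, 190, n_prepace = 6)
  st <- map_to_state(g, f, amap, tpl)
  res <- run_monodomain(g, f, list(), t_end = 1000, state = st, dt = 0.05)
  ph <- compute_phase(res, tau = 10)
  trajs <- track_ps(ph)
  ec <- classify_episode(res, trajs, induced = TRUE, geom = g,
                         window = 800, stable_window = 800)
  expect_true(ec$class %in% c("Fl", "stable_llPS"))
})
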