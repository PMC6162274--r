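test_that("basins of the lattice are the Voronoi cells of its minima", {
  hm <- makeSurface(s10_100, 200, 1)
  bm <- basinMap(hm)
  mins <- minima(bm)
  expect_equal(nrow(mins), 4L)

  # compare with nearest-minimum (Voronoi) assignment, away from boundaries
  xs <- seq(0, 200, 1)
  X <- outer(rep(1, 201), xs); Y <- outer(xs, rep(1, 201))
  d2 <- array(0, c(201, 201, 4))
  for (k in 1:4) d2[, , k] <- (X - mins$x[k])^2 + (Y - mins$y[k])^2
  vor <- apply(d2, c(1, 2), which.min)
  agree <- mean(basinLabels(bm) == vor)
  expect_gt(agree, 0.99)

  # minima sit inside their own basins and at their basin's lowest height
  z <- heights(hm)
  for (k in 1:4) {
    idx <- curvotaxis:::.pixelIndex(mins$x[k], mins$y[k], dim(z),
                                    spacing(bm), gridOrigin(bm))
    expect_equal(basinLabels(bm)[idx$row, idx$col], k)
    expect_equal(mins$z[k], min(z[basinLabels(bm) == k]))
  }
})

test_that("a single bowl yields a single basin", {
  xs <- seq(-20, 20, 1)
  bowl <- heightMap(outer(xs, xs, function(y, x) 0.01 * (x^2 + y^2)))
  bm <- basinMap(bowl)
  expect_equal(nrow(minima(bm)), 1L)
  expect_true(all(basinLabels(bm) == 1L))
  expect_error(basinMap(heightMap(matrix(1, 5, 5))), "constant")
})

test_that("speed attribution covers all segments and recovers constant speed", {
  hb <- bandsS10(200, 1)
  # diagonal track through valleys and peaks at constant 1 µm/min
  n <- 250
  step <- 1 / sqrt(2)
  trk <- data.frame(t = 0:(n - 1), x = (0:(n - 1)) * step,
                    y = (0:(n - 1)) * step)
  sp <- speedByHeight(list(trk), hb)
  expect_true(all(sp$n > 0))                    # crosses all five bands
  expect_equal(sum(sp$n), n - 1)                # every segment attributed
  expect_true(all(abs(sp$meanSpeed - 1) < 1e-9))

  expect_error(speedByHeight(list(), hb), "empty")
  expect_warning(
    sp1 <- speedByHeight(list(trk, data.frame(t = 0, x = 1, y = 1)), hb),
    "single-sample")
})

test_that("valley transitions are detected with dwell debouncing", {
  hm <- makeSurface(s10_100, 200, 1)
  bm <- basinMap(hm)

  dwell <- function(x, y, k) data.frame(x = rep(x, k), y = rep(y, k))
  mk <- function(df) cbind(t = seq_len(nrow(df)), df)

  # long dwells in two adjacent valleys, brief pass through the col
  tr <- mk(rbind(dwell(50, 50, 10), dwell(100, 50, 1), dwell(150, 50, 10)))
  ev <- detectValleyTransitions(tr, bm, minDwell = 3)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$fromBasin != ev$toBasin)
  expect_lt(ev$tStart, ev$tEnd)

  # two hops: valley 1 -> 2 -> back
  tr3 <- mk(rbind(dwell(50, 50, 8), dwell(150, 50, 8), dwell(50, 50, 8)))
  ev3 <- detectValleyTransitions(tr3, bm, minDwell = 3)
  expect_equal(nrow(ev3), 2L)
  expect_equal(ev3$toBasin[1], ev3$fromBasin[2])

  # confinement: no transitions
  conf <- mk(dwell(50, 50, 20))
  expect_equal(nrow(detectValleyTransitions(conf, bm)), 0L)

  # a one-frame flicker across the boundary is debounced away
  flick <- mk(rbind(dwell(50, 50, 10), dwell(150, 50, 1), dwell(50, 50, 10)))
  expect_equal(nrow(detectValleyTransitions(flick, bm, minDwell = 3)), 0L)

  # time reversal preserves events with swapped endpoints
  rev <- tr3
  rev$x <- rev(tr3$x); rev$y <- rev(tr3$y)
  evR <- detectValleyTransitions(rev, bm, minDwell = 3)
  expect_equal(nrow(evR), nrow(ev3))
  expect_equal(evR$fromBasin, rev(ev3$toBasin))
  expect_equal(evR$toBasin, rev(ev3$fromBasin))
})

test_that("distance to the nearest minimum uses in-plane geometry", {
  ex <- locateExtrema(s10_100, c(200, 200))
  trk <- data.frame(t = c(0, 10, 20), x = c(50, 0, 30), y = c(50, 0, 50))
  d <- distanceToNearestMinimum(trk, ex)
  expect_equal(d$d[1], 0)
  expect_equal(d$d[2], 50 * sqrt(2), tolerance = 1e-12)  # peak to minima ring
  expect_equal(d$d[3], 20)
  expect_error(distanceToNearestMinimum(
    trk, new("ExtremaSet", minima = data.frame(x = numeric(), y = numeric(),
                                               z = numeric()),
             maxima = minima(ex), saddles = minima(ex))), "no minima")
})

test_that("biased walkers approach the minima between early and late windows", {
  cfg <- simulationConfig(spec = s10_100, nCells = 150, chi = 0.1,
                          duration = 1200, seed = 13)
  sim <- simulateCurvotaxis(cfg)
  ex <- locateExtrema(s10_100, c(200, 200))
  dAll <- do.call(rbind, lapply(split(sim$centroids, sim$centroids$track_id),
                                distanceToNearestMinimum, extrema = ex))
  early <- dAll$d[dAll$t >= 30 & dAll$t <= 270]     # 0.5 h - 4.5 h
  late <- dAll$d[dAll$t >= 960 & dAll$t <= 1200]    # 16 h - 20 h
  expect_lt(mean(late), mean(early))
})

test_that("nucleus offset alignment hits its three constructed poles", {
  ex <- locateExtrema(s10_100, c(200, 200))
  cent <- data.frame(cx = 30, cy = 40)            # nearest minimum (50, 50)
  dir <- c(20, 10) / sqrt(500)
  toward <- cbind(cent, x = 30 + 2 * dir[1], y = 40 + 2 * dir[2])
  away <- cbind(cent, x = 30 - 2 * dir[1], y = 40 - 2 * dir[2])
  expect_equal(nucleusOffsetAlignment(toward, ex)$meanCosine, 1,
               tolerance = 1e-12)
  expect_equal(nucleusOffsetAlignment(away, ex)$meanCosine, -1,
               tolerance = 1e-12)

  # isotropic offsets average to zero within Monte-Carlo error
  set.seed(91)
  n <- 10000
  ang <- runif(n, 0, 2 * pi)
  iso <- data.frame(cx = runif(n, 0, 200), cy = runif(n, 0, 200))
  iso$x <- iso$cx + 2 * cos(ang); iso$y <- iso$cy + 2 * sin(ang)
  res <- nucleusOffsetAlignment(iso, ex)
  expect_lt(abs(res$meanCosine), 3 / sqrt(n) * sqrt(0.5) * 3)
  expect_equal(res$nUsed, n)

  # offsets below the threshold yield the undefined sentinel
  tiny <- cbind(cent, x = 30.1, y = 40)
  res0 <- nucleusOffsetAlignment(tiny, ex, minOffset = 0.5)
  expect_true(is.na(res0$meanCosine))
  expect_equal(res0$nUsed, 0L)
})

test_that("alignment is invariant under global rigid motions", {
  ex <- locateExtrema(s10_100, c(200, 200))
  set.seed(17)
  n <- 200
  pr <- data.frame(cx = runif(n, 0, 200), cy = runif(n, 0, 200))
  pr$x <- pr$cx + rnorm(n); pr$y <- pr$cy + rnorm(n)
  base <- nucleusOffsetAlignment(pr, ex)$meanCosine

  th <- 0.83; dx <- 37; dy <- -12
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + dx,
                             y = sin(th) * x + cos(th) * y + dy)
  prR <- pr
  cR <- rot(pr$cx, pr$cy); nR <- rot(pr$x, pr$y)
  prR$cx <- cR$x; prR$cy <- cR$y; prR$x <- nR$x; prR$y <- nR$y
  mR <- rot(minima(ex)$x, minima(ex)$y)
  exR <- new("ExtremaSet",
             minima = data.frame(x = mR$x, y = mR$y, z = minima(ex)$z),
             maxima = maxima(ex), saddles = saddles(ex))
  expect_equal(nucleusOffsetAlignment(prR, exR)$meanCosine, base,
               tolerance = 1e-9)
})
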