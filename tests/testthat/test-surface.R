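test_that("makeSurface samples the stated forms with the stated range", {
  hm <- makeSurface(s10_100, extent = 300, spacing = 1)
  expect_equal(diff(range(heights(hm))), 10)  # S10/100 peak-to-valley

  flat <- makeSurface(sinusoidSpec("sum", 0, 100, zOffset = 1.25),
                      extent = 150, spacing = 5)
  expect_true(all(heights(flat) == 1.25))

  expect_error(makeSurface(s10_100, extent = 300, spacing = 60), "alias")
})

test_that("sum form equals the 45-degree-rotated product form", {
  set.seed(4)
  px <- runif(200, -100, 400); py <- runif(200, -100, 400)
  prod45 <- sinusoidSpec("product", amplitude = 5, period = sqrt(2) * 100)
  zSum <- evalSinusoid(s10_100, px, py)
  zProd <- evalSinusoid(prod45, (px + py) / sqrt(2), (px - py) / sqrt(2))
  expect_lt(max(abs(zSum - zProd)), 1e-9)
})

test_that("analytic curvature matches closed forms at critical points", {
  flat <- sinusoidSpec("sum", 0, 100)
  cv0 <- analyticCurvature(flat, c(0, 13, -7), c(0, 2, 91))
  expect_true(all(cv0$H == 0) && all(cv0$K == 0))

  # at the global maximum H = -B(2*pi/P)^2: convex hills carry H < 0
  atPeak <- analyticCurvature(s10_100, 0, 0)
  expect_equal(atPeak$H, -2.5 * (2 * pi / 100)^2, tolerance = 1e-12)
  expect_equal(1 / abs(atPeak$H), 101.3212, tolerance = 1e-4)
  # at the global minimum the sign flips: concave valleys carry H > 0
  atValley <- analyticCurvature(s10_100, 50, 50)
  expect_equal(atValley$H, +2.5 * (2 * pi / 100)^2, tolerance = 1e-12)

  # a col is a saddle: negative Gaussian curvature, kappa signs opposite
  atCol <- analyticCurvature(s10_100, 50, 0)
  expect_lt(atCol$K, 0)
  expect_true(atCol$kappa1 > 0 && atCol$kappa2 < 0)
})

test_that("discrete curvature converges to the analytic field at order 2", {
  tilted <- heightMap(outer(seq(0, 50, 1), seq(0, 50, 1),
                            function(y, x) 0.3 * x - 0.1 * y + 2))
  cfT <- discreteCurvature(tilted)
  expect_lt(max(abs(meanH(cfT))), 1e-10)

  maxErr <- function(spacing) {
    hm <- makeSurface(s10_100, 300, spacing)
    cf <- discreteCurvature(hm)
    xs <- seq(0, 300, spacing)
    Ha <- outer(xs, xs, function(y, x) analyticCurvature(s10_100, x, y)$H)
    max(abs(meanH(cf) - Ha)[cf@interior])
  }
  e1 <- maxErr(1)
  e05 <- maxErr(0.5)
  expect_lt(e1, 1e-4)
  slope <- log2(e1 / e05)
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("discrete curvature satisfies the field invariants", {
  hm <- makeSurface(specPV(6, 80, phaseX = 0.4), 200, 1)
  cf <- discreteCurvature(hm)
  pcs <- principalCurvatures(cf)
  expect_true(all(pcs$kappa1 >= pcs$kappa2))
  expect_lt(max(abs((pcs$kappa1 + pcs$kappa2) / 2 - meanH(cf))), 1e-9)
  expect_lt(max(abs(pcs$kappa1 * pcs$kappa2 - gaussK(cf))), 1e-9)
})

test_that("isoheight bands partition the field and respect its symmetry", {
  hm <- makeSurface(s10_100, 300, 1)
  hb <- segmentHeightBands(hm)
  expect_equal(sum(bandArea(hb)), prod(dim(heights(hm))))
  expect_true(all(bandLabels(hb) %in% 1:5))
  expect_equal(length(bandEdges(hb)), 6L)

  # on a periodic sample of the zero-phase lattice, z -> -z is an exact
  # symmetry, so outer and inner band pairs have identical areas
  hper <- periodicSurface(s10_100, 200, 1)
  hbp <- segmentHeightBands(hper)
  a <- bandArea(hbp)
  expect_equal(a[1], a[5], tolerance = 0)
  expect_equal(a[2], a[4], tolerance = 0)

  expect_error(segmentHeightBands(heightMap(matrix(2, 5, 5))), "constant")
})

test_that("band area fractions match level-set quadrature of the sinusoid", {
  hb <- segmentHeightBands(makeSurface(s10_100, 300, 0.5))
  got <- bandArea(hb) / sum(bandArea(hb))
  # independent oracle: dense periodic quadrature of the continuous surface
  u <- seq(0, 2 * pi, length.out = 1201)[-1201]
  zo <- 2.5 * outer(cos(u), cos(u), `+`)
  edges <- seq(-5, 5, length.out = 6)
  want <- diff(ecdf_vals <- sapply(edges, function(e) mean(zo < e)))
  want[5] <- 1 - sum(want[1:4])
  expect_equal(got, want, tolerance = 0.01)
})

test_that("equal-area bands have near-equal areas", {
  hb <- segmentHeightBands(makeSurface(s10_100, 300, 1), mode = "equal_area")
  fr <- bandArea(hb) / sum(bandArea(hb))
  expect_true(all(abs(fr - 0.2) < 0.01))
})

test_that("extrema of the lattice sit on the closed-form critical grid", {
  ex <- locateExtrema(s10_100, c(200, 200))
  mins <- minima(ex)[order(minima(ex)$y, minima(ex)$x), ]
  expect_equal(mins$x, c(50, 150, 50, 150), tolerance = 1e-9)
  expect_equal(mins$y, c(50, 50, 150, 150), tolerance = 1e-9)
  expect_true(all(mins$z == -5))

  # exactly one peak per full period cell
  one <- locateExtrema(s10_100, c(0.5, 100.5, 0.5, 100.5))
  expect_equal(nrow(maxima(one)), 1L)

  # every col sits strictly between the global extremes
  sdl <- saddles(ex)
  expect_true(all(sdl$z > -5 & sdl$z < 5))

  # gradient vanishes at every reported critical point
  allPts <- rbind(minima(ex), maxima(ex), sdl)
  g <- sinusoidGradient(s10_100, allPts$x, allPts$y)
  expect_lt(max(abs(c(g$zx, g$zy))), 1e-9)

  expect_warning(ex0 <- locateExtrema(sinusoidSpec("sum", 0, 100), c(100, 100)),
                 "amplitude 0|flat")
  expect_equal(nrow(minima(ex0)), 0L)
})

test_that("product-form extrema follow the same lattice logic", {
  sp <- sinusoidSpec("product", 5, sqrt(2) * 100)
  ex <- locateExtrema(sp, c(300, 300))
  expect_true(all(minima(ex)$z == -5))
  expect_true(all(maxima(ex)$z == 5))
  expect_true(all(abs(saddles(ex)$z) < 1e-9))
})

test_that("minimal curvature radius follows amplitude and scale", {
  expect_equal(curvatureRadiusExtremes(s10_100)$rMin, 101.3212,
               tolerance = 1e-4)
  # 10x smaller amplitude, 10x larger radius
  expect_equal(curvatureRadiusExtremes(specPV(1, 100))$rMin, 1013.212,
               tolerance = 1e-4)
  # homothetic scaling multiplies the radius by the scale factor
  r30 <- curvatureRadiusExtremes(specPV(3, 30))$rMin
  r300 <- curvatureRadiusExtremes(specPV(30, 300))$rMin
  expect_equal(r300 / r30, 10, tolerance = 1e-9)
  # the dense-grid supremum agrees with the closed form at the extrema
  expect_equal(curvatureRadiusExtremes(s10_100, method = "grid")$rMin,
               curvatureRadiusExtremes(s10_100)$rMin, tolerance = 0.02)
  expect_equal(curvatureRadiusExtremes(sinusoidSpec("sum", 0, 100))$rMin, Inf)
})

test_that("unit-cell counting on a patterned disc", {
  # 8 mm disc at 100 µm period: pi * 4000^2 / 100^2 -> 5027 cells
  expect_identical(discUnitCellCount(8000, 100), 5027L)
  expect_identical(discUnitCellCount(1000, 100), as.integer(round(pi * 25)))
})
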