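test_that("simulation runs are bit-reproducible and seed-sensitive", {
  cfg <- simulationConfig(nCells = 20, duration = 300, chi = 0.05,
                          nucleusGain = 0.5, seed = 7)
  a <- simulateCurvotaxis(cfg)
  b <- simulateCurvotaxis(cfg)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$centroids, b$centroids)
  expect_equal(nrow(a$centroids), 20 * (300 / 10 + 1))  # duration/dt + 1

  cfg2 <- simulationConfig(nCells = 20, duration = 300, chi = 0.05,
                           nucleusGain = 0.5, seed = 8)
  expect_false(identical(simulateCurvotaxis(cfg2)$nuclei, a$nuclei))
})

test_that("unbiased walkers occupy the landscape uniformly", {
  hb <- bandsS10(200, 1)
  cfg <- simulationConfig(spec = s10_100, nCells = 400, chi = 0,
                          lambdaSpeed = 0, nucleusGain = 0, seed = 3)
  sim <- simulateCurvotaxis(cfg)
  d <- assignToBands(sim$points, hb)
  frac12 <- sum(d$fractions[1:2])
  areaFrac <- sum(bandArea(hb)[1:2]) / sum(bandArea(hb))
  sd12 <- sqrt(areaFrac * (1 - areaFrac) / 400)
  expect_lt(abs(frac12 - areaFrac), 3 * sd12)
})

test_that("strong drift gathers nearly all nuclei into the valleys", {
  hb <- bandsS10(200, 1)
  cfg <- simulationConfig(spec = s10_100, nCells = 200, chi = 0.5, seed = 5)
  sim <- simulateCurvotaxis(cfg)
  d <- suppressWarnings(assignToBands(sim$points, hb))
  expect_gte(sum(d$fractions[1:2]), 0.9)
})

test_that("concave occupancy rises monotonically with bias strength", {
  hb <- bandsS10(200, 1)
  frac <- vapply(c(0, 0.01, 0.03, 0.1, 0.3), function(chi) {
    sim <- simulateCurvotaxis(simulationConfig(spec = s10_100, nCells = 200,
                                               chi = chi, seed = 42))
    nuc <- sim$nuclei
    late <- nuc[nuc$t >= max(nuc$t) / 2, c("x", "y")]
    d <- suppressWarnings(assignToBands(late, hb))
    sum(d$fractions[1:2])
  }, numeric(1))
  expect_identical(order(frac), 1:5)  # Spearman rho = 1 over the dose grid
})

test_that("height-speed coupling shows up in band speeds and only then", {
  hb <- bandsS10(200, 1)
  simL <- simulateCurvotaxis(simulationConfig(spec = s10_100, nCells = 200,
                                              lambdaSpeed = 0.5, seed = 9))
  sp <- speedByHeight(simL$centroids, hb)
  expect_gt(sp$meanSpeed[5], sp$meanSpeed[1])

  # with no coupling the band-5 vs band-1 difference stays unremarkable
  # in at least 9 of 10 replicate runs
  bandSpeedP <- function(sim) {
    sp <- speedByHeight(sim$centroids, hb)
    # two-sided z-ish test from the per-band summaries
    z <- (sp$meanSpeed[5] - sp$meanSpeed[1]) /
      sqrt(sp$sdSpeed[5]^2 / sp$n[5] + sp$sdSpeed[1]^2 / sp$n[1])
    2 * pnorm(-abs(z))
  }
  hits <- vapply(1:10, function(s) {
    sim0 <- simulateCurvotaxis(simulationConfig(spec = s10_100, nCells = 60,
                                                duration = 600,
                                                lambdaSpeed = 0, seed = 100 + s))
    bandSpeedP(sim0) > 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("nucleus leads the centroid downhill when the gain is on", {
  ex <- locateExtrema(s10_100, c(200, 200))
  simG <- simulateCurvotaxis(simulationConfig(spec = s10_100, nCells = 100,
                                              chi = 0.1, nucleusGain = 0.6,
                                              nucleusNoise = 0.05, seed = 11))
  late <- simG$nuclei[simG$nuclei$t >= max(simG$nuclei$t) / 2, ]
  expect_gt(nucleusOffsetAlignment(late, ex)$meanCosine, 0.8)

  sim0 <- simulateCurvotaxis(simulationConfig(spec = s10_100, nCells = 100,
                                              chi = 0.1, nucleusGain = 0,
                                              nucleusNoise = 0.3, seed = 12))
  late0 <- sim0$nuclei[sim0$nuclei$t >= max(sim0$nuclei$t) / 2, ]
  res0 <- nucleusOffsetAlignment(late0, ex, minOffset = 0.1)
  expect_lt(abs(res0$meanCosine), 3 / sqrt(res0$nUsed) * 3)
})

test_that("Boltzmann placement matches its density and symmetries", {
  hb <- bandsS10(200, 1)
  areaFrac <- bandArea(hb) / sum(bandArea(hb))

  u <- placePointsBoltzmann(s10_100, beta = 0, n = 4000, extent = 200,
                            seed = 1)
  du <- assignToBands(u, hb)
  expect_equal(du$fractions, areaFrac, tolerance = 0.05)

  b2 <- placePointsBoltzmann(s10_100, beta = 2, n = 2000, extent = 200,
                             seed = 2)
  expect_gt(sum(assignToBands(b2, hb)$fractions[1:2]), 0.95)

  # negative beta mirrors the enrichment onto the convex bands
  bm <- placePointsBoltzmann(s10_100, beta = -0.5, n = 4000, extent = 200,
                             seed = 3)
  bp <- placePointsBoltzmann(s10_100, beta = +0.5, n = 4000, extent = 200,
                             seed = 4)
  fm <- assignToBands(bm, hb)$fractions
  fp <- assignToBands(bp, hb)$fractions
  expect_equal(sum(fm[4:5]), sum(fp[1:2]), tolerance = 0.03)

  expect_identical(placePointsBoltzmann(s10_100, 1, 50, 100, seed = 9),
                   placePointsBoltzmann(s10_100, 1, 50, 100, seed = 9))
})

test_that("noisy height maps reduce to the ideal surface without noise", {
  sp <- specPV(10, 100, phaseX = 0.2)
  clean <- makeNoisyHeightMap(sp, noiseSd = 0, wavinessAmp = 0, extent = 200,
                              spacing = 2, seed = 1)
  expect_identical(heights(clean), heights(makeSurface(sp, 200, 2)))

  n1 <- makeNoisyHeightMap(sp, noiseSd = 0.05, extent = 200, spacing = 2,
                           seed = 6)
  n2 <- makeNoisyHeightMap(sp, noiseSd = 0.05, extent = 200, spacing = 2,
                           seed = 6)
  expect_identical(heights(n1), heights(n2))
  expect_gt(sd(heights(n1) - heights(clean)), 0.04)
})

test_that("invalid simulation configs are rejected before sampling", {
  expect_error(simulationConfig(nCells = 0), "nCells")
  expect_error(simulationConfig(lambdaSpeed = 1.2), "lambdaSpeed")
  expect_error(simulationConfig(dt = 0), "dt")
  expect_error(simulationConfig(nucleusGain = 2), "nucleusGain")
})
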