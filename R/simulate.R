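#' @include AllClasses.R utils.R surface.R
NULL

#' Simulate curvotactic cell migration on a sinusoidal landscape
#'
#' A biased persistent random walk embodying the nuclear-sliding model of
#' curvature-guided migration: cells explore the landscape with a
#' persistent heading, a downhill drift biases their random walk toward
#' concave valleys, speed is modulated by local height (faster on convex
#' hills), and the nucleus is offset from the cell centroid toward the
#' local downhill direction.
#'
#' Per frame of length \eqn{dt}:
#' \deqn{\theta_{t+dt} = \theta_t + \sqrt{2\,dt/\tau}\,\eta,\qquad
#'       \mathbf{x}_{t+dt} = \mathbf{x}_t +
#'       [v(\mathbf{x})\hat{e}(\theta) - \chi\nabla h(\mathbf{x})]\,dt}
#' with \eqn{v(\mathbf{x}) = v_0(1+\lambda\tilde z)\,\varepsilon_t},
#' \eqn{\tilde z} the height normalized to \eqn{[-1,1]}, \eqn{\eta} standard
#' normal, \eqn{\varepsilon_t} a lognormal mean-1 frame-to-frame speed
#' fluctuation of coefficient of variation \code{speedCV} (cell motility is
#' not metronomic), and reflecting borders. The nucleus sits at
#' \deqn{\mathbf{n} = \mathbf{x} + g\,r_{cell}
#'       \frac{|\nabla h|}{g_{max}}\,\hat{u}_{downhill} + \varepsilon,}
#' \eqn{g} the nucleus gain, \eqn{g_{max}} the maximal slope of the
#' landscape and \eqn{\varepsilon} isotropic Gaussian jitter. These
#' equations are this package's minimal embodiment of the qualitative
#' model (concave accumulation, higher convex speed, nucleus pointing at
#' minima), not measured kinetics; see the methods vignette.
#'
#' All randomness is drawn from a single stream seeded by
#' \code{config@seed}; identical configs give bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return list with \code{centroids} and \code{nuclei} (data.frames
#'   \code{track_id}, \code{t}, \code{x}, \code{y}; nuclei also carry the
#'   paired centroid as \code{cx}, \code{cy}), \code{points} (final nucleus
#'   positions, columns \code{x}, \code{y}) and \code{config}.
#' @examples
#' sim <- simulateCurvotaxis(simulationConfig(nCells = 5, duration = 100))
#' head(sim$nuclei)
#' @export
simulateCurvotaxis <- function(config) {
  validObject(config)
  spec <- config@spec
  nSteps <- floor(config@duration / config@dt)
  nc <- config@nCells
  ex <- config@extent
  halfRange <- heightRange(spec) / 2
  k <- 2 * pi / spec@period
  gmax <- if (spec@form == "sum") sqrt(2) * spec@amplitude * k else
    spec@amplitude * k
  set.seed(config@seed)
  x <- stats::runif(nc, 0, ex[1])
  y <- stats::runif(nc, 0, ex[2])
  theta <- stats::runif(nc, 0, 2 * pi)
  angNoise <- matrix(stats::rnorm(nc * nSteps, sd = sqrt(2 * config@dt /
                                                           config@persistenceTau)),
                     nc, nSteps)
  sLog <- sqrt(log(1 + config@speedCV^2))
  speedFluc <- matrix(exp(stats::rnorm(nc * nSteps, -sLog^2 / 2, sLog)),
                      nc, nSteps)
  nucJitter <- array(stats::rnorm(nc * (nSteps + 1L) * 2L,
                                  sd = config@nucleusNoise),
                     c(nc, nSteps + 1L, 2L))
  X <- matrix(0, nc, nSteps + 1L); Y <- matrix(0, nc, nSteps + 1L)
  X[, 1] <- x; Y[, 1] <- y
  reflect <- function(p, hi) {
    p <- p %% (2 * hi)
    ifelse(p > hi, 2 * hi - p, p)
  }
  for (s in seq_len(nSteps)) {
    d <- .sinusoidDerivs(spec, x, y)
    ztil <- (d$z - spec@zOffset) / halfRange
    v <- config@v0 * (1 + config@lambdaSpeed * ztil) * speedFluc[, s]
    theta <- theta + angNoise[, s]
    x <- x + (v * cos(theta) - config@chi * d$zx) * config@dt
    y <- y + (v * sin(theta) - config@chi * d$zy) * config@dt
    x <- reflect(x, ex[1])
    y <- reflect(y, ex[2])
    X[, s + 1L] <- x; Y[, s + 1L] <- y
  }
  ## nucleus offset downhill at every stored frame
  g <- .sinusoidDerivs(spec, X, Y)
  gn <- sqrt(g$zx^2 + g$zy^2)
  sc <- config@nucleusGain * config@cellRadius *
    pmin(gn / gmax, 1) / pmax(gn, .Machine$double.eps)
  NX <- X - sc * g$zx + nucJitter[, , 1L]
  NY <- Y - sc * g$zy + nucJitter[, , 2L]
  tvec <- (0:nSteps) * config@dt
  ids <- sprintf("cell%03d", seq_len(nc))
  centroids <- data.frame(
    track_id = rep(ids, each = nSteps + 1L),
    t = rep(tvec, times = nc),
    x = as.vector(t(X)), y = as.vector(t(Y)))
  nuclei <- data.frame(
    track_id = centroids$track_id, t = centroids$t,
    x = as.vector(t(NX)), y = as.vector(t(NY)),
    cx = centroids$x, cy = centroids$y)
  list(centroids = centroids, nuclei = nuclei,
       points = data.frame(x = NX[, nSteps + 1L], y = NY[, nSteps + 1L]),
       config = config)
}

#' Sample nuclei positions from a height-Boltzmann distribution
#'
#' Fast stationary-distribution stand-in for the migration simulator:
#' points with density \eqn{\propto e^{-\beta z(x,y)}} are drawn by
#' rejection sampling. Positive \eqn{\beta} enriches valleys (concave
#' bands), \eqn{\beta = 0} is uniform, negative \eqn{\beta} mirrors the
#' enrichment onto hills.
#'
#' @param spec a [SinusoidSpec-class].
#' @param beta inverse-height bias in µm^-1.
#' @param n number of points (>= 1).
#' @param extent sampling window, µm; scalar or length 2.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{x}, \code{y} (µm).
#' @examples
#' p <- placePointsBoltzmann(sinusoidSpec("sum", 2.5, 100), beta = 2,
#'                           n = 100, extent = 200, seed = 1)
#' @export
placePointsBoltzmann <- function(spec, beta, n, extent, seed = 1) {
  validObject(spec)
  .stopIfNot(n >= 1, "n must be >= 1")
  if (length(extent) == 1L) extent <- rep(extent, 2L)
  zlo <- spec@zOffset - heightRange(spec) / 2
  logM <- -beta * if (beta > 0) zlo else zlo + heightRange(spec)
  set.seed(as.integer(seed))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    todo <- n - length(xs)
    batch <- max(2L * todo, 100L)
    cx <- stats::runif(batch, 0, extent[1])
    cy <- stats::runif(batch, 0, extent[2])
    acc <- log(stats::runif(batch)) < -beta * evalSinusoid(spec, cx, cy) - logM
    xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Generate a noisy height map emulating a measured topography
#'
#' The ideal landscape plus white Gaussian nanoroughness and a
#' long-wavelength cosine form error (waviness), the two blemishes a real
#' interferometric measurement of a machined sinusoid carries. Used to
#' exercise the metrology chain; the same seed yields the identical map.
#'
#' @param spec a [SinusoidSpec-class].
#' @param noiseSd roughness standard deviation, µm.
#' @param wavinessAmp form-error amplitude, µm.
#' @param wavinessPeriod form-error wavelength, µm (should exceed the
#'   landscape period).
#' @param extent,spacing grid geometry as in [makeSurface()].
#' @param seed integer RNG seed.
#' @return A [HeightMap-class].
#' @export
makeNoisyHeightMap <- function(spec, noiseSd = 0.05, wavinessAmp = 0,
                               wavinessPeriod = 2000, extent = 300,
                               spacing = 1, seed = 1) {
  hm <- makeSurface(spec, extent = extent, spacing = spacing)
  z <- hm@heights
  if (wavinessAmp != 0) {
    xs <- xCoords(hm); ys <- yCoords(hm)
    ## oblique plane wave so the waviness is not aligned with the lattice
    W <- outer(ys, xs, function(y, x)
      wavinessAmp * cos(2 * pi * (cos(0.3) * x + sin(0.3) * y) /
                          wavinessPeriod))
    z <- z + W
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    z <- z + matrix(stats::rnorm(length(z), sd = noiseSd), nrow(z), ncol(z))
  }
  heightMap(z, spacing = hm@spacing, origin = hm@origin)
}
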