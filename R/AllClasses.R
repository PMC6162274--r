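#' @import methods
NULL

#' Parametric description of an ideal sinusoidal landscape
#'
#' A \code{SinusoidSpec} fixes the analytic form of a cell-scale
#' hills-and-valleys surface. Two equivalent parameterizations are supported:
#' the \emph{sum} form
#' \deqn{z(x,y) = B[\cos(2\pi x/P + \phi_x) + \cos(2\pi y/P + \phi_y)] + z_0}
#' whose axes are the lattice axes, and the \emph{product} form
#' \deqn{z(x,y) = A\cos(2\pi x/P + \phi_x)\cos(2\pi y/P + \phi_y) + z_0}
#' whose axes are the lattice diagonals. A sum-form surface with component
#' amplitude \eqn{B} and axis period \eqn{P} equals a product-form surface
#' with amplitude \eqn{A = 2B} and period \eqn{\sqrt{2}P}, rotated by 45
#' degrees (the identity \eqn{\cos a + \cos b = 2\cos\frac{a+b}{2}\cos\frac{a-b}{2}}).
#'
#' The conventional surface names S10/100, S3/30, ... give peak-to-valley
#' amplitude / axis period in micrometres; for the sum form the peak-to-valley
#' range is \eqn{4B}, so S10/100 corresponds to \code{amplitude = 2.5},
#' \code{period = 100}.
#'
#' @slot form either \code{"sum"} or \code{"product"}.
#' @slot amplitude component amplitude in micrometres (\eqn{B} for the sum
#'   form, \eqn{A} for the product form); must be non-negative.
#' @slot period axis period \eqn{P} of each cosine in micrometres; positive.
#' @slot phaseX,phaseY phase shifts in radians.
#' @slot zOffset height offset \eqn{z_0} in micrometres.
#' @seealso [sinusoidSpec()], [makeSurface()], [analyticCurvature()]
#' @export
setClass("SinusoidSpec",
  representation(form = "character", amplitude = "numeric",
                 period = "numeric", phaseX = "numeric", phaseY = "numeric",
                 zOffset = "numeric"),
  prototype(form = "sum", amplitude = 2.5, period = 100,
            phaseX = 0, phaseY = 0, zOffset = 0))

setValidity("SinusoidSpec", function(object) {
  msg <- character()
  if (length(object@form) != 1L || !object@form %in% c("sum", "product"))
    msg <- c(msg, "form must be \"sum\" or \"product\"")
  for (s in c("amplitude", "period", "phaseX", "phaseY", "zOffset")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste(s, "must be a finite scalar"))
  }
  if (length(object@period) == 1L && is.finite(object@period) && object@period <= 0)
    msg <- c(msg, "period must be > 0")
  if (length(object@amplitude) == 1L && is.finite(object@amplitude) && object@amplitude < 0)
    msg <- c(msg, "amplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SinusoidSpec
#'
#' @param form \code{"sum"} (lattice axes) or \code{"product"} (diagonal axes).
#' @param amplitude component amplitude in µm (\eqn{B} for sum, \eqn{A} for
#'   product form).
#' @param period axis period in µm.
#' @param phaseX,phaseY phases in radians.
#' @param zOffset height offset in µm.
#' @return A [SinusoidSpec-class] object.
#' @examples
#' s10 <- sinusoidSpec("sum", amplitude = 2.5, period = 100)  # S10/100
#' heightRange(s10)   # peak-to-valley 10 µm
#' @export
sinusoidSpec <- function(form = c("sum", "product"), amplitude, period,
                         phaseX = 0, phaseY = 0, zOffset = 0) {
  form <- match.arg(form)
  new("SinusoidSpec", form = form, amplitude = as.numeric(amplitude),
      period = as.numeric(period), phaseX = as.numeric(phaseX),
      phaseY = as.numeric(phaseY), zOffset = as.numeric(zOffset))
}

#' Sampled surface z(x, y) on a regular grid
#'
#' Heights are stored as a numeric matrix in micrometres with rows indexing
#' \eqn{y} and columns indexing \eqn{x}; samples sit at pixel centres. The
#' pixel at row \eqn{i}, column \eqn{j} is centred at
#' \eqn{(origin_x + (j-1)s_x,\ origin_y + (i-1)s_y)}.
#'
#' @slot heights numeric matrix of heights (µm), all finite.
#' @slot spacing numeric(2): pixel spacing (µm) along x and y.
#' @slot origin numeric(2): coordinates (µm) of the first pixel centre.
#' @seealso [heightMap()], [makeSurface()], [readHeightMap()]
#' @export
setClass("HeightMap",
  representation(heights = "matrix", spacing = "numeric", origin = "numeric"),
  prototype(heights = matrix(0, 2, 2), spacing = c(1, 1), origin = c(0, 0)))

setValidity("HeightMap", function(object) {
  msg <- character()
  h <- object@heights
  if (!is.numeric(h)) msg <- c(msg, "heights must be numeric")
  if (nrow(h) < 2L || ncol(h) < 2L) msg <- c(msg, "grid must be at least 2x2")
  if (!all(is.finite(h))) msg <- c(msg, "all heights must be finite")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive values (µm)")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite values (µm)")
  if (length(msg)) msg else TRUE
})

#' Construct a HeightMap from a matrix of heights
#'
#' @param heights numeric matrix (µm), rows = y, columns = x.
#' @param spacing pixel spacing in µm; scalar or length-2 (x, y).
#' @param origin coordinates of the first pixel centre (µm); length 2.
#' @return A [HeightMap-class] object.
#' @export
heightMap <- function(heights, spacing = 1, origin = c(0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  new("HeightMap", heights = heights, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Mean, Gaussian and principal curvature grids of a height map
#'
#' Sign convention: the surface normal points up (+z), so \eqn{H > 0} in
#' concave valleys and \eqn{H < 0} on convex hills. \code{kappa1} is the
#' larger principal curvature pointwise (\code{kappa1 >= kappa2}),
#' \eqn{H = (\kappa_1+\kappa_2)/2} and \eqn{K = \kappa_1\kappa_2}.
#'
#' @slot meanH mean curvature grid (µm^-1).
#' @slot gaussK Gaussian curvature grid (µm^-2).
#' @slot kappa1,kappa2 principal curvature grids (µm^-1).
#' @slot interior logical matrix: TRUE where the full central-difference
#'   stencil applied; border pixels (one-sided stencils, lower accuracy) are
#'   FALSE.
#' @slot spacing,origin grid geometry, as for [HeightMap-class].
#' @seealso [discreteCurvature()], [analyticCurvature()]
#' @export
setClass("CurvatureField",
  representation(meanH = "matrix", gaussK = "matrix", kappa1 = "matrix",
                 kappa2 = "matrix", interior = "matrix",
                 spacing = "numeric", origin = "numeric"))

setValidity("CurvatureField", function(object) {
  msg <- character()
  d <- dim(object@meanH)
  for (s in c("gaussK", "kappa1", "kappa2", "interior"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste(s, "dimensions differ from meanH"))
  if (!length(msg)) {
    if (any(object@kappa1 < object@kappa2 - 1e-9, na.rm = TRUE))
      msg <- c(msg, "kappa1 must be >= kappa2 pointwise")
    if (max(abs((object@kappa1 + object@kappa2) / 2 - object@meanH)) > 1e-9)
      msg <- c(msg, "(kappa1+kappa2)/2 must equal meanH")
    if (max(abs(object@kappa1 * object@kappa2 - object@gaussK)) > 1e-9)
      msg <- c(msg, "kappa1*kappa2 must equal gaussK")
  }
  if (length(msg)) msg else TRUE
})

#' Isoheight-band segmentation of a height map
#'
#' The landscape is split into \code{nBands} areas delimited by isoheight
#' contour lines (five by default, band 1 the lowest/most concave). Pixels are
#' assigned by the half-open interval \eqn{[e_i, e_{i+1})}; the top band is
#' closed so every pixel is labelled.
#'
#' @slot edges ordered numeric vector of nBands+1 band-edge heights (µm).
#' @slot labels integer matrix of band indices 1..nBands.
#' @slot bandArea projected area per band (µm^2).
#' @slot mode \code{"equal_height"} or \code{"equal_area"}.
#' @slot spacing,origin grid geometry, as for [HeightMap-class].
#' @seealso [segmentHeightBands()], [assignToBands()]
#' @export
setClass("HeightBands",
  representation(edges = "numeric", labels = "matrix", bandArea = "numeric",
                 mode = "character", spacing = "numeric", origin = "numeric"))

setValidity("HeightBands", function(object) {
  msg <- character()
  n <- length(object@bandArea)
  if (length(object@edges) != n + 1L) msg <- c(msg, "need nBands+1 edges")
  if (any(diff(object@edges) <= 0)) msg <- c(msg, "edges must be strictly increasing")
  if (any(!object@labels %in% seq_len(n))) msg <- c(msg, "every pixel must carry a band label")
  a <- prod(dim(object@labels)) * prod(object@spacing)
  if (abs(sum(object@bandArea) - a) > 1e-6 * a)
    msg <- c(msg, "band areas must sum to the field area")
  if (length(msg)) msg else TRUE
})

#' Critical points of a sinusoidal landscape
#'
#' Minima, maxima and saddles (cols) of the surface, each a data.frame with
#' columns \code{x}, \code{y}, \code{z} in micrometres.
#'
#' @slot minima,maxima,saddles data.frames of critical points.
#' @seealso [locateExtrema()], [distanceToNearestMinimum()]
#' @export
setClass("ExtremaSet",
  representation(minima = "data.frame", maxima = "data.frame",
                 saddles = "data.frame"))

setValidity("ExtremaSet", function(object) {
  msg <- character()
  for (s in c("minima", "maxima", "saddles")) {
    df <- slot(object, s)
    if (nrow(df) && !all(c("x", "y", "z") %in% names(df)))
      msg <- c(msg, paste(s, "needs columns x, y, z"))
  }
  if (nrow(object@minima) && nrow(object@maxima) &&
      min(object@maxima$z) < max(object@minima$z))
    msg <- c(msg, "minima z must not exceed maxima z")
  if (length(msg)) msg else TRUE
})

#' Watershed basins of attraction of the surface minima
#'
#' Each pixel is labelled with the index of the minimum its steepest-descent
#' path terminates at (8-connectivity).
#'
#' @slot labels integer matrix of basin indices.
#' @slot minima an [ExtremaSet-class] holding the basin minima (one per label).
#' @slot spacing,origin grid geometry.
#' @seealso [basinMap()], [detectValleyTransitions()]
#' @export
setClass("BasinMap",
  representation(labels = "matrix", minima = "ExtremaSet",
                 spacing = "numeric", origin = "numeric"))

#' Surface-quality report in the style of areal metrology tables
#'
#' Produced by [fitSinusoid()]: the closest product-form sinusoid (amplitude,
#' period along the product axes, phases, axis orientation), the residual
#' \dQuote{shape} statistic (standard deviation of measured minus fitted
#' heights) and Sa of the input.
#'
#' @slot fittedSpec product-form [SinusoidSpec-class] of the best fit.
#' @slot theta fitted product-axis orientation, radians from the x axis.
#' @slot shapeResidual standard deviation of the fit residual (µm).
#' @slot sa arithmetic mean deviation Sa of the input map (µm).
#' @slot fittedPeriod spatial period along the product axes (µm); for a
#'   lattice of axis period P this is sqrt(2)*P.
#' @slot latticePeriod the equivalent lattice-axis period, fittedPeriod/sqrt(2).
#' @slot fittedAmplitude product amplitude A (µm).
#' @slot converged logical fit-convergence flag.
#' @slot diagnostics list of fit diagnostics (starts tried, RSS trace).
#' @export
setClass("MetrologyReport",
  representation(fittedSpec = "SinusoidSpec", theta = "numeric",
                 shapeResidual = "numeric", sa = "numeric",
                 fittedPeriod = "numeric", latticePeriod = "numeric",
                 fittedAmplitude = "numeric", converged = "logical",
                 diagnostics = "list"))

setValidity("MetrologyReport", function(object) {
  msg <- character()
  if (object@shapeResidual < 0) msg <- c(msg, "shapeResidual must be >= 0")
  if (object@sa < 0) msg <- c(msg, "sa must be >= 0")
  if (object@fittedPeriod <= 0) msg <- c(msg, "fittedPeriod must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of the Monte-Carlo complete-spatial-randomness curvotaxis test
#'
#' @slot concaveFractionObs observed fraction of points in the concave bands.
#' @slot nullMean,nullSd mean and sd of the fraction under the uniform null.
#' @slot pValue one-sided Monte-Carlo p-value for concave enrichment.
#' @slot nMc number of Monte-Carlo draws.
#' @slot nTotal number of points used.
#' @slot concaveBands the band indices counted as concave.
#' @slot seed RNG seed used (reproducibility contract).
#' @seealso [csrTest()]
#' @export
setClass("CurvotaxisTestResult",
  representation(concaveFractionObs = "numeric", nullMean = "numeric",
                 nullSd = "numeric", pValue = "numeric", nMc = "integer",
                 nTotal = "integer", concaveBands = "integer", seed = "integer"))

setValidity("CurvotaxisTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]" else TRUE
})

#' Voxelized 3-D binary mask (e.g. a segmented nucleus)
#'
#' @slot mask 3-D logical/0-1 array indexed (x, y, z).
#' @slot voxelSize numeric(3): voxel edge lengths in µm (anisotropy allowed).
#' @seealso [voxelMask()], [shapeFromMask()]
#' @export
setClass("VoxelMask",
  representation(mask = "array", voxelSize = "numeric"))

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be a 3-D array")
  if (!sum(object@mask != 0)) msg <- c(msg, "mask needs at least one foreground voxel")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values (µm)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelMask
#'
#' @param mask 3-D array; non-zero entries are foreground.
#' @param voxelSize voxel size in µm, scalar or length-3 (x, y, z).
#' @return A [VoxelMask-class] object.
#' @export
voxelMask <- function(mask, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("VoxelMask", mask = mask, voxelSize = as.numeric(voxelSize))
}

#' Configuration of the curvotaxis random-walk simulator
#'
#' Parameters of the biased persistent random walk used to emulate time-lapse
#' migration data on sinusoidal landscapes; see [simulateCurvotaxis()] for the
#' model equations and the methods vignette for the rationale behind the
#' defaults.
#'
#' @slot spec the landscape, a [SinusoidSpec-class].
#' @slot nCells number of simulated cells.
#' @slot dt sampling interval (minutes).
#' @slot duration total simulated time (minutes).
#' @slot v0 base migration speed (µm/min).
#' @slot persistenceTau heading correlation time (minutes).
#' @slot chi curvotactic bias coefficient (µm/min per unit slope).
#' @slot lambdaSpeed dimensionless height-speed coupling; speed is
#'   v0*(1 + lambdaSpeed * ztilde) with ztilde the height normalized to [-1, 1].
#' @slot speedCV coefficient of variation of the multiplicative lognormal
#'   frame-to-frame speed fluctuation (cell motility is not metronomic).
#' @slot nucleusGain dimensionless in [0, 1]: fraction of the cell radius by
#'   which the nucleus is offset downhill from the centroid.
#' @slot nucleusNoise sd of the isotropic Gaussian jitter on the nucleus (µm).
#' @slot cellRadius bound on the nucleus offset (µm).
#' @slot extent numeric(2): simulation domain size (µm), reflecting borders.
#' @slot seed integer RNG seed; runs are bit-reproducible given the config.
#' @export
setClass("SimulationConfig",
  representation(spec = "SinusoidSpec", nCells = "integer", dt = "numeric",
                 duration = "numeric", v0 = "numeric",
                 persistenceTau = "numeric", chi = "numeric",
                 lambdaSpeed = "numeric", speedCV = "numeric",
                 nucleusGain = "numeric",
                 nucleusNoise = "numeric", cellRadius = "numeric",
                 extent = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@duration < object@dt) msg <- c(msg, "duration must be >= dt")
  if (object@v0 < 0) msg <- c(msg, "v0 must be >= 0")
  if (object@persistenceTau <= 0) msg <- c(msg, "persistenceTau must be > 0")
  if (abs(object@lambdaSpeed) >= 1)
    msg <- c(msg, "|lambdaSpeed| must be < 1 so speed stays positive")
  if (object@speedCV < 0) msg <- c(msg, "speedCV must be >= 0")
  if (object@nucleusGain < 0 || object@nucleusGain > 1)
    msg <- c(msg, "nucleusGain must lie in [0, 1]")
  if (object@nucleusNoise < 0) msg <- c(msg, "nucleusNoise must be >= 0")
  if (object@cellRadius <= 0) msg <- c(msg, "cellRadius must be > 0")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    msg <- c(msg, "extent must be two positive lengths (µm)")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe a responsive mesenchymal-like cell population on an
#' S10/100 landscape sampled every 10 minutes for 20 hours; see the methods
#' vignette for how each value was chosen.
#'
#' @param spec landscape [SinusoidSpec-class]; default S10/100 sum form.
#' @param nCells number of cells.
#' @param dt frame interval, minutes.
#' @param duration run length, minutes.
#' @param v0 base speed, µm/min.
#' @param persistenceTau heading persistence time, minutes.
#' @param chi curvotactic drift coefficient (µm/min per unit slope); 0 gives
#'   an unbiased persistent random walk.
#' @param lambdaSpeed height-speed coupling in (-1, 1).
#' @param speedCV frame-to-frame multiplicative speed variability
#'   (lognormal, mean 1), coefficient of variation.
#' @param nucleusGain nucleus downhill-offset gain in [0, 1].
#' @param nucleusNoise nucleus jitter sd, µm.
#' @param cellRadius cell radius bounding the nucleus offset, µm.
#' @param extent domain size (µm), default two period cells in each direction.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(spec = sinusoidSpec("sum", 2.5, 100),
                             nCells = 200, dt = 10, duration = 1200,
                             v0 = 0.3, persistenceTau = 3, chi = 0,
                             lambdaSpeed = 0, speedCV = 0.3, nucleusGain = 0,
                             nucleusNoise = 0.1, cellRadius = 15,
                             extent = NULL, seed = 1) {
  if (is.null(extent)) extent <- rep(2 * spec@period, 2L)
  if (length(extent) == 1L) extent <- rep(extent, 2L)
  new("SimulationConfig", spec = spec, nCells = as.integer(nCells),
      dt = as.numeric(dt), duration = as.numeric(duration),
      v0 = as.numeric(v0), persistenceTau = as.numeric(persistenceTau),
      chi = as.numeric(chi), lambdaSpeed = as.numeric(lambdaSpeed),
      speedCV = as.numeric(speedCV), nucleusGain = as.numeric(nucleusGain),
      nucleusNoise = as.numeric(nucleusNoise),
      cellRadius = as.numeric(cellRadius), extent = as.numeric(extent),
      seed = as.integer(seed))
}
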