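#' @include AllClasses.R AllGenerics.R
NULL

## ---- accessors ----

#' @rdname accessors
setMethod("heights", "HeightMap", function(x) x@heights)
#' @rdname accessors
setMethod("spacing", "HeightMap", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "CurvatureField", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "HeightBands", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BasinMap", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "HeightMap", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "CurvatureField", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "HeightBands", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "BasinMap", function(x) x@origin)
#' @rdname accessors
setMethod("bandEdges", "HeightBands", function(x) x@edges)
#' @rdname accessors
setMethod("bandArea", "HeightBands", function(x) x@bandArea)
#' @rdname accessors
setMethod("bandLabels", "HeightBands", function(x) x@labels)
#' @rdname accessors
setMethod("minima", "ExtremaSet", function(x) x@minima)
#' @rdname accessors
setMethod("minima", "BasinMap", function(x) x@minima@minima)
#' @rdname accessors
setMethod("maxima", "ExtremaSet", function(x) x@maxima)
#' @rdname accessors
setMethod("saddles", "ExtremaSet", function(x) x@saddles)
#' @rdname accessors
setMethod("basinLabels", "BasinMap", function(x) x@labels)
#' @rdname accessors
setMethod("meanH", "CurvatureField", function(x) x@meanH)
#' @rdname accessors
setMethod("gaussK", "CurvatureField", function(x) x@gaussK)
#' @rdname accessors
setMethod("principalCurvatures", "CurvatureField",
          function(x) list(kappa1 = x@kappa1, kappa2 = x@kappa2))

#' @rdname heightRange
setMethod("heightRange", "SinusoidSpec", function(x)
  if (x@form == "sum") 4 * x@amplitude else 2 * x@amplitude)

## ---- show methods ----

setMethod("show", "SinusoidSpec", function(object) {
  cat(sprintf("SinusoidSpec (%s form): amplitude %.4g µm, period %.4g µm\n",
              object@form, object@amplitude, object@period))
  cat(sprintf("  phases (%.3g, %.3g) rad, z offset %.4g µm, peak-to-valley %.4g µm\n",
              object@phaseX, object@phaseY, object@zOffset, heightRange(object)))
})

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@heights)
  cat(sprintf("HeightMap: %d x %d pixels, spacing (%.3g, %.3g) µm\n",
              d[2], d[1], object@spacing[1], object@spacing[2]))
  cat(sprintf("  extent %.4g x %.4g µm, z range [%.4g, %.4g] µm\n",
              d[2] * object@spacing[1], d[1] * object@spacing[2],
              min(object@heights), max(object@heights)))
})

setMethod("show", "CurvatureField", function(object) {
  d <- dim(object@meanH)
  cat(sprintf("CurvatureField: %d x %d pixels\n", d[2], d[1]))
  cat(sprintf("  mean curvature H in [%.4g, %.4g] µm^-1 (H>0 concave)\n",
              min(object@meanH), max(object@meanH)))
})

setMethod("show", "HeightBands", function(object) {
  n <- length(object@bandArea)
  cat(sprintf("HeightBands: %d bands (%s), band 1 lowest\n", n, object@mode))
  cat("  edges (µm):", paste(sprintf("%.3g", object@edges), collapse = ", "), "\n")
  cat("  area fractions:",
      paste(sprintf("%.3f", object@bandArea / sum(object@bandArea)), collapse = ", "), "\n")
})

setMethod("show", "ExtremaSet", function(object) {
  cat(sprintf("ExtremaSet: %d minima, %d maxima, %d saddles\n",
              nrow(object@minima), nrow(object@maxima), nrow(object@saddles)))
})

setMethod("show", "BasinMap", function(object) {
  cat(sprintf("BasinMap: %d basins over %d x %d pixels\n",
              nrow(object@minima@minima), dim(object@labels)[2],
              dim(object@labels)[1]))
})

setMethod("show", "MetrologyReport", function(object) {
  cat("MetrologyReport (product-form sinusoid fit)\n")
  cat(sprintf("  amplitude %.4g µm, period %.5g µm (lattice axis %.5g µm)\n",
              object@fittedAmplitude, object@fittedPeriod, object@latticePeriod))
  cat(sprintf("  axis orientation %.2f deg, shape residual %.4g µm, Sa %.4g µm\n",
              object@theta * 180 / pi, object@shapeResidual, object@sa))
  if (!object@converged) cat("  WARNING: fit flagged as not converged\n")
})

setMethod("show", "CurvotaxisTestResult", function(object) {
  cat(sprintf("CSR curvotaxis test: concave fraction %.3f (null %.3f ± %.3f)\n",
              object@concaveFractionObs, object@nullMean, object@nullSd))
  cat(sprintf("  one-sided p = %.4g (%d Monte-Carlo draws, n = %d, bands %s)\n",
              object@pValue, object@nMc, object@nTotal,
              paste(object@concaveBands, collapse = ",")))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VoxelMask: %d x %d x %d voxels of %.3g x %.3g x %.3g µm, %d foreground\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], sum(object@mask != 0)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d cells, dt %.3g min, duration %.4g min\n",
              object@nCells, object@dt, object@duration))
  cat(sprintf("  v0 %.3g µm/min, tau %.3g min, chi %.3g, lambda %.3g, gain %.3g\n",
              object@v0, object@persistenceTau, object@chi, object@lambdaSpeed,
              object@nucleusGain))
  cat(sprintf("  extent %.4g x %.4g µm, seed %d\n", object@extent[1],
              object@extent[2], object@seed))
})
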