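#' @include AllClasses.R utils.R
NULL

#' Sample an ideal sinusoidal landscape on a regular grid
#'
#' Generates the hills-and-valleys surface described by \code{spec} at pixel
#' centres over a rectangular extent. The sum form is
#' \eqn{z = B[\cos(2\pi x/P+\phi_x) + \cos(2\pi y/P+\phi_y)] + z_0}; the
#' product form \eqn{z = A\cos(2\pi x/P+\phi_x)\cos(2\pi y/P+\phi_y) + z_0}.
#'
#' @param spec a [SinusoidSpec-class].
#' @param extent field size in µm; scalar or length-2 (x, y). Must cover at
#'   least one period in each direction.
#' @param spacing pixel spacing in µm; scalar or length-2. Must resolve the
#'   period (\code{spacing <= period/10}); values at or beyond
#'   \code{period/2} alias and are rejected.
#' @param origin coordinates of the first pixel centre, µm.
#' @return A [HeightMap-class].
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), extent = 300, spacing = 1)
#' diff(range(heights(hm)))  # 10 µm peak-to-valley (S10/100)
#' @export
makeSurface <- function(spec, extent, spacing = 1, origin = c(0, 0)) {
  validObject(spec)
  if (length(extent) == 1L) extent <- rep(extent, 2L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  .stopIfNot(all(spacing > 0), "spacing must be positive")
  if (any(spacing >= spec@period / 2))
    stop("spacing ", paste(spacing, collapse = "x"), " µm aliases a period of ",
         spec@period, " µm (need spacing < period/2)", call. = FALSE)
  if (any(spacing > spec@period / 10))
    warning("spacing exceeds period/10; the surface is under-resolved")
  .stopIfNot(all(extent >= spec@period),
             "extent must cover at least one period in each direction")
  xs <- seq(origin[1], origin[1] + extent[1], by = spacing[1])
  ys <- seq(origin[2], origin[2] + extent[2], by = spacing[2])
  z <- outer(ys, xs, function(y, x) evalSinusoid(spec, x, y))
  heightMap(z, spacing = spacing, origin = origin)
}

#' Closed-form curvature of an ideal landscape at arbitrary points
#'
#' Mean curvature \eqn{H}, Gaussian curvature \eqn{K} and principal
#' curvatures \eqn{\kappa_1 \ge \kappa_2} of the graph \eqn{z = h(x,y)} from
#' exact partial derivatives:
#' \deqn{H = \frac{(1+h_y^2)h_{xx} - 2h_xh_yh_{xy} + (1+h_x^2)h_{yy}}
#'            {2(1+h_x^2+h_y^2)^{3/2}}, \quad
#'       K = \frac{h_{xx}h_{yy}-h_{xy}^2}{(1+h_x^2+h_y^2)^2}.}
#' With the upward normal used throughout, \eqn{H < 0} on convex hills and
#' \eqn{H > 0} in concave valleys.
#'
#' @param spec a [SinusoidSpec-class].
#' @param x,y point coordinates in µm (equal-length vectors).
#' @return data.frame with columns \code{x}, \code{y}, \code{H} (µm^-1),
#'   \code{K} (µm^-2), \code{kappa1}, \code{kappa2} (µm^-1).
#' @examples
#' s <- sinusoidSpec("sum", 2.5, 100)
#' analyticCurvature(s, 0, 0)$H         # -B(2*pi/P)^2 at the peak
#' 1 / abs(analyticCurvature(s, 0, 0)$H)  # curvature radius ~ 101.3 µm
#' @export
analyticCurvature <- function(spec, x, y) {
  validObject(spec)
  .stopIfNot(length(x) == length(y), "x and y must have equal length")
  cv <- .graphCurvature(.sinusoidDerivs(spec, x, y))
  data.frame(x = x, y = y, H = cv$H, K = cv$K,
             kappa1 = cv$kappa1, kappa2 = cv$kappa2)
}

## second-order accurate derivative stencils along columns (x) of a matrix
.d1cols <- function(m, h) {
  nc <- ncol(m)
  out <- (m[, c(2:nc, nc), drop = FALSE] - m[, c(1, 1:(nc - 1)), drop = FALSE]) / (2 * h)
  out[, 1] <- (-3 * m[, 1] + 4 * m[, 2] - m[, 3]) / (2 * h)
  out[, nc] <- (3 * m[, nc] - 4 * m[, nc - 1] + m[, nc - 2]) / (2 * h)
  out
}
.d2cols <- function(m, h) {
  nc <- ncol(m)
  out <- (m[, c(2:nc, nc), drop = FALSE] - 2 * m +
            m[, c(1, 1:(nc - 1)), drop = FALSE]) / h^2
  out[, 1] <- (2 * m[, 1] - 5 * m[, 2] + 4 * m[, 3] - m[, 4]) / h^2
  out[, nc] <- (2 * m[, nc] - 5 * m[, nc - 1] + 4 * m[, nc - 2] - m[, nc - 3]) / h^2
  out
}

#' Discrete curvature field of a sampled height map
#'
#' Central second-order finite differences estimate \eqn{h_x, h_y, h_{xx},
#' h_{yy}, h_{xy}} on the grid and are inserted into the graph-curvature
#' formulas of [analyticCurvature()]. Border pixels use one-sided
#' second-order stencils and are flagged (slot \code{interior}) as lower
#' accuracy.
#'
#' @param hm a [HeightMap-class] with at least a 4x4 grid.
#' @return A [CurvatureField-class].
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), 200, spacing = 2)
#' cf <- discreteCurvature(hm)
#' range(meanH(cf))
#' @export
discreteCurvature <- function(hm) {
  validObject(hm)
  z <- hm@heights
  .stopIfNot(nrow(z) >= 4 && ncol(z) >= 4, "grid must be at least 4x4")
  hx <- hm@spacing[1]; hy <- hm@spacing[2]
  zx <- .d1cols(z, hx)
  zy <- t(.d1cols(t(z), hy))
  d <- list(zx = zx, zy = zy,
            zxx = .d2cols(z, hx),
            zyy = t(.d2cols(t(z), hy)),
            zxy = t(.d1cols(t(zx), hy)))
  cv <- .graphCurvature(d)
  interior <- matrix(FALSE, nrow(z), ncol(z))
  interior[2:(nrow(z) - 1), 2:(ncol(z) - 1)] <- TRUE
  new("CurvatureField", meanH = cv$H, gaussK = cv$K, kappa1 = cv$kappa1,
      kappa2 = cv$kappa2, interior = interior, spacing = hm@spacing,
      origin = hm@origin)
}

#' Segment a height map into isoheight bands
#'
#' Splits the landscape into \code{nBands} areas delimited by isoheight
#' contour lines, band 1 the lowest (most concave). In \code{equal_height}
#' mode the band edges are evenly spaced between the minimum and maximum
#' height; in \code{equal_area} mode they are height quantiles so bands have
#' (nearly) equal projected area. Pixels are assigned by the half-open
#' interval \eqn{[e_i, e_{i+1})} with the top band closed.
#'
#' @param hm a [HeightMap-class] with non-zero height range.
#' @param nBands number of bands (default 5).
#' @param mode \code{"equal_height"} (default) or \code{"equal_area"}.
#' @param area \code{"projected"} (pixel count times pixel area, default) or
#'   \code{"surface"} (corrected by the local area element
#'   \eqn{\sqrt{1+|\nabla h|^2}}, for sensitivity checks).
#' @return A [HeightBands-class].
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), 300, spacing = 1)
#' hb <- segmentHeightBands(hm)
#' bandArea(hb) / sum(bandArea(hb))
#' @export
segmentHeightBands <- function(hm, nBands = 5,
                               mode = c("equal_height", "equal_area"),
                               area = c("projected", "surface")) {
  validObject(hm)
  mode <- match.arg(mode)
  area <- match.arg(area)
  z <- hm@heights
  rng <- range(z)
  if (diff(rng) <= 0)
    stop("height range is zero; a constant map cannot be banded", call. = FALSE)
  edges <- if (mode == "equal_height") {
    seq(rng[1], rng[2], length.out = nBands + 1)
  } else {
    e <- unname(stats::quantile(z, probs = seq(0, 1, length.out = nBands + 1),
                                type = 8))
    if (any(diff(e) <= 0))
      stop("equal_area edges are not strictly increasing (heights too discrete)",
           call. = FALSE)
    e
  }
  lab <- findInterval(z, edges, rightmost.closed = TRUE)
  lab <- matrix(pmin.int(pmax.int(lab, 1L), nBands), nrow(z), ncol(z))
  pixArea <- prod(hm@spacing)
  ba <- if (area == "projected") {
    tabulate(lab, nBands) * pixArea
  } else {
    zx <- .d1cols(z, hm@spacing[1])
    zy <- t(.d1cols(t(z), hm@spacing[2]))
    w <- sqrt(1 + zx^2 + zy^2) * pixArea
    as.numeric(tapply(w, factor(lab, levels = seq_len(nBands)), sum, default = 0))
  }
  bands <- new("HeightBands", edges = edges, labels = lab, bandArea = ba,
               mode = mode, spacing = hm@spacing, origin = hm@origin)
  if (area == "surface") return(bands)  # validity checks projected totals only
  validObject(bands)
  bands
}

## lattice of solutions of k*x + phase = target (mod 2*pi) within [lo, hi]
.phaseLattice <- function(period, phase, target, lo, hi) {
  k <- 2 * pi / period
  x0 <- (target - phase) / k
  mlo <- ceiling((lo - x0) / period - 1e-9)
  mhi <- floor((hi - x0) / period + 1e-9)
  if (mhi < mlo) return(numeric())
  x0 + (mlo:mhi) * period
}

#' Locate the critical points of an ideal landscape
#'
#' Solves \eqn{\nabla z = 0} in closed form. For the sum form, maxima sit
#' where both cosines equal +1, minima where both equal -1, and saddles
#' (cols) where the signs are mixed; the product form has the analogous
#' lattice with saddles at the zero crossings of both cosines.
#'
#' @param spec a [SinusoidSpec-class].
#' @param extent region to search, µm: length-2 \code{c(xmax, ymax)} (from 0)
#'   or length-4 \code{c(xmin, xmax, ymin, ymax)}.
#' @return An [ExtremaSet-class]. Amplitude 0 yields an empty set with a
#'   warning.
#' @examples
#' ex <- locateExtrema(sinusoidSpec("sum", 2.5, 100), c(200, 200))
#' minima(ex)  # (50,50), (150,50), (50,150), (150,150)
#' @export
locateExtrema <- function(spec, extent) {
  validObject(spec)
  if (length(extent) == 2L) extent <- c(0, extent[1], 0, extent[2])
  .stopIfNot(length(extent) == 4L, "extent must have length 2 or 4")
  emptyDf <- data.frame(x = numeric(), y = numeric(), z = numeric())
  if (spec@amplitude == 0) {
    warning("flat landscape (amplitude 0): no extrema")
    return(new("ExtremaSet", minima = emptyDf, maxima = emptyDf,
               saddles = emptyDf))
  }
  latt <- function(target, lo, hi, phase)
    .phaseLattice(spec@period, phase, target, lo, hi)
  cross <- function(xs, ys) {
    if (!length(xs) || !length(ys)) return(emptyDf)
    g <- expand.grid(x = xs, y = ys)
    g$z <- evalSinusoid(spec, g$x, g$y)
    g
  }
  xin <- function(t) latt(t, extent[1], extent[2], spec@phaseX)
  yin <- function(t) latt(t, extent[3], extent[4], spec@phaseY)
  if (spec@form == "sum") {
    maxi <- cross(xin(0), yin(0))
    mini <- cross(xin(pi), yin(pi))
    sdl <- rbind(cross(xin(0), yin(pi)), cross(xin(pi), yin(0)))
  } else {
    maxi <- rbind(cross(xin(0), yin(0)), cross(xin(pi), yin(pi)))
    mini <- rbind(cross(xin(0), yin(pi)), cross(xin(pi), yin(0)))
    sdl <- rbind(cross(xin(pi / 2), yin(pi / 2)),
                 cross(xin(pi / 2), yin(3 * pi / 2)),
                 cross(xin(3 * pi / 2), yin(pi / 2)),
                 cross(xin(3 * pi / 2), yin(3 * pi / 2)))
  }
  new("ExtremaSet", minima = mini, maxima = maxi, saddles = sdl)
}

#' Minimal curvature radius of an ideal landscape
#'
#' The tightest curvature radius \eqn{r_{min} = 1/\max|H|}, the quantity the
#' cell response follows logarithmically across amplitude series. For both
#' forms the maximum of \eqn{|H|} over the surface is attained at the peaks
#' and valleys, where \eqn{|H| = B(2\pi/P)^2} (sum form) resp.
#' \eqn{A(2\pi/P)^2} (product form); \code{method = "grid"} instead searches
#' a dense sample of one period cell, for maps where the closed form is in
#' doubt.
#'
#' @param spec a [SinusoidSpec-class].
#' @param method \code{"extremum"} (closed form at critical points, default)
#'   or \code{"grid"} (dense numerical supremum).
#' @param gridN grid resolution per period for \code{method = "grid"}.
#' @return list with \code{rMin} (µm), \code{H} (the signed mean curvature at
#'   the attaining point, µm^-1) and \code{location} (x, y of one attaining
#'   minimum). Amplitude 0 returns \code{rMin = Inf}.
#' @examples
#' curvatureRadiusExtremes(sinusoidSpec("sum", 2.5, 100))$rMin   # ~101.3
#' curvatureRadiusExtremes(sinusoidSpec("sum", 0.25, 100))$rMin  # ~1013
#' @export
curvatureRadiusExtremes <- function(spec, method = c("extremum", "grid"),
                                    gridN = 201) {
  validObject(spec)
  method <- match.arg(method)
  if (spec@amplitude == 0)
    return(list(rMin = Inf, H = 0, location = c(NA_real_, NA_real_)))
  k <- 2 * pi / spec@period
  if (method == "extremum") {
    Hmax <- spec@amplitude * k^2  # |h_xx + h_yy|/2 at critical points
    ex <- locateExtrema(spec, c(0, spec@period, 0, spec@period))
    loc <- unlist(ex@minima[1, c("x", "y")])
    list(rMin = 1 / Hmax, H = Hmax, location = loc)
  } else {
    xs <- seq(0, spec@period, length.out = gridN)
    g <- expand.grid(x = xs, y = xs)
    cv <- analyticCurvature(spec, g$x, g$y)
    i <- which.max(abs(cv$H))
    list(rMin = 1 / abs(cv$H[i]), H = cv$H[i],
         location = c(cv$x[i], cv$y[i]))
  }
}

#' Number of period unit cells tiling a patterned disc
#'
#' How many square unit cells of the sinusoidal lattice (one peak/valley
#' pair per cell) fit in the circular patterned area of a specimen: the disc
#' area divided by the cell area, rounded to the nearest integer. For the
#' 8-mm-diameter mask patterned at a 100 µm period this gives 5027.
#'
#' @param diameter patterned-disc diameter in µm.
#' @param period lattice axis period in µm.
#' @return Integer count of unit cells.
#' @examples
#' discUnitCellCount(8000, 100)  # 5027
#' @export
discUnitCellCount <- function(diameter, period) {
  .stopIfNot(diameter > 0 && period > 0, "diameter and period must be > 0")
  as.integer(round(pi * (diameter / 2)^2 / period^2))
}
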