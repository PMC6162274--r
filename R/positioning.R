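#' @include AllClasses.R utils.R
NULL

## points: data.frame with columns x, y (µm). Returns integer band labels,
## NA for points outside the grid.
.pointBands <- function(points, bands) {
  idx <- .pixelIndex(points$x, points$y, dim(bands@labels),
                     bands@spacing, bands@origin)
  out <- rep(NA_integer_, nrow(points))
  out[idx$inside] <- bands@labels[cbind(idx$row[idx$inside], idx$col[idx$inside])]
  out
}

#' Count nuclei per isoheight band
#'
#' Assigns each point (nucleus position) the band of its containing pixel
#' and tabulates counts, fractions and area-normalized densities. Points
#' outside the banded extent are excluded with a warning.
#'
#' @param points data.frame with columns \code{x}, \code{y} (µm) and
#'   optionally \code{label}.
#' @param bands a [HeightBands-class].
#' @return list with \code{counts}, \code{fractions}, \code{densities}
#'   (µm^-2), \code{nTotal} and \code{nExcluded}. An empty point set yields
#'   zero counts, a warning and no fractions (NA).
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), 200, spacing = 2)
#' hb <- segmentHeightBands(hm)
#' assignToBands(data.frame(x = 50, y = 50), hb)$counts  # the global minimum
#' @export
assignToBands <- function(points, bands) {
  .stopIfNot(is.data.frame(points) && all(c("x", "y") %in% names(points)),
             "points must be a data.frame with columns x and y")
  nBands <- length(bands@bandArea)
  if (nrow(points) == 0L) {
    warning("empty point set")
    return(list(counts = integer(nBands), fractions = rep(NA_real_, nBands),
                densities = rep(NA_real_, nBands), nTotal = 0L, nExcluded = 0L))
  }
  lab <- .pointBands(points, bands)
  nExcl <- sum(is.na(lab))
  if (nExcl > 0)
    warning(nExcl, " point(s) outside the banded extent were excluded")
  counts <- tabulate(lab[!is.na(lab)], nBands)
  nTot <- sum(counts)
  list(counts = counts,
       fractions = if (nTot > 0) counts / nTot else rep(NA_real_, nBands),
       densities = counts / bands@bandArea,
       nTotal = nTot, nExcluded = as.integer(nExcl))
}

#' Nuclei density on concave, flat and convex curvature classes
#'
#' Pixels are classed by mean curvature: concave where \eqn{H > \tau},
#' convex where \eqn{H < -\tau} and flat otherwise, with
#' \eqn{\tau = } \code{flatThreshold} \eqn{\times \max|H|}. Point densities
#' are counts per class area.
#'
#' @param points data.frame with columns \code{x}, \code{y} (µm).
#' @param cf a [CurvatureField-class] co-registered with the points.
#' @param flatThreshold fraction of \eqn{\max|H|} bounding the flat class
#'   (default 0.2).
#' @return list with per-class \code{counts}, \code{area} (µm^2) and
#'   \code{density} (µm^-2; NA where a class has zero area), in the order
#'   concave, flat, convex.
#' @export
densityByCurvatureClass <- function(points, cf, flatThreshold = 0.2) {
  .stopIfNot(is.data.frame(points) && all(c("x", "y") %in% names(points)),
             "points must be a data.frame with columns x and y")
  .stopIfNot(flatThreshold >= 0 && flatThreshold < 1,
             "flatThreshold must lie in [0, 1)")
  H <- cf@meanH
  tau <- flatThreshold * max(abs(H))
  cls <- matrix(2L, nrow(H), ncol(H))      # flat
  cls[H > tau] <- 1L                       # concave
  cls[H < -tau] <- 3L                      # convex
  pixArea <- prod(cf@spacing)
  area <- tabulate(cls, 3L) * pixArea
  idx <- .pixelIndex(points$x, points$y, dim(H), cf@spacing, cf@origin)
  if (any(!idx$inside))
    warning(sum(!idx$inside), " point(s) outside the field were excluded")
  pcls <- cls[cbind(idx$row[idx$inside], idx$col[idx$inside])]
  counts <- tabulate(pcls, 3L)
  dens <- ifelse(area > 0, counts / area, NA_real_)
  list(counts = stats::setNames(counts, c("concave", "flat", "convex")),
       area = stats::setNames(area, c("concave", "flat", "convex")),
       density = stats::setNames(dens, c("concave", "flat", "convex")))
}

#' Monte-Carlo complete-spatial-randomness test for concave enrichment
#'
#' Tests whether the observed fraction of points in the concave bands
#' exceeds what uniformly random placement over the banded extent would
#' give. The null draws \code{nTotal} uniform points \code{nMc} times; the
#' one-sided p-value is \eqn{(1 + \#\{null \ge obs\})/(nMc + 1)}.
#'
#' @param points data.frame with columns \code{x}, \code{y} (µm).
#' @param bands a [HeightBands-class] covering the points.
#' @param nMc number of Monte-Carlo draws (>= 99; default 999).
#' @param seed integer RNG seed.
#' @param concaveBands band indices counted as concave (default 1:2, the
#'   bottom 40 percent of the height range).
#' @return A [CurvotaxisTestResult-class].
#' @export
csrTest <- function(points, bands, nMc = 999, seed = 1, concaveBands = 1:2) {
  .stopIfNot(nMc >= 99, "nMc must be >= 99")
  dist <- assignToBands(points, bands)
  n <- dist$nTotal
  if (n < 1L) stop("no points inside the banded extent", call. = FALSE)
  obs <- sum(dist$fractions[concaveBands])
  d <- dim(bands@labels)
  ext <- d[c(2, 1)] * bands@spacing
  lo <- bands@origin - bands@spacing / 2
  conc <- matrix(bands@labels %in% concaveBands, d[1], d[2])
  set.seed(as.integer(seed))
  xs <- matrix(stats::runif(nMc * n, lo[1], lo[1] + ext[1]), nMc, n)
  ys <- matrix(stats::runif(nMc * n, lo[2], lo[2] + ext[2]), nMc, n)
  idx <- .pixelIndex(as.vector(xs), as.vector(ys), d, bands@spacing,
                     bands@origin)
  row <- pmin.int(pmax.int(idx$row, 1L), d[1])
  col <- pmin.int(pmax.int(idx$col, 1L), d[2])
  hit <- matrix(conc[cbind(row, col)], nMc, n)
  nullFrac <- rowMeans(hit)
  p <- (1 + sum(nullFrac >= obs)) / (nMc + 1)
  new("CurvotaxisTestResult", concaveFractionObs = obs,
      nullMean = mean(nullFrac), nullSd = stats::sd(nullFrac),
      pValue = p, nMc = as.integer(nMc), nTotal = as.integer(n),
      concaveBands = as.integer(concaveBands), seed = as.integer(seed))
}

#' Replicate-level one-sample t-test of concave fractions
#'
#' The experiment-level statistic used throughout the study: the concave
#' fraction of each independent replicate is compared to the area-expected
#' fraction by a two-sided one-sample Student's t-test.
#'
#' @param replicateFractions numeric vector of per-replicate concave
#'   fractions (>= 2 replicates).
#' @param nullFraction the concave area fraction expected under uniform
#'   placement.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean} and
#'   \code{degenerate} (TRUE when the replicates have zero variance, in
#'   which case t and p are NA).
#' @examples
#' replicateTTest(c(0.45, 0.50, 0.55), 0.20)$p  # < 0.05
#' @export
replicateTTest <- function(replicateFractions, nullFraction) {
  .stopIfNot(length(replicateFractions) >= 2,
             "need at least two replicates")
  m <- mean(replicateFractions)
  s <- stats::sd(replicateFractions)
  if (s == 0) {
    if (m == nullFraction)   # all equal to the null: t = 0, p = 1
      return(list(t = 0, df = length(replicateFractions) - 1L, p = 1,
                  mean = m, degenerate = FALSE))
    warning("zero variance across replicates: t is not finite")
    return(list(t = NA_real_, df = length(replicateFractions) - 1L,
                p = NA_real_, mean = m, degenerate = TRUE))
  }
  ht <- stats::t.test(replicateFractions, mu = nullFraction)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = m, degenerate = FALSE)
}

#' Logarithmic response-versus-curvature-radius regression
#'
#' Fits \eqn{y = a + b\ln(r)} by ordinary least squares, the relation
#' linking the cell response (percentage of cells on concave) to the
#' minimal curvature radius across a surface series; on amplitude series
#' the response falls with radius, i.e. \eqn{b < 0}.
#'
#' @param radius minimal curvature radii in µm (positive, >= 3 values).
#' @param response responses (e.g. percent of cells on concave).
#' @return list with \code{intercept}, \code{slope}, \code{rSquared} and the
#'   underlying \code{lm} fit.
#' @examples
#' r <- c(100, 300, 1000)
#' responseVsRadius(r, 10 - 2 * log(r))$slope  # -2
#' @export
responseVsRadius <- function(radius, response) {
  .stopIfNot(length(radius) == length(response), "lengths differ")
  .stopIfNot(length(radius) >= 3, "need at least 3 observations")
  if (any(radius <= 0)) stop("radii must be positive", call. = FALSE)
  fit <- stats::lm(response ~ log(radius))
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       rSquared = r2, fit = fit)
}
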