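#' @include AllClasses.R
NULL

## x/y coordinates of pixel centres
xCoords <- function(x) x@origin[1] + (seq_len(ncol(x@heights)) - 1) * x@spacing[1]
yCoords <- function(x) x@origin[2] + (seq_len(nrow(x@heights)) - 1) * x@spacing[2]

## nearest-pixel lookup for points on any grid-carrying object.
## Returns list(row, col, inside); pixel j covers centre +/- spacing/2.
.pixelIndex <- function(px, py, dimgrid, spacing, origin) {
  col <- floor((px - origin[1]) / spacing[1] + 0.5) + 1
  row <- floor((py - origin[2]) / spacing[2] + 0.5) + 1
  inside <- col >= 1 & col <= dimgrid[2] & row >= 1 & row <= dimgrid[1] &
    is.finite(px) & is.finite(py)
  list(row = row, col = col, inside = inside)
}

## Evaluate the ideal landscape and its derivatives at arbitrary points.
## Returns list(z, zx, zy, zxx, zyy, zxy); each the same shape as x.
.sinusoidDerivs <- function(spec, x, y) {
  k <- 2 * pi / spec@period
  ax <- k * x + spec@phaseX
  ay <- k * y + spec@phaseY
  if (spec@form == "sum") {
    B <- spec@amplitude
    list(z = B * (cos(ax) + cos(ay)) + spec@zOffset,
         zx = -B * k * sin(ax), zy = -B * k * sin(ay),
         zxx = -B * k^2 * cos(ax), zyy = -B * k^2 * cos(ay),
         zxy = 0 * ax)
  } else {
    A <- spec@amplitude
    list(z = A * cos(ax) * cos(ay) + spec@zOffset,
         zx = -A * k * sin(ax) * cos(ay), zy = -A * k * cos(ax) * sin(ay),
         zxx = -A * k^2 * cos(ax) * cos(ay),
         zyy = -A * k^2 * cos(ax) * cos(ay),
         zxy = A * k^2 * sin(ax) * sin(ay))
  }
}

#' Evaluate an ideal sinusoidal landscape at arbitrary points
#'
#' @param spec a [SinusoidSpec-class].
#' @param x,y coordinates in µm (vectors or matrices of equal shape).
#' @return Heights z(x, y) in µm, same shape as \code{x}.
#' @examples
#' s <- sinusoidSpec("sum", 2.5, 100)
#' evalSinusoid(s, 0, 0)    # global maximum, z = 5
#' evalSinusoid(s, 50, 50)  # global minimum, z = -5
#' @export
evalSinusoid <- function(spec, x, y) {
  validObject(spec)
  .sinusoidDerivs(spec, x, y)$z
}

#' Slope (gradient) of an ideal sinusoidal landscape
#'
#' @inheritParams evalSinusoid
#' @return list with components \code{zx}, \code{zy} (µm/µm).
#' @export
sinusoidGradient <- function(spec, x, y) {
  d <- .sinusoidDerivs(spec, x, y)
  list(zx = d$zx, zy = d$zy)
}

## curvature of a graph z = h(x,y) from its derivatives; upward normal, so
## H > 0 in concave valleys.
.graphCurvature <- function(d) {
  g2 <- 1 + d$zx^2 + d$zy^2
  H <- ((1 + d$zy^2) * d$zxx - 2 * d$zx * d$zy * d$zxy +
          (1 + d$zx^2) * d$zyy) / (2 * g2^1.5)
  K <- (d$zxx * d$zyy - d$zxy^2) / g2^2
  disc <- sqrt(pmax(H^2 - K, 0))
  list(H = H, K = K, kappa1 = H + disc, kappa2 = H - disc)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
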