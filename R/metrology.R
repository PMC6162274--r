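#' @include AllClasses.R utils.R surface.R
NULL

#' Rectify a height map by polynomial form removal
#'
#' Subtracts the least-squares polynomial of the given total degree in
#' \eqn{(x, y)} — degree 1 (a tilted plane) is the conventional first step of
#' areal metrology. The output has (numerically) zero mean for any
#' \code{degree >= 0}.
#'
#' @param hm a [HeightMap-class].
#' @param degree total polynomial degree (default 1).
#' @return A rectified [HeightMap-class].
#' @examples
#' z <- outer(0:20, 0:20, function(i, j) 0.5 + 0.02 * i - 0.03 * j)
#' max(abs(heights(rectify(heightMap(z)))))  # ~0: a plane rectifies to zero
#' @export
rectify <- function(hm, degree = 1) {
  validObject(hm)
  .stopIfNot(degree >= 0, "degree must be >= 0")
  z <- hm@heights
  if (diff(range(z)) == 0) {
    warning("constant map: rectification returns zeros")
    return(heightMap(z * 0, spacing = hm@spacing, origin = hm@origin))
  }
  xs <- xCoords(hm); ys <- yCoords(hm)
  # centred/scaled coordinates keep the normal equations well conditioned
  X <- matrix(rep(scale(xs, scale = max(abs(xs - mean(xs)))), each = nrow(z)),
              nrow(z), ncol(z))
  Y <- matrix(rep(scale(ys, scale = max(abs(ys - mean(ys)))), times = ncol(z)),
              nrow(z), ncol(z))
  terms <- list()
  for (d in 0:degree)
    for (i in 0:d) terms[[length(terms) + 1L]] <- as.vector(X^(d - i) * Y^i)
  M <- do.call(cbind, terms)
  .stopIfNot(length(z) >= ncol(M), "grid too small for the requested degree")
  fit <- stats::lm.fit(M, as.vector(z))
  heightMap(matrix(fit$residuals, nrow(z), ncol(z)),
            spacing = hm@spacing, origin = hm@origin)
}

#' Arithmetic mean deviation Sa of a height map
#'
#' The areal roughness parameter \eqn{S_a}: the mean absolute deviation of
#' heights from their mean. Meaningful as a roughness figure only after form
#' removal ([rectify()]) and high-pass filtering ([highpassSpline()]).
#'
#' @param hm a [HeightMap-class].
#' @return Sa in µm.
#' @examples
#' computeSa(heightMap(matrix(c(1, -1, 1, -1), 2, 2)))  # 1
#' @export
computeSa <- function(hm) {
  validObject(hm)
  z <- hm@heights
  mean(abs(z - mean(z)))
}

#' Amplitude transmission of the roughness high-pass filter
#'
#' The filter separates roughness from form with a fourth-order rational
#' transmission characteristic: the low-pass (reference surface) transmits
#' \eqn{1/(1+(\lambda_c/\lambda)^4)} of the amplitude at wavelength
#' \eqn{\lambda}, i.e. exactly 50\% at the cutoff and ~100\% for long
#' wavelengths; the high-pass (roughness) transmits the complement
#' \eqn{1/(1+(\lambda/\lambda_c)^4)}.
#'
#' @param wavelength wavelength(s) in µm.
#' @param cutoff cutoff wavelength in µm.
#' @param type \code{"highpass"} (roughness, default) or \code{"lowpass"}.
#' @return Amplitude transmission in [0, 1].
#' @examples
#' splineFilterTransmission(5, cutoff = 5)     # 0.5 at the cutoff
#' splineFilterTransmission(141.4, cutoff = 5) # ~0 for the sinusoid form
#' @export
splineFilterTransmission <- function(wavelength, cutoff,
                                     type = c("highpass", "lowpass")) {
  type <- match.arg(type)
  lp <- 1 / (1 + (cutoff / wavelength)^4)
  if (type == "lowpass") lp else 1 - lp
}

## mirror (symmetric) extension of a matrix to twice its size in each dim
.mirrorPad <- function(z) {
  z2 <- rbind(z, z[nrow(z):1, , drop = FALSE])
  cbind(z2, z2[, ncol(z2):1, drop = FALSE])
}

#' High-pass filter a height map at a roughness cutoff
#'
#' Computes the roughness map: input minus a long-wavelength smooth reference
#' surface obtained by a low-pass filter whose amplitude transmission is 50\%
#' at \code{cutoff} (see [splineFilterTransmission()] for the exact curve).
#' Implemented in the frequency domain on a mirror-extended grid, which
#' avoids wrap-around edge discontinuities.
#'
#' @param hm a [HeightMap-class]; spacing must satisfy
#'   \code{spacing < cutoff/2}.
#' @param cutoff cutoff wavelength in µm (default 5, the conventional
#'   nano-roughness cutoff for these landscapes).
#' @return A [HeightMap-class] holding the roughness (µm).
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), 200, spacing = 1)
#' computeSa(highpassSpline(hm, 5))  # ~0: the 141 µm form is rejected
#' @export
highpassSpline <- function(hm, cutoff = 5) {
  validObject(hm)
  .stopIfNot(cutoff > 0, "cutoff must be > 0")
  if (cutoff <= 2 * max(hm@spacing))
    stop("cutoff ", cutoff, " µm is not resolvable at spacing ",
         max(hm@spacing), " µm (need cutoff > 2*spacing)", call. = FALSE)
  z <- hm@heights
  mu <- mean(z)
  zp <- .mirrorPad(z - mu)
  n <- nrow(zp); m <- ncol(zp)
  fy <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * hm@spacing[2])
  fx <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / (m * hm@spacing[1])
  f <- sqrt(outer(fy^2, fx^2, `+`))
  hp <- 1 - 1 / (1 + (cutoff * f)^4)  # 0 at f=0, 0.5 at f=1/cutoff
  rough <- Re(stats::fft(stats::fft(zp) * hp, inverse = TRUE)) / (n * m)
  heightMap(rough[seq_len(nrow(z)), seq_len(ncol(z)), drop = FALSE],
            spacing = hm@spacing, origin = hm@origin)
}

## residual sum of squares of the two-plane-wave model with wave vectors
## packed in par = c(k1x, k1y, k2x, k2y); linear amplitudes profiled out.
.waveRss <- function(par, xv, yv, zv) {
  p1 <- par[1] * xv + par[2] * yv
  p2 <- par[3] * xv + par[4] * yv
  M <- cbind(1, xv, yv, cos(p1), sin(p1), cos(p2), sin(p2))
  cf <- tryCatch(qr.coef(qr(M), zv), error = function(e) NULL)
  if (is.null(cf) || anyNA(cf)) return(sum(zv^2))
  sum((zv - M %*% cf)^2)
}

## full product-form model evaluated from par =
## c(A, P, theta, phiU, phiV, offset, slopeX, slopeY); the degree-1 plane
## absorbs the tilt that rectification of a finite sinusoid patch leaves
## (the x-moment of a cosine over whole periods is not zero)
.productModel <- function(par, xv, yv) {
  k <- 2 * pi / par[2]
  u <- cos(par[3]) * xv + sin(par[3]) * yv
  v <- -sin(par[3]) * xv + cos(par[3]) * yv
  par[1] * cos(k * u + par[4]) * cos(k * v + par[5]) + par[6] +
    par[7] * xv + par[8] * yv
}

#' Fit the product-form sinusoid model to a measured height map
#'
#' Estimates the closest product-form sinusoid
#' \eqn{z = A\cos(2\pi u/P'+\phi_1)\cos(2\pi v/P'+\phi_2) + c}
#' (with \eqn{(u,v)} the in-plane axes at orientation \eqn{\theta}) by
#' nonlinear least squares, and reports the \dQuote{shape} statistic: the
#' standard deviation of the residual (measured minus fitted heights).
#'
#' The fit proceeds in three stages: (1) the two dominant spectral peaks of
#' the map initialize two plane-wave vectors; (2) the wave vectors are
#' refined with amplitudes/phases profiled out linearly (variable
#' projection); (3) the six product-form parameters are polished jointly,
#' with a multi-start over a phase grid as a fallback against local minima.
#' Because a sum-form lattice of axis period \eqn{P} equals a product form on
#' the 45-degree diagonals, the fitted period of such a surface is
#' \eqn{\sqrt{2}P} (e.g. ~141.4 µm for a 100 µm lattice) and the fitted
#' amplitude is twice the component amplitude (5 µm for S10/100).
#'
#' @param hm a [HeightMap-class], ideally rectified, covering at least two
#'   periods in each direction.
#' @param rectifyFirst subtract a degree-1 polynomial first (default TRUE).
#' @return A [MetrologyReport-class].
#' @examples
#' hm <- makeSurface(sinusoidSpec("sum", 2.5, 100), 300, spacing = 2)
#' rep <- fitSinusoid(hm)
#' c(rep@fittedAmplitude, rep@fittedPeriod)  # ~5, ~141.42
#' @export
fitSinusoid <- function(hm, rectifyFirst = TRUE) {
  validObject(hm)
  if (rectifyFirst) hm <- rectify(hm, 1)
  z <- hm@heights
  sa <- computeSa(hm)
  xs <- xCoords(hm); ys <- yCoords(hm)
  xv <- rep(xs, each = nrow(z)); yv <- rep(ys, times = ncol(z))
  zv <- as.vector(z)

  ## stage 1: two dominant, non-collinear spectral peaks
  F <- stats::fft(z - mean(z))
  n <- nrow(z); m <- ncol(z)
  fy <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * hm@spacing[2])
  fx <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / (m * hm@spacing[1])
  A2 <- Mod(F)
  keep <- outer(fy >= 0, rep(TRUE, m)) & outer(fy^2, fx^2, `+`) > 0
  ord <- order(A2[keep], decreasing = TRUE)
  kxAll <- 2 * pi * rep(fx, each = n)[keep][ord]
  kyAll <- 2 * pi * rep(fy, times = m)[keep][ord]
  k1 <- c(kxAll[1], kyAll[1])
  ang <- abs(kxAll * k1[2] - kyAll * k1[1]) /
    (sqrt(kxAll^2 + kyAll^2) * sqrt(sum(k1^2)))
  i2 <- which(ang > 0.5)[1]          # > 30 degrees off the first peak
  k2 <- if (is.na(i2)) c(-k1[2], k1[1]) else c(kxAll[i2], kyAll[i2])

  ## stage 2: variable-projection refinement of the wave vectors
  opt <- stats::optim(c(k1, k2), .waveRss, xv = xv, yv = yv, zv = zv,
                      method = "BFGS", control = list(maxit = 300, reltol = 1e-14))
  par <- opt$par
  p1 <- par[1] * xv + par[2] * yv; p2 <- par[3] * xv + par[4] * yv
  M <- cbind(1, xv, yv, cos(p1), sin(p1), cos(p2), sin(p2))
  cf <- qr.coef(qr(M), zv)
  B1 <- sqrt(cf[4]^2 + cf[5]^2); ps1 <- atan2(-cf[5], cf[4])
  B2 <- sqrt(cf[6]^2 + cf[7]^2); ps2 <- atan2(-cf[7], cf[6])

  ## convert the two waves to product-form parameters
  qu <- (par[1:2] + par[3:4]) / 2
  qv <- (par[1:2] - par[3:4]) / 2
  theta <- atan2(qu[2], qu[1])
  P <- 2 * pi / sqrt(sum(qu^2))
  start <- c(A = B1 + B2, P = P, theta = theta,
             phiU = (ps1 + ps2) / 2, phiV = (ps1 - ps2) / 2, c = cf[1],
             sx = cf[2], sy = cf[3])

  ## stage 3: joint polish with analytic gradient, multi-start over phases
  ## if the surface is badly non-ideal and the polish lands high
  obj <- function(p) sum((zv - .productModel(p, xv, yv))^2)
  grad <- function(p) {
    k <- 2 * pi / p[2]
    u <- cos(p[3]) * xv + sin(p[3]) * yv
    v <- -sin(p[3]) * xv + cos(p[3]) * yv
    c1 <- cos(k * u + p[4]); s1 <- sin(k * u + p[4])
    c2 <- cos(k * v + p[5]); s2 <- sin(k * v + p[5])
    r <- zv - (p[1] * c1 * c2 + p[6] + p[7] * xv + p[8] * yv)
    dA <- c1 * c2
    dk <- p[1] * (-u * s1 * c2 - v * c1 * s2)
    dP <- dk * (-2 * pi / p[2]^2)
    dth <- p[1] * k * (-v * s1 * c2 + u * c1 * s2)
    -2 * c(sum(r * dA), sum(r * dP), sum(r * dth),
           sum(r * (-p[1] * s1 * c2)), sum(r * (-p[1] * c1 * s2)),
           sum(r), sum(r * xv), sum(r * yv))
  }
  polish <- function(s0) stats::optim(s0, obj, grad, method = "BFGS",
                                      control = list(maxit = 1000,
                                                     reltol = 1e-16))
  best <- polish(start)
  ## a correct fit of a dominantly sinusoidal surface explains almost all
  ## variance; a phase/orientation local minimum leaves a large share of it
  tol <- max(1e-10, 0.02 * sum((zv - mean(zv))^2))
  tried <- 1L
  if (best$value > tol) {
    for (du in c(0, pi / 2, pi, 3 * pi / 2)) for (dv in c(0, pi / 2, pi, 3 * pi / 2)) {
      if (du == 0 && dv == 0) next
      s2 <- start; s2[4] <- s2[4] + du; s2[5] <- s2[5] + dv
      cand <- polish(s2)
      tried <- tried + 1L
      if (cand$value < best$value) best <- cand
      if (best$value <= tol) break
    }
  }
  p <- unname(best$par)
  if (p[1] < 0) { p[1] <- -p[1]; p[4] <- p[4] + pi }   # canonical A >= 0
  p[2] <- abs(p[2])
  resid <- zv - .productModel(p, xv, yv)
  shape <- stats::sd(resid)
  fitted <- sinusoidSpec("product", amplitude = p[1], period = p[2],
                         phaseX = p[4] %% (2 * pi), phaseY = p[5] %% (2 * pi),
                         zOffset = p[6])
  new("MetrologyReport", fittedSpec = fitted,
      theta = p[3] %% pi, shapeResidual = shape, sa = sa,
      fittedPeriod = p[2], latticePeriod = p[2] / sqrt(2),
      fittedAmplitude = p[1],
      converged = best$convergence == 0,
      diagnostics = list(rss = best$value, startsTried = tried,
                         waveRss = opt$value, stage1Waves = rbind(k1, k2),
                         plane = p[7:8]))
}

#' Full metrology report for a measured landscape
#'
#' Convenience wrapper reproducing the standard surface-quality workflow:
#' degree-1 rectification, product-form sinusoid fit (shape residual,
#' period, amplitude), then high-pass filtering of the fit residual at the
#' roughness cutoff and its Sa (the microroughness figure).
#'
#' The sinusoid form is fitted on a decimated copy of fine-pitched maps
#' (the form only needs the long wavelengths); the fitted model is then
#' evaluated and subtracted at full resolution, where the residual is
#' filtered and Sa measured.
#'
#' @param hm a [HeightMap-class].
#' @param cutoff roughness cutoff wavelength in µm (default 5).
#' @param fitMaxPixels decimate the map to at most this many pixels for the
#'   form fit (default 4e4).
#' @return list with the [MetrologyReport-class] (\code{$fit}) and the
#'   post-filter roughness figure \code{$saRoughness} (µm).
#' @export
metrologyReport <- function(hm, cutoff = 5, fitMaxPixels = 4e4) {
  rect <- rectify(hm, 1)
  stride <- max(1L, ceiling(sqrt(length(rect@heights) / fitMaxPixels)))
  fitIn <- if (stride > 1L) {
    heightMap(rect@heights[seq(1, nrow(rect@heights), by = stride),
                           seq(1, ncol(rect@heights), by = stride),
                           drop = FALSE],
              spacing = rect@spacing * stride, origin = rect@origin)
  } else rect
  rep <- fitSinusoid(fitIn, rectifyFirst = FALSE)
  xs <- xCoords(rect); ys <- yCoords(rect)
  xv <- rep(xs, each = nrow(rect@heights))
  yv <- rep(ys, times = ncol(rect@heights))
  p <- c(rep@fittedAmplitude, rep@fittedPeriod, rep@theta,
         rep@fittedSpec@phaseX, rep@fittedSpec@phaseY, rep@fittedSpec@zOffset,
         rep@diagnostics$plane)
  residMap <- heightMap(rect@heights -
                          matrix(.productModel(p, xv, yv),
                                 nrow(rect@heights), ncol(rect@heights)),
                        spacing = rect@spacing, origin = rect@origin)
  list(fit = rep, saRoughness = computeSa(highpassSpline(residMap, cutoff)))
}
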