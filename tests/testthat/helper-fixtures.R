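# Shared fixtures. Surface names follow the S<peak-to-valley>/<period>
# convention; the sum form carries component amplitude B = PV/4.
specPV <- function(pv, period, ...) {
  sinusoidSpec("sum", amplitude = pv / 4, period = period, ...)
}

s10_100 <- specPV(10, 100)

# height map sampled periodically (endpoint excluded), so that discrete
# symmetries of the lattice hold exactly on the sample set
periodicSurface <- function(spec, extent, spacing = 1) {
  xs <- seq(0, extent - spacing, by = spacing)
  z <- outer(xs, xs, function(y, x) evalSinusoid(spec, x, y))
  heightMap(z, spacing = spacing)
}

bandsS10 <- function(extent = 200, spacing = 1) {
  segmentHeightBands(makeSurface(s10_100, extent, spacing))
}
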