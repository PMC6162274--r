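#' @include AllClasses.R utils.R surface.R
NULL

#' Watershed basins of attraction of a height map
#'
#' Labels every pixel with the surface minimum its steepest-descent path
#' (8-connectivity, slope = drop divided by centre distance) terminates at.
#' Plateau ties are broken toward the neighbour with the smallest linear
#' pixel index; border pixels can only descend inward. For a sinusoidal
#' hills-and-valleys lattice the basin boundaries are the ridge lines through
#' the maxima and cols, i.e. the Voronoi diagram of the minima lattice.
#'
#' @param hm a non-constant [HeightMap-class].
#' @return A [BasinMap-class].
#' @export
basinMap <- function(hm) {
  validObject(hm)
  z <- hm@heights
  if (diff(range(z)) == 0)
    stop("constant map has no basins", call. = FALSE)
  n <- nrow(z); m <- ncol(z)
  sx <- hm@spacing[1]; sy <- hm@spacing[2]
  sd2 <- sqrt(sx^2 + sy^2)
  npix <- n * m
  parent <- seq_len(npix)
  bestDrop <- rep(0, npix)
  ri <- rep(seq_len(n), times = m)
  ci <- rep(seq_len(m), each = n)
  zv <- as.vector(z)
  ## neighbour offsets ordered by linear-index offset (smallest first) so
  ## that ties resolve to the smallest linear index under strict improvement
  offs <- list(c(-1L, -1L, sd2), c(0L, -1L, sx), c(1L, -1L, sd2),
               c(-1L, 0L, sy),                   c(1L, 0L, sy),
               c(-1L, 1L, sd2),  c(0L, 1L, sx),  c(1L, 1L, sd2))
  ord <- order(vapply(offs, function(o) o[1] + o[2] * n, numeric(1)))
  for (o in offs[ord]) {
    dr <- o[1]; dc <- o[2]; dist <- o[3]
    ok <- ri + dr >= 1L & ri + dr <= n & ci + dc >= 1L & ci + dc <= m
    nb <- (ci[ok] + dc - 1L) * n + (ri[ok] + dr)
    drop <- (zv[ok] - zv[nb]) / dist
    upd <- drop > bestDrop[ok]
    w <- which(ok)[upd]
    bestDrop[w] <- drop[which(upd)]
    parent[w] <- nb[upd]
  }
  ## path doubling to the fixed point (basin roots point to themselves)
  repeat {
    pp <- parent[parent]
    if (identical(pp, parent)) break
    parent <- pp
  }
  roots <- sort(unique(parent))
  lab <- matrix(match(parent, roots), n, m)
  rr <- (roots - 1L) %% n + 1L
  rc <- (roots - 1L) %/% n + 1L
  mins <- data.frame(x = hm@origin[1] + (rc - 1) * sx,
                     y = hm@origin[2] + (rr - 1) * sy,
                     z = zv[roots])
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric())
  new("BasinMap", labels = lab,
      minima = new("ExtremaSet", minima = mins, maxima = empty,
                   saddles = empty),
      spacing = hm@spacing, origin = hm@origin)
}

.checkTrack <- function(track) {
  .stopIfNot(is.data.frame(track) && all(c("t", "x", "y") %in% names(track)),
             "a track must be a data.frame with columns t, x, y")
  .stopIfNot(all(diff(track$t) > 0), "track times must be strictly increasing")
  .stopIfNot(all(is.finite(track$x)) && all(is.finite(track$y)),
             "track coordinates must be finite")
}

#' Mean migration speed per isoheight band
#'
#' Instantaneous speed of each track segment (in-plane displacement over the
#' frame interval) is attributed to the band containing the segment
#' midpoint, then summarized per band. Single-sample tracks contribute
#' nothing and are warned about.
#'
#' @param tracks list of track data.frames (columns \code{t} minutes,
#'   \code{x}, \code{y} µm), or a single data.frame with a \code{track_id}
#'   column.
#' @param bands a [HeightBands-class].
#' @return data.frame with one row per band: \code{band}, \code{meanSpeed},
#'   \code{sdSpeed} (µm/min) and \code{n} segments.
#' @export
speedByHeight <- function(tracks, bands) {
  tracks <- .asTrackList(tracks)
  .stopIfNot(length(tracks) > 0, "empty track list")
  segs <- lapply(tracks, function(tr) {
    .checkTrack(tr)
    if (nrow(tr) < 2L) {
      warning("single-sample track skipped")
      return(NULL)
    }
    i <- seq_len(nrow(tr) - 1L)
    data.frame(mx = (tr$x[i] + tr$x[i + 1L]) / 2,
               my = (tr$y[i] + tr$y[i + 1L]) / 2,
               speed = sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t))
  })
  segs <- do.call(rbind, segs)
  .stopIfNot(!is.null(segs) && nrow(segs) > 0, "no usable track segments")
  band <- .pointBands(data.frame(x = segs$mx, y = segs$my), bands)
  if (anyNA(band))
    warning(sum(is.na(band)), " segment midpoint(s) off the banded extent")
  nBands <- length(bands@bandArea)
  f <- factor(band, levels = seq_len(nBands))
  data.frame(band = seq_len(nBands),
             meanSpeed = as.numeric(tapply(segs$speed, f, mean)),
             sdSpeed = as.numeric(tapply(segs$speed, f, stats::sd)),
             n = as.integer(table(f)))
}

.asTrackList <- function(tracks) {
  if (is.data.frame(tracks)) {
    if ("track_id" %in% names(tracks))
      return(split(tracks, tracks$track_id))
    return(list(tracks))
  }
  tracks
}

#' Detect debounced valley-to-valley transitions of a track
#'
#' Maps each track sample to its watershed basin and emits one
#' [TransitionEvent]-style row per accepted basin change. The label sequence
#' is debounced: a new basin must persist for at least \code{minDwell}
#' consecutive frames to count, so brief boundary flickers during a
#' saltatory crossing are ignored. \code{tStart} is the last time the track
#' was seen in the source basin, \code{tEnd} the first frame of the accepted
#' destination dwell.
#'
#' @param track data.frame with columns \code{t}, \code{x}, \code{y}.
#' @param bm a [BasinMap-class]; off-map samples are excluded with a warning.
#' @param minDwell minimum persistent frames for a basin change (default 3).
#' @return data.frame with columns \code{tStart}, \code{tEnd},
#'   \code{fromBasin}, \code{toBasin} (zero rows when the track never
#'   changes basin).
#' @export
detectValleyTransitions <- function(track, bm, minDwell = 3) {
  .checkTrack(track)
  .stopIfNot(minDwell >= 1, "minDwell must be >= 1")
  idx <- .pixelIndex(track$x, track$y, dim(bm@labels), bm@spacing, bm@origin)
  if (any(!idx$inside)) {
    warning(sum(!idx$inside), " off-map sample(s) excluded")
    track <- track[idx$inside, , drop = FALSE]
    idx <- lapply(idx, `[`, which(idx$inside))
  }
  if (nrow(track) == 0L)
    return(data.frame(tStart = numeric(), tEnd = numeric(),
                      fromBasin = integer(), toBasin = integer()))
  lab <- bm@labels[cbind(idx$row, idx$col)]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  accepted <- which(r$lengths >= minDwell)
  ev <- list()
  if (length(accepted)) {
    cur <- r$values[accepted[1]]
    curEnd <- ends[accepted[1]]
    for (a in accepted[-1]) {
      if (r$values[a] != cur) {
        ## last time seen in the source basin before this dwell
        prior <- which(r$values[seq_len(a - 1L)] == cur)
        tS <- track$t[ends[prior[length(prior)]]]
        ev[[length(ev) + 1L]] <- data.frame(
          tStart = tS, tEnd = track$t[starts[a]],
          fromBasin = cur, toBasin = r$values[a])
      }
      cur <- r$values[a]
      curEnd <- ends[a]
    }
  }
  if (!length(ev))
    return(data.frame(tStart = numeric(), tEnd = numeric(),
                      fromBasin = integer(), toBasin = integer()))
  do.call(rbind, ev)
}

#' Distance from a track to the nearest surface minimum over time
#'
#' In-plane Euclidean distance from each track sample to the nearest
#' minimum; ties resolve to the smallest minimum index.
#'
#' @param track data.frame with columns \code{t}, \code{x}, \code{y}.
#' @param extrema an [ExtremaSet-class] with at least one minimum.
#' @return data.frame with columns \code{t}, \code{d} (µm) and
#'   \code{whichMin} (row index into \code{minima(extrema)}).
#' @export
distanceToNearestMinimum <- function(track, extrema) {
  .checkTrack(track)
  mins <- extrema@minima
  .stopIfNot(nrow(mins) >= 1, "extrema set contains no minima")
  d2 <- outer(track$x, mins$x, `-`)^2 + outer(track$y, mins$y, `-`)^2
  j <- apply(d2, 1L, which.min)
  data.frame(t = track$t, d = sqrt(d2[cbind(seq_len(nrow(track)), j)]),
             whichMin = j)
}

#' Alignment of the cell-nucleus vector with the direction to the minimum
#'
#' For each paired (cell centroid, nucleus) observation with nucleus offset
#' of at least \code{minOffset}, computes the cosine between the
#' centroid-to-nucleus vector and the centroid-to-nearest-minimum vector,
#' and averages it. A mean cosine near 1 means the nucleus leads the cell
#' toward the closest valley floor.
#'
#' @param pairs data.frame with columns \code{cx}, \code{cy} (centroid) and
#'   \code{x}, \code{y} (nucleus), µm.
#' @param extrema an [ExtremaSet-class] with at least one minimum.
#' @param minOffset minimum nucleus-centroid offset to use a pair (µm,
#'   default 0.5); pairs whose centroid sits exactly on a minimum are also
#'   skipped (direction undefined).
#' @return list with \code{meanCosine} (NA when no pair qualifies) and
#'   \code{nUsed}.
#' @export
nucleusOffsetAlignment <- function(pairs, extrema, minOffset = 0.5) {
  .stopIfNot(is.data.frame(pairs) &&
               all(c("cx", "cy", "x", "y") %in% names(pairs)),
             "pairs must have columns cx, cy, x, y")
  .stopIfNot(nrow(pairs) >= 1, "need at least one pair")
  mins <- extrema@minima
  .stopIfNot(nrow(mins) >= 1, "extrema set contains no minima")
  ox <- pairs$x - pairs$cx
  oy <- pairs$y - pairs$cy
  onorm <- sqrt(ox^2 + oy^2)
  d2 <- outer(pairs$cx, mins$x, `-`)^2 + outer(pairs$cy, mins$y, `-`)^2
  j <- apply(d2, 1L, which.min)
  vx <- mins$x[j] - pairs$cx
  vy <- mins$y[j] - pairs$cy
  vnorm <- sqrt(vx^2 + vy^2)
  use <- onorm >= minOffset & vnorm > 0
  if (!any(use)) return(list(meanCosine = NA_real_, nUsed = 0L))
  cosv <- (ox[use] * vx[use] + oy[use] * vy[use]) / (onorm[use] * vnorm[use])
  list(meanCosine = mean(cosv), nUsed = as.integer(sum(use)))
}
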