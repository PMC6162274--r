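#' @include AllClasses.R utils.R
NULL

## separable Gaussian smoothing of a 3-D array, sigma in voxels per axis.
## Reflective borders via padded convolution with a truncated kernel.
.gauss3d <- function(a, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    d <- dim(a)
    n <- d[axis]
    idx <- c(pmin.int(pmax.int(seq(1 - r, 0), 1L), n),  # reflect-clamp pad
             seq_len(n),
             pmin.int(pmax.int(seq(n + 1, n + r), 1L), n))
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap[idx, , ], n + 2L * r, dp[2] * dp[3])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * m[seq_len(n) + (i - 1L), , drop = FALSE]
    ap <- array(out, dp)
    a <- aperm(ap, order(perm))
  }
  a
}

## Total area of the 0.5 iso-surface of field F (3-D array) with vertex
## spacing vx, vy, vz, by marching tetrahedra: each lattice cube is split
## into 6 tetrahedra around its main diagonal and the linear iso-surface
## inside each tetrahedron (a triangle or a quad) is accumulated.
.marchingTetraArea <- function(F, voxel, iso = 0.5) {
  d <- dim(F)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ## corner index arrays for all cubes, linear indices into F
  ix <- seq_len(nx - 1L); iy <- seq_len(ny - 1L); iz <- seq_len(nz - 1L)
  lin <- function(dx, dy, dz) {
    as.vector(outer(outer(ix + dx, (iy + dy - 1L) * nx, `+`),
                    (iz + dz - 1L) * nx * ny, `+`))
  }
  ## cube vertex numbering: v0=(0,0,0) v1=(1,0,0) v2=(1,1,0) v3=(0,1,0)
  ##                        v4=(0,0,1) v5=(1,0,1) v6=(1,1,1) v7=(0,1,1)
  corner <- list(lin(0, 0, 0), lin(1, 0, 0), lin(1, 1, 0), lin(0, 1, 0),
                 lin(0, 0, 1), lin(1, 0, 1), lin(1, 1, 1), lin(0, 1, 1))
  cpos <- list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  ## 6-tetrahedron decomposition around diagonal v0-v6
  tets <- list(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  ## cube base coordinates (of v0), in physical units
  bx <- (as.vector(outer(outer(ix, iy * 0, `+`), iz * 0, `+`)) - 1) * voxel[1]
  by <- (as.vector(outer(outer(ix * 0, iy, `+`), iz * 0, `+`)) - 1) * voxel[2]
  bz <- (as.vector(outer(outer(ix * 0, iy * 0, `+`), iz, `+`)) - 1) * voxel[3]

  triArea <- function(p1, p2, p3) {
    ux <- p2[, 1] - p1[, 1]; uy <- p2[, 2] - p1[, 2]; uz <- p2[, 3] - p1[, 3]
    vx <- p3[, 1] - p1[, 1]; vy <- p3[, 2] - p1[, 2]; vz <- p3[, 3] - p1[, 3]
    cx <- uy * vz - uz * vy; cy <- uz * vx - ux * vz; cz <- ux * vy - uy * vx
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  area <- 0
  for (tet in tets) {
    f <- cbind(F[corner[[tet[1]]]], F[corner[[tet[2]]]],
               F[corner[[tet[3]]]], F[corner[[tet[4]]]])
    inside <- f > iso
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    active <- which(code > 0L & code < 15L)
    if (!length(active)) next
    fA <- f[active, , drop = FALSE]
    codeA <- code[active]
    ## physical coordinates of the 4 tetra vertices for active cubes
    vcoord <- lapply(tet, function(v) {
      cbind(bx[active] + cpos[[v]][1] * voxel[1],
            by[active] + cpos[[v]][2] * voxel[2],
            bz[active] + cpos[[v]][3] * voxel[3])
    })
    edgePt <- function(a, b, rows) {
      t <- (iso - fA[rows, a]) / (fA[rows, b] - fA[rows, a])
      vcoord[[a]][rows, , drop = FALSE] +
        t * (vcoord[[b]][rows, , drop = FALSE] - vcoord[[a]][rows, , drop = FALSE])
    }
    for (cd in sort(unique(codeA))) {
      rows <- which(codeA == cd)
      ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      if (length(ins) == 1L || length(ins) == 3L) {
        a <- if (length(ins) == 1L) ins else outs
        others <- setdiff(1:4, a)
        p1 <- edgePt(a, others[1], rows)
        p2 <- edgePt(a, others[2], rows)
        p3 <- edgePt(a, others[3], rows)
        area <- area + sum(triArea(p1, p2, p3))
      } else {  # 2 in / 2 out: quad (a1c1, a1c2, a2c2, a2c1)
        a1 <- ins[1]; a2 <- ins[2]; c1 <- outs[1]; c2 <- outs[2]
        q1 <- edgePt(a1, c1, rows); q2 <- edgePt(a1, c2, rows)
        q3 <- edgePt(a2, c2, rows); q4 <- edgePt(a2, c1, rows)
        area <- area + sum(triArea(q1, q2, q3)) + sum(triArea(q1, q3, q4))
      }
    }
  }
  area
}

#' Volume, surface area and sphericity of a voxelized nucleus
#'
#' Volume is the foreground voxel count times the voxel volume. Surface area
#' is measured on an iso-surface mesh: the binary mask is mollified with a
#' small Gaussian (in index space) and the 0.5 level surface is triangulated
#' by marching tetrahedra — voxel-face counting would systematically
#' overestimate the area and depress sphericity. Sphericity is the
#' isoperimetric ratio \eqn{\Psi = \pi^{1/3}(6V)^{2/3}/A} (1 for a perfect
#' sphere).
#'
#' @param mask a [VoxelMask-class]; anisotropic voxels are supported. A mask
#'   with more than one connected foreground component is accepted with a
#'   warning (checked along faces).
#' @param smoothSigma mollifier sd in voxels (default 1.2); 0 gives the raw
#'   staircase mesh.
#' @return list with \code{volume} (µm^3), \code{surfaceArea} (µm^2) and
#'   \code{sphericity}.
#' @examples
#' r <- 8
#' g <- seq(-r - 2, r + 2)
#' m <- outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2
#' shapeFromMask(voxelMask(m, 1))$sphericity  # close to 1
#' @export
shapeFromMask <- function(mask, smoothSigma = 1.2) {
  validObject(mask)
  m <- mask@mask != 0
  .stopIfNot(sum(m) > 0, "empty mask")
  if (.nComponents(m) > 1L)
    warning("mask has more than one connected component")
  vol <- sum(m) * prod(mask@voxelSize)
  ## pad with background so the iso-surface closes, then mollify
  d <- dim(m)
  pad <- 3L
  F <- array(0, d + 2L * pad)
  F[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  F <- .gauss3d(F, rep(smoothSigma, 3L))
  area <- .marchingTetraArea(F, mask@voxelSize)
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  list(volume = vol, surfaceArea = area, sphericity = sph)
}

## 6-connectivity component count via flood fill on the foreground
.nComponents <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(m)
  for (s in idx) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer()
      i <- (p - 1L) %% d[1] + 1L
      j <- ((p - 1L) %/% d[1]) %% d[2] + 1L
      k <- (p - 1L) %/% (d[1] * d[2]) + 1L
      for (o in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                     c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] &
          kk >= 1L & kk <= d[3]
        q <- (kk[ok] - 1L) * d[1] * d[2] + (jj[ok] - 1L) * d[1] + ii[ok]
        q <- q[m[q] & lab[q] == 0L]
        lab[q] <- cur
        queue <- c(queue, q)
      }
      queue <- unique(queue)
    }
  }
  cur
}

#' Compare nuclear shape between two groups
#'
#' Welch two-sample t-tests of sphericity and volume between two groups of
#' shape records (e.g. nuclei from cells on concave versus flat substrata).
#'
#' @param groupA,groupB lists of records as returned by [shapeFromMask()],
#'   or data.frames with columns \code{sphericity} and \code{volume};
#'   at least 2 records per group.
#' @return list with one entry per metric (\code{sphericity},
#'   \code{volume}), each holding \code{meanA}, \code{meanB}, \code{t},
#'   \code{df}, \code{p}.
#' @export
compareShapeGroups <- function(groupA, groupB) {
  asDf <- function(g) {
    if (is.data.frame(g)) return(g)
    do.call(rbind, lapply(g, function(r)
      data.frame(volume = r$volume, sphericity = r$sphericity)))
  }
  a <- asDf(groupA); b <- asDf(groupB)
  .stopIfNot(nrow(a) >= 2 && nrow(b) >= 2,
             "need at least 2 records per group")
  one <- function(metric) {
    va <- a[[metric]]; vb <- b[[metric]]
    if (stats::sd(c(va, vb)) == 0)
      return(list(meanA = mean(va), meanB = mean(vb), t = 0,
                  df = length(va) + length(vb) - 2, p = 1))
    ht <- stats::t.test(va, vb)
    list(meanA = mean(va), meanB = mean(vb), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
  }
  list(sphericity = one("sphericity"), volume = one("volume"))
}
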