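# Low-level voxel helpers shared by the generator and the geometry module.
# Conventions: 1-based array indices; physical voxel centers at
# (index - 0.5) * spacing um; 'coords' are n x 3 integer index matrices.

voxelCenters <- function(idx, spacing) {
    idx <- rbind(idx)
    cbind((idx[, 1] - 0.5) * spacing[1],
          (idx[, 2] - 0.5) * spacing[2],
          (idx[, 3] - 0.5) * spacing[3])
}

# Containing voxel of physical points (n x 3 um matrix); errors when outside.
pointToVoxel <- function(points, spacing, volumeDim) {
    points <- rbind(points)
    idx <- floor(sweep(points, 2L, spacing, "/")) + 1L
    # a point exactly on the far face belongs to the last voxel
    for (j in 1:3) idx[, j] <- pmin(idx[, j], volumeDim[j])
    if (any(idx < 1L) || any(sweep(idx, 2L, volumeDim, ">")))
        stop("point outside volume bounds")
    storage.mode(idx) <- "integer"
    idx
}

# Shift a 3D logical/integer array by one voxel along an axis, padding
# with 'fill'. Used for face-exposure counting.
shiftArray <- function(a, axis, by, fill = FALSE) {
    d <- dim(a)
    out <- array(fill, dim = d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (by > 0) {
        dst[[axis]] <- (by + 1):d[axis]
        src[[axis]] <- 1:(d[axis] - by)
    } else {
        dst[[axis]] <- 1:(d[axis] + by)
        src[[axis]] <- (1 - by):d[axis]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

# Rasterize a sphere; returns n x 3 integer coords of voxels whose centers
# fall within 'radius' um of 'center' (um). Restricted to the volume.
rasterizeSphere <- function(center, radius, spacing, volumeDim) {
    lo <- pmax(floor((center - radius) / spacing), 0) + 1
    hi <- pmin(ceiling((center + radius) / spacing), volumeDim)
    if (any(lo > hi)) return(matrix(integer(), 0, 3))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- (ix - 0.5) * spacing[1] - center[1]
    cy <- (iy - 0.5) * spacing[2] - center[2]
    cz <- (iz - 0.5) * spacing[3] - center[3]
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    keep <- which(d2 <= radius^2, arr.ind = TRUE)
    if (!nrow(keep)) return(matrix(integer(), 0, 3))
    cbind(ix[keep[, 1]], iy[keep[, 2]], iz[keep[, 3]])
}

# Rasterize a capsule (segment p0-p1 dilated by 'radius'); coords as above.
rasterizeCapsule <- function(p0, p1, radius, spacing, volumeDim) {
    lo <- pmax(floor((pmin(p0, p1) - radius) / spacing), 0) + 1
    hi <- pmin(ceiling((pmax(p0, p1) + radius) / spacing), volumeDim)
    if (any(lo > hi)) return(matrix(integer(), 0, 3))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    grid <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    pts <- voxelCenters(grid, spacing)
    v <- p1 - p0
    vv <- sum(v^2)
    if (vv == 0) {
        d2 <- rowSums(sweep(pts, 2L, p0)^2)
    } else {
        t <- pmin(pmax(as.vector(sweep(pts, 2L, p0) %*% v) / vv, 0), 1)
        proj <- outer(t, v) + rep(p0, each = nrow(pts))
        d2 <- rowSums((pts - proj)^2)
    }
    grid[d2 <= radius^2, , drop = FALSE]
}

setVoxels <- function(a, coords, value) {
    if (nrow(coords)) {
        a[coords[, 1] + dim(a)[1] * (coords[, 2] - 1) +
          dim(a)[1] * dim(a)[2] * (coords[, 3] - 1)] <- value
    }
    a
}

getVoxels <- function(a, coords) {
    a[coords[, 1] + dim(a)[1] * (coords[, 2] - 1) +
      dim(a)[1] * dim(a)[2] * (coords[, 3] - 1)]
}

linearIndex <- function(coords, d) {
    coords[, 1] + d[1] * (coords[, 2] - 1) + d[1] * d[2] * (coords[, 3] - 1)
}

# Nearest-point kernel: for query rows q, min_j |q - ref_j|^2 equals
# qn2 - 2 * max_j (q.ref_j - rn2_j / 2). Augmenting q with a 1-column and
# ref with -rn2/2 turns that inner maximand into a single GEMM, and max.col
# finds the argmax, so the whole search runs in compiled code.
.nearestKernel <- function(qAug, refAug, rn2) {
    A <- tcrossprod(qAug, refAug)
    j <- max.col(A, ties.method = "first")
    n <- nrow(qAug)
    d2 <- rowSums(qAug[, 1:3, drop = FALSE]^2) - 2 * A[cbind(seq_len(n), j)]
    list(d2 = pmax(d2, 0), idx = j)
}

.nearestChunked <- function(query, ref, chunk) {
    query <- rbind(query)
    ref <- rbind(ref)
    rn2 <- ref[, 1]^2 + ref[, 2]^2 + ref[, 3]^2
    refAug <- cbind(ref, -rn2 / 2)
    qAug <- cbind(query, 1)
    n <- nrow(query)
    d2 <- numeric(n)
    idx <- integer(n)
    i <- 1L
    while (i <= n) {
        j <- min(i + chunk - 1L, n)
        k <- .nearestKernel(qAug[i:j, , drop = FALSE], refAug, rn2)
        d2[i:j] <- k$d2
        idx[i:j] <- k$idx
        i <- j + 1L
    }
    list(d2 = d2, idx = idx)
}

# Minimum Euclidean distance from each query point (um) to a reference point
# set (um), chunked so BLAS does the heavy lifting. +Inf for an empty set.
minDistToSet <- function(query, ref, chunk = 4096L) {
    query <- rbind(query)
    if (is.null(ref) || nrow(rbind(ref)) == 0L)
        return(rep(Inf, nrow(query)))
    sqrt(.nearestChunked(query, ref, chunk)$d2)
}

# Index of the nearest reference point for each query point.
nearestInSet <- function(query, ref, chunk = 4096L) {
    .nearestChunked(query, ref, chunk)$idx
}

# Exact nearest distance accelerated by a bounding-box prefilter: reference
# points outside the query bbox expanded by 'pad' are at least 'pad' away,
# so the filtered answer is exact whenever it is <= pad; other rows are
# recomputed against the full set.
minDistPrefiltered <- function(query, ref, pad = 12) {
    query <- rbind(query)
    if (is.null(ref) || nrow(rbind(ref)) == 0L)
        return(rep(Inf, nrow(query)))
    ref <- rbind(ref)
    lo <- apply(query, 2L, min) - pad
    hi <- apply(query, 2L, max) + pad
    sel <- ref[, 1] >= lo[1] & ref[, 1] <= hi[1] &
           ref[, 2] >= lo[2] & ref[, 2] <= hi[2] &
           ref[, 3] >= lo[3] & ref[, 3] <= hi[3]
    if (!any(sel)) return(minDistToSet(query, ref))
    d <- minDistToSet(query, ref[sel, , drop = FALSE])
    bad <- d > pad
    if (any(bad))
        d[bad] <- minDistToSet(query[bad, , drop = FALSE], ref)
    d
}

# Boundary voxels of a mask: mask voxels with >= 1 of their 6 faces exposed
# to background (the volume border counts as background). Returns coords plus
# per-axis positive/negative exposure flags.
maskBoundary <- function(mask) {
    stopifnot(length(dim(mask)) == 3L)
    exposure <- vector("list", 6L)
    k <- 1L
    for (axis in 1:3) {
        for (by in c(1L, -1L)) {
            nb <- shiftArray(mask, axis, by, fill = FALSE)
            exposure[[k]] <- mask & !nb
            k <- k + 1L
        }
    }
    any_exposed <- exposure[[1]]
    for (k in 2:6) any_exposed <- any_exposed | exposure[[k]]
    coords <- which(any_exposed, arr.ind = TRUE)
    colnames(coords) <- NULL
    flags <- vapply(exposure, function(e) getVoxels(e, coords), logical(nrow(coords)))
    if (nrow(coords) == 1L) flags <- matrix(flags, nrow = 1L)
    list(coords = coords, flags = flags)
}

# Area weights for boundary voxels: magnitude of the net signed exposed-face
# vector plus the full area of cancelling (opposite) face pairs. Matches the
# closed-box area for an isolated voxel and tracks smooth-surface area
# without L1 staircase inflation.
boundaryAreaWeights <- function(flags, spacing) {
    faceArea <- c(spacing[2] * spacing[3],   # x faces
                  spacing[1] * spacing[3],   # y faces
                  spacing[1] * spacing[2])   # z faces
    net <- matrix(0, nrow(flags), 3L)
    cancel <- numeric(nrow(flags))
    for (axis in 1:3) {
        p <- flags[, 2 * axis - 1]
        m <- flags[, 2 * axis]
        net[, axis] <- abs(as.numeric(p) - as.numeric(m)) * faceArea[axis]
        cancel <- cancel + 2 * pmin(as.numeric(p), as.numeric(m)) * faceArea[axis]
    }
    sqrt(rowSums(net^2)) + cancel
}
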