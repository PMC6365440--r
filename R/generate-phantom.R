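# Synthetic islet phantom generator. Emits labeled voxel volumes matching
# the two-photon imaging geometry (0.994 um xy, 3 um z) with a connected
# piecewise-cylindrical vessel lumen inside a spherical islet, perivascular
# CD11c blobs placed until the realized contact-zone fraction hits the
# preset target, and T-cell instances placed to preset in-zone /
# direct-contact / extravascular probabilities. Ground truth is re-measured
# on the emitted volume with the geometry and enrichment modules, never
# copied from the preset.

# Outward wall normal at a surface voxel: direction from the local lumen
# centroid (within ~4 um) to the voxel center.
outwardNormal <- function(surfVoxel, lumenMask, spacing) {
    d <- dim(lumenMask)
    rad <- pmax(ceiling(4 / spacing), 1)
    lo <- pmax(surfVoxel - rad, 1L)
    hi <- pmin(surfVoxel + rad, d)
    sub <- lumenMask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    idx <- which(sub, arr.ind = TRUE)
    idx <- sweep(idx, 2L, lo - 1L, "+")
    ctr <- colMeans(voxelCenters(idx, spacing))
    v <- voxelCenters(rbind(surfVoxel), spacing)[1, ] - ctr
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) c(1, 0, 0) else v / nv
}

randomUnit <- function() {
    repeat {
        v <- stats::rnorm(3)
        n <- sqrt(sum(v^2))
        if (n > 1e-6) return(v / n)
    }
}

# Random-walk capsule chain for the vessel centerline, kept inside a sphere
# of radius 'rmax' around 'center'.
vesselCenterline <- function(center, rmax, nSegments, segLength) {
    p0 <- center + randomUnit() * stats::runif(1, 0, 0.3 * rmax)
    dir <- randomUnit()
    pts <- matrix(0, nSegments + 1L, 3L)
    pts[1L, ] <- p0
    for (i in seq_len(nSegments)) {
        for (try in 1:100) {
            cand_dir <- dir + 0.6 * randomUnit()
            cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
            cand <- pts[i, ] + cand_dir * segLength
            if (sqrt(sum((cand - center)^2)) <= rmax) break
            # pull back toward the islet center when about to exit
            dir <- (center - pts[i, ]) / sqrt(sum((center - pts[i, ])^2))
        }
        if (sqrt(sum((cand - center)^2)) > rmax)
            cand <- pts[i, ] + dir * segLength
        pts[i + 1L, ] <- cand
        dir <- (pts[i + 1L, ] - pts[i, ]) / segLength
    }
    pts
}

#' Generate a labeled 3D islet phantom
#'
#' Builds the synthetic scene every downstream module consumes: a spherical
#' islet containing a connected tubular vessel lumen, perivascular CD11c
#' blobs added one at a time until the realized area-weighted contact-zone
#' fraction lies within +-0.01 of the preset target, and T-cell instances
#' placed intravascularly (wall-adherent, biased into contact zones and into
#' direct CD11c contact per the preset probabilities) or in the parenchyma.
#' Every placement is verified against the same measurement rules the
#' analysis modules use (centroid signed distance, nearest-surface-voxel
#' zone membership, voxel surface-to-surface contact distance), so the
#' emitted ground truth is a re-measurement, not a copy of the preset.
#'
#' @param preset a [geometryPreset()] bundle.
#' @param n_tcells override for the T-cell count (default derived from
#'   \code{infiltration_fraction} as \code{f * (R_islet / r_tcell)^3}).
#' @param deltaZ contact-zone distance threshold, um (default 1.5).
#' @param deltaC direct-contact distance threshold, um (default 1.0).
#' @return list with \code{phantom} ([IsletPhantom-class]), \code{surface},
#'   \code{zone_map}, and \code{ground_truth} (list of realized zone
#'   fraction, in-zone fraction, direct-contact fraction, extravascular
#'   fraction, per-cell intent table, counts, seed).
#' @export
generateIsletPhantom <- function(preset, n_tcells = NULL,
                                 deltaZ = 1.5, deltaC = 1.0) {
    stopifnot(inherits(preset, "GeometryPreset"))
    validateGeometryPreset(preset)
    withr::with_seed(preset$seed, {
        .generatePhantomImpl(preset, n_tcells, deltaZ, deltaC)
    })
}

.generatePhantomImpl <- function(preset, n_tcells, deltaZ, deltaC) {
    sp <- preset$spacing
    R <- preset$islet_radius
    extent <- rep(2 * (R + 2), 3L)
    d <- as.integer(ceiling(extent / sp))
    center <- d * sp / 2

    # islet sphere
    cx <- ((seq_len(d[1]) - 0.5) * sp[1] - center[1])^2
    cy <- ((seq_len(d[2]) - 0.5) * sp[2] - center[2])^2
    cz <- ((seq_len(d[3]) - 0.5) * sp[3] - center[3])^2
    isletMask <- outer(outer(cx, cy, "+"), cz, "+") <= R^2

    # connected tubular lumen
    rmax <- R - preset$vessel_radius - 4
    pts <- vesselCenterline(center, rmax, preset$vessel_segments, 0.72 * R)
    lumenMask <- array(FALSE, d)
    for (i in seq_len(nrow(pts) - 1L)) {
        cc <- rasterizeCapsule(pts[i, ], pts[i + 1L, ],
                               preset$vessel_radius, sp, d)
        lumenMask <- setVoxels(lumenMask, cc, TRUE)
    }
    lumenMask <- lumenMask & isletMask

    phantom0 <- new("IsletPhantom", isletMask = isletMask,
                    lumenMask = lumenMask,
                    cd11cLabels = array(0L, d), tcellLabels = array(0L, d),
                    spacing = as.numeric(sp))
    surface <- extractVascularSurface(phantom0)
    surfCenters <- voxelCenters(surface@coords, sp)
    w <- surface@weights
    totW <- sum(w)

    # --- CD11c placement: iterate to the target zone fraction -------------
    cd11cLabels <- array(0L, d)
    nearestDist <- rep(Inf, nrow(surface@coords))
    tz <- preset$target_zone_fraction
    nBlobs <- 0L
    consecutiveRejects <- 0L
    zf <- 0
    maxAttempts <- 60L * preset$cd11c_count
    attempts <- 0L
    while (zf < tz - 0.01 && nBlobs < preset$cd11c_count &&
           attempts < maxAttempts) {
        attempts <- attempts + 1L
        outIdx <- which(nearestDist > deltaZ)
        if (!length(outIdx)) break
        pick <- outIdx[sample.int(length(outIdx), 1L, prob = w[outIdx])]
        nrm <- outwardNormal(surface@coords[pick, ], lumenMask, sp)
        offs <- stats::runif(1, 0.2, 0.8) * preset$cd11c_radius
        bctr <- surfCenters[pick, ] + nrm * offs
        blob <- rasterizeSphere(bctr, preset$cd11c_radius, sp, d)
        if (!nrow(blob)) next
        keep <- !getVoxels(lumenMask, blob) & getVoxels(isletMask, blob) &
                getVoxels(cd11cLabels, blob) == 0L
        blob <- blob[keep, , drop = FALSE]
        if (nrow(blob) < 20L) next
        # incremental nearest-distance update over the blob's neighborhood
        pad <- preset$cd11c_radius + deltaZ + 2 * max(sp)
        lo <- bctr - pad; hi <- bctr + pad
        sel <- which(surfCenters[, 1] >= lo[1] & surfCenters[, 1] <= hi[1] &
                     surfCenters[, 2] >= lo[2] & surfCenters[, 2] <= hi[2] &
                     surfCenters[, 3] >= lo[3] & surfCenters[, 3] <= hi[3])
        newDist <- nearestDist
        if (length(sel)) {
            dd <- minDistToSet(surfCenters[sel, , drop = FALSE],
                               voxelCenters(blob, sp))
            newDist[sel] <- pmin(newDist[sel], dd)
        }
        zfNew <- sum(w[newDist <= deltaZ]) / totW
        if (zfNew > tz + 0.01) {        # overshoot: try another site
            consecutiveRejects <- consecutiveRejects + 1L
            if (consecutiveRejects > 200L) break
            next
        }
        consecutiveRejects <- 0L
        nBlobs <- nBlobs + 1L
        cd11cLabels <- setVoxels(cd11cLabels, blob, nBlobs)
        nearestDist <- newDist
        zf <- zfNew
    }
    if (zf < tz - 0.01)
        stop(sprintf(paste0(
            "unreachable target_zone_fraction %.3f with cd11c_count %d and ",
            "radius %.1f um: realized maximum %.3f"),
            tz, preset$cd11c_count, preset$cd11c_radius, zf))

    zoneMap <- computeContactZones(surface, cd11cLabels, deltaZ)
    cd11cBoundary <- maskBoundary(cd11cLabels > 0L)$coords
    cd11cBoundaryCenters <- voxelCenters(cd11cBoundary, sp)

    # --- T cells ----------------------------------------------------------
    n <- if (is.null(n_tcells))
        as.integer(round(preset$infiltration_fraction *
                         (R / preset$tcell_radius)^3))
    else as.integer(n_tcells)
    nExtra <- as.integer(round(preset$frac_extravascular * n))
    nIntra <- n - nExtra
    rc <- preset$tcell_radius

    tcellLabels <- array(0L, d)
    inZoneIdx <- which(zoneMap@inZone)
    outZoneIdx <- which(!zoneMap@inZone)
    intents <- data.frame(cell_id = integer(), compartment = character(),
                          in_zone = logical(), direct_contact = logical(),
                          achieved = logical())

    measureCell <- function(cellVox) {
        ctr <- colMeans(voxelCenters(cellVox, sp))
        sd0 <- distanceToSurface(ctr, surface, lumenMask)
        nn <- nearestInSet(rbind(ctr), surfCenters)[1L]
        overlap <- any(getVoxels(cd11cLabels, cellVox) > 0L)
        cdDist <- if (overlap) 0 else
            min(minDistPrefiltered(voxelCenters(cellVox, sp),
                                   cd11cBoundaryCenters))
        list(signed = sd0, in_zone = zoneMap@inZone[nn],
             contact = cdDist <= deltaC, cd_dist = cdDist)
    }

    placeSphere <- function(ctr, minFree = 0.45) {
        # arrested cells pack tightly: later cells may be carved by earlier
        # ones as long as most of the body remains
        vox <- rasterizeSphere(ctr, rc, sp, d)
        if (!nrow(vox)) return(NULL)
        vox <- vox[getVoxels(isletMask, vox), , drop = FALSE]
        free <- getVoxels(tcellLabels, vox) == 0L
        if (sum(free) < minFree * nrow(vox)) return(NULL)
        vox[free, , drop = FALSE]
    }

    cellId <- 0L
    if (nIntra > 0L) {
        wantZone <- stats::runif(nIntra) < preset$p_in_zone
        wantContact <- wantZone & (stats::runif(nIntra) < preset$p_direct_contact)
        sampleSite <- function(inz) {
            idx <- if (inz) inZoneIdx else outZoneIdx
            idx[sample.int(length(idx), 1L, prob = w[idx])]
        }
        tryPlace <- function(wantZ, wantC, requireContact = TRUE) {
            if (wantZ && !length(inZoneIdx)) return(NULL)
            pick <- sampleSite(wantZ)
            nrm <- outwardNormal(surface@coords[pick, ], lumenMask, sp)
            depth <- if (wantZ && !wantC)
                min(rc + deltaC + deltaZ + stats::runif(1, 1.0, 2.2),
                    preset$vessel_radius - 1)
            else stats::runif(1, 1.2, 2.8)
            ctr <- surfCenters[pick, ] - nrm * depth
            vox <- placeSphere(ctr)
            if (is.null(vox)) return(NULL)
            m <- measureCell(vox)
            ok <- m$signed < 0 && m$in_zone == wantZ &&
                  (!requireContact || m$contact == wantC)
            if (ok) list(vox = vox, m = m) else NULL
        }
        for (i in seq_len(nIntra)) {
            hit <- NULL
            achieved <- TRUE
            for (try in 1:200) {          # full intent
                hit <- tryPlace(wantZone[i], wantContact[i])
                if (!is.null(hit)) break
            }
            if (is.null(hit)) {           # keep zone membership at least
                achieved <- FALSE
                for (try in 1:100) {
                    hit <- tryPlace(wantZone[i], wantContact[i],
                                    requireContact = FALSE)
                    if (!is.null(hit)) break
                }
            }
            if (is.null(hit)) {           # any intravascular placement
                for (try in 1:100) {
                    pick <- sample.int(nrow(surface@coords), 1L, prob = w)
                    nrm <- outwardNormal(surface@coords[pick, ], lumenMask,
                                         sp)
                    ctr <- surfCenters[pick, ] -
                        nrm * stats::runif(1, 1.2, 2.8)
                    vox <- placeSphere(ctr)
                    if (is.null(vox)) next
                    m <- measureCell(vox)
                    if (m$signed < 0) {
                        hit <- list(vox = vox, m = m)
                        break
                    }
                }
            }
            if (!is.null(hit)) {
                cellId <- cellId + 1L
                tcellLabels <- setVoxels(tcellLabels, hit$vox, cellId)
                intents <- rbind(intents, data.frame(
                    cell_id = cellId, compartment = "intravascular",
                    in_zone = hit$m$in_zone, direct_contact = hit$m$contact,
                    achieved = achieved &&
                        hit$m$in_zone == wantZone[i] &&
                        hit$m$contact == wantContact[i]))
            }
        }
    }

    if (nExtra > 0L) {
        parenchyma <- which(isletMask & !lumenMask)
        for (i in seq_len(nExtra)) {
            for (try in 1:200) {
                v <- parenchyma[sample.int(length(parenchyma), 1L)]
                vi <- arrayInd(v, d)
                ctr <- voxelCenters(vi, sp)[1L, ]
                sd0 <- distanceToSurface(ctr, surface, lumenMask)
                if (sd0 < 0.8 * rc) next
                vox <- rasterizeSphere(ctr, rc, sp, d)
                vox <- vox[getVoxels(isletMask, vox) &
                           !getVoxels(lumenMask, vox), , drop = FALSE]
                if (!nrow(vox)) next
                free <- getVoxels(tcellLabels, vox) == 0L
                if (sum(free) < 0.6 * nrow(vox)) next
                vox <- vox[free, , drop = FALSE]
                cellId <- cellId + 1L
                tcellLabels <- setVoxels(tcellLabels, vox, cellId)
                intents <- rbind(intents, data.frame(
                    cell_id = cellId, compartment = "extravascular",
                    in_zone = NA, direct_contact = NA, achieved = TRUE))
                break
            }
        }
    }

    phantom <- new("IsletPhantom", isletMask = isletMask,
                   lumenMask = lumenMask, cd11cLabels = cd11cLabels,
                   tcellLabels = tcellLabels, spacing = as.numeric(sp))

    # ground truth is re-measured on the emitted volume
    gt <- list(realized_zone_fraction = zoneMap@zoneFraction,
               n_cd11c = nBlobs, n_tcells = cellId,
               seed = preset$seed, deltaZ = deltaZ, deltaC = deltaC,
               intents = intents)
    if (cellId > 0L) {
        loc <- localizeCells(phantom, surface, zoneMap, deltaC = deltaC)
        intra <- loc[loc$compartment == "intravascular", , drop = FALSE]
        gt$realized_extravascular_fraction <-
            mean(loc$compartment == "extravascular")
        gt$realized_in_zone_fraction <-
            if (nrow(intra)) mean(intra$in_zone) else NA_real_
        gt$realized_direct_contact_fraction <-
            if (nrow(intra)) mean(intra$direct_contact) else NA_real_
    } else {
        gt$realized_extravascular_fraction <- NA_real_
        gt$realized_in_zone_fraction <- NA_real_
        gt$realized_direct_contact_fraction <- NA_real_
    }
    list(phantom = phantom, surface = surface, zone_map = zoneMap,
         ground_truth = gt)
}
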