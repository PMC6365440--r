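#' Extract the voxel vascular surface from a phantom
#'
#' The vascular surface is the inner boundary of the vessel lumen: every
#' lumen voxel with at least one of its six faces exposed to non-lumen (the
#' volume border counts as non-lumen). Each surface voxel carries an
#' anisotropy-aware area weight in um^2 (see [VascularSurface-class]); this
#' surface is the reference against which leading-edge distances, contact
#' zones and intravascular/extravascular compartments are defined.
#'
#' @param phantom an [IsletPhantom-class].
#' @return a [VascularSurface-class].
#' @examples
#' ph <- generateIsletPhantom(geometryPreset("fig2_geometry",
#'     islet_radius = 30, vessel_segments = 2, cd11c_count = 20,
#'     infiltration_fraction = 0, seed = 1))$phantom
#' extractVascularSurface(ph)
#' @export
extractVascularSurface <- function(phantom) {
    stopifnot(is(phantom, "IsletPhantom"))
    if (!any(phantom@lumenMask))
        stop("empty lumen: no vascular surface to extract")
    b <- maskBoundary(phantom@lumenMask)
    w <- boundaryAreaWeights(b$flags, phantom@spacing)
    new("VascularSurface",
        coords = b$coords, weights = w,
        spacing = as.numeric(phantom@spacing),
        volumeDim = as.integer(dim(phantom@lumenMask)))
}

#' Compute CD11c-vascular contact zones
#'
#' A surface voxel is inside a CD11c-vascular contact zone when the Euclidean
#' distance (voxel centers, anisotropic spacing) from it to the nearest CD11c
#' voxel is at most \code{deltaZ} um. The zone fraction is the area-weighted
#' fraction of the vascular surface in zone - the quantity whose average the
#' random-placement null expectation equals.
#'
#' @param surface a [VascularSurface-class].
#' @param cd11cLabels integer 3D label array of CD11c instances (same grid as
#'   the phantom the surface came from), or an [IsletPhantom-class].
#' @param deltaZ contact distance threshold in um (default 1.5, about one
#'   xy voxel plus margin; "direct contact" at sub-cellular proximity).
#' @return a [ContactZoneMap-class]; zone fraction 0 with a warning when no
#'   CD11c voxels exist.
#' @export
computeContactZones <- function(surface, cd11cLabels, deltaZ = 1.5) {
    stopifnot(is(surface, "VascularSurface"), deltaZ >= 0)
    if (is(cd11cLabels, "IsletPhantom")) cd11cLabels <- cd11cLabels@cd11cLabels
    n <- nrow(surface@coords)
    cdIdx <- which(cd11cLabels > 0L, arr.ind = TRUE)
    if (nrow(cdIdx) == 0L) {
        warning("no CD11c voxels: zone fraction is 0")
        return(new("ContactZoneMap", inZone = rep(FALSE, n), zoneFraction = 0,
                   nearestCd11cDist = rep(Inf, n), deltaZ = deltaZ))
    }
    # distance to a filled blob is attained on its boundary (surface voxels
    # are lumen voxels, never interior to a CD11c instance)
    mask <- cd11cLabels > 0L
    bd <- maskBoundary(mask)$coords
    d <- minDistToSet(voxelCenters(surface@coords, surface@spacing),
                      voxelCenters(bd, surface@spacing))
    # degenerate labelings may place CD11c on the surface voxel itself
    d[getVoxels(mask, surface@coords)] <- 0
    inz <- d <= deltaZ
    zf <- if (sum(surface@weights) > 0)
        sum(surface@weights[inz]) / sum(surface@weights) else 0
    new("ContactZoneMap", inZone = inz, zoneFraction = zf,
        nearestCd11cDist = d, deltaZ = deltaZ)
}

#' Re-threshold an existing contact-zone map
#'
#' Uses the stored nearest-CD11c distances, so the zone fraction can be
#' examined as a function of the contact threshold without recomputation.
#'
#' @param map a [ContactZoneMap-class].
#' @param surface the [VascularSurface-class] the map was computed on.
#' @param deltaZ new threshold, um.
#' @return a [ContactZoneMap-class].
#' @export
rethresholdZones <- function(map, surface, deltaZ) {
    stopifnot(is(map, "ContactZoneMap"), deltaZ >= 0)
    inz <- map@nearestCd11cDist <= deltaZ
    zf <- if (sum(surface@weights) > 0)
        sum(surface@weights[inz]) / sum(surface@weights) else 0
    new("ContactZoneMap", inZone = inz, zoneFraction = zf,
        nearestCd11cDist = map@nearestCd11cDist, deltaZ = deltaZ)
}

#' Classify islet infiltration state
#'
#' Islet infiltration state follows the T-cell volume fraction of the islet:
#' mild when 0.1-30% of the islet volume is T-cell infiltrated, advanced at
#' 30-60%; fractions below 0.1% are uninfiltrated. The 30% boundary belongs
#' to the upper (advanced) class; fractions above 60% are reported as
#' advanced with an out-of-range flag.
#'
#' @param phantom an [IsletPhantom-class] with non-empty islet mask.
#' @return list with \code{category} (factor level of uninfiltrated / mild /
#'   advanced), \code{tcell_volume_fraction}, \code{out_of_range}.
#' @export
classifyInfiltration <- function(phantom) {
    stopifnot(is(phantom, "IsletPhantom"))
    nIslet <- sum(phantom@isletMask)
    if (nIslet == 0L) stop("empty islet mask")
    frac <- sum(phantom@tcellLabels > 0L) / nIslet
    category <- if (frac < 0.001) "uninfiltrated"
        else if (frac < 0.30) "mild"
        else "advanced"
    list(category = factor(category,
             levels = c("uninfiltrated", "mild", "advanced")),
         tcell_volume_fraction = frac,
         out_of_range = frac > 0.60)
}

#' Signed distance from points to the vascular surface
#'
#' Magnitude is the distance to the nearest surface voxel center; the sign is
#' negative inside the lumen and positive outside, so extravasation reads as
#' a trajectory rising through zero.
#'
#' @param points n x 3 matrix (or length-3 vector) of physical um
#'   coordinates; must lie within the volume bounds.
#' @param surface a [VascularSurface-class].
#' @param lumenMask logical 3D lumen array (or an [IsletPhantom-class]).
#' @return numeric signed distances, um.
#' @export
distanceToSurface <- function(points, surface, lumenMask) {
    stopifnot(is(surface, "VascularSurface"))
    if (is(lumenMask, "IsletPhantom")) lumenMask <- lumenMask@lumenMask
    points <- rbind(points)
    vox <- pointToVoxel(points, surface@spacing, surface@volumeDim)
    inside <- getVoxels(lumenMask, vox)
    d <- minDistToSet(points, voxelCenters(surface@coords, surface@spacing))
    ifelse(inside, -d, d)
}
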