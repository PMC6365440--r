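#' @import methods
NULL

#' Labeled 3D islet phantom
#'
#' Container for a labeled voxel volume of a pancreatic islet as seen by
#' intravital two-photon microscopy: a spherical islet mask, a connected
#' tubular vessel lumen, perivascular CD11c+ cell instances and T-cell
#' instances. All grids share one shape; voxel label 0 is background and
#' positive integers are instance ids. Physical voxel centers are at
#' \code{(index - 0.5) * spacing} micrometres (0-based voxel \code{i} spans
#' \code{[i, i+1] * spacing}).
#'
#' @slot isletMask logical 3D array, TRUE inside the islet sphere.
#' @slot lumenMask logical 3D array, TRUE inside the vessel lumen.
#' @slot cd11cLabels integer 3D array of CD11c instance labels.
#' @slot tcellLabels integer 3D array of T-cell instance labels.
#' @slot spacing numeric length-3, micrometres per voxel along (x, y, z).
#'
#' @seealso [generateIsletPhantom()], [extractVascularSurface()]
#' @export
setClass("IsletPhantom",
    representation(
        isletMask   = "array",
        lumenMask   = "array",
        cd11cLabels = "array",
        tcellLabels = "array",
        spacing     = "numeric"
    )
)

setValidity("IsletPhantom", function(object) {
    msg <- character()
    d <- dim(object@isletMask)
    if (length(d) != 3L)
        msg <- c(msg, "isletMask must be a 3D array")
    for (nm in c("lumenMask", "cd11cLabels", "tcellLabels")) {
        if (!identical(dim(slot(object, nm)), d))
            msg <- c(msg, sprintf("%s dims differ from isletMask", nm))
    }
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (any(object@cd11cLabels < 0) || any(object@tcellLabels < 0))
        msg <- c(msg, "instance labels must be non-negative integers")
    if (any(object@lumenMask & !object@isletMask))
        msg <- c(msg, "lumen must lie inside the islet mask")
    if (length(msg)) msg else TRUE
})

#' Discretised vascular surface
#'
#' The inner boundary voxels of the vessel lumen (lumen voxels with at least
#' one face exposed to non-lumen), each carrying an area weight in square
#' micrometres. The weight combines the net signed exposed-face vector with
#' the area of cancelling face pairs, so an isolated voxel gets its full
#' closed-box area while smooth walls are estimated without the staircase
#' inflation of raw face counting.
#'
#' @slot coords integer matrix (n x 3) of 1-based voxel indices.
#' @slot weights numeric per-voxel area weight, um^2.
#' @slot spacing numeric length-3 voxel spacing, um.
#' @slot volumeDim integer length-3 dims of the originating volume.
#'
#' @seealso [extractVascularSurface()], [computeContactZones()]
#' @export
setClass("VascularSurface",
    representation(
        coords    = "matrix",
        weights   = "numeric",
        spacing   = "numeric",
        volumeDim = "integer"
    )
)

setValidity("VascularSurface", function(object) {
    msg <- character()
    if (ncol(object@coords) != 3L)
        msg <- c(msg, "coords must have 3 columns")
    if (nrow(object@coords) != length(object@weights))
        msg <- c(msg, "one weight per surface voxel required")
    if (length(object@weights) && any(object@weights < 0))
        msg <- c(msg, "area weights must be non-negative")
    if (length(msg)) msg else TRUE
})

#' CD11c-vascular contact zone map
#'
#' Flags every vascular surface voxel as inside/outside a CD11c-vascular
#' contact zone (within \code{deltaZ} um of a CD11c voxel) and stores the
#' area-weighted zone fraction. The per-voxel nearest CD11c distance is kept
#' so the map can be re-thresholded without recomputation.
#'
#' @slot inZone logical per surface voxel.
#' @slot zoneFraction numeric in [0, 1]; area-weighted fraction in zone.
#' @slot nearestCd11cDist numeric per surface voxel, um.
#' @slot deltaZ numeric contact distance threshold, um.
#'
#' @seealso [computeContactZones()], [enrichmentTest()]
#' @export
setClass("ContactZoneMap",
    representation(
        inZone           = "logical",
        zoneFraction     = "numeric",
        nearestCd11cDist = "numeric",
        deltaZ           = "numeric"
    )
)

setValidity("ContactZoneMap", function(object) {
    msg <- character()
    if (length(object@inZone) != length(object@nearestCd11cDist))
        msg <- c(msg, "inZone and nearestCd11cDist lengths differ")
    if (object@zoneFraction < 0 || object@zoneFraction > 1)
        msg <- c(msg, "zoneFraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
})
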