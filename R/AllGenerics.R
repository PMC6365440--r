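#' Voxel spacing of an object
#'
#' @param x an object carrying physical voxel spacing.
#' @return numeric length-3, micrometres per voxel along (x, y, z).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "IsletPhantom", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VascularSurface", function(x) x@spacing)

#' Total surface area
#'
#' @param x a [VascularSurface-class].
#' @return total area-weighted surface area in um^2.
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))

#' @rdname totalArea
#' @export
setMethod("totalArea", "VascularSurface", function(x) sum(x@weights))

#' Surface voxel coordinates
#'
#' @param x a [VascularSurface-class].
#' @return integer matrix (n x 3) of 1-based voxel indices.
#' @export
setGeneric("surfaceCoords", function(x) standardGeneric("surfaceCoords"))

#' @rdname surfaceCoords
#' @export
setMethod("surfaceCoords", "VascularSurface", function(x) x@coords)

#' Per-voxel surface area weights
#'
#' @param x a [VascularSurface-class].
#' @return numeric vector of per-voxel area weights, um^2.
#' @export
setGeneric("surfaceWeights", function(x) standardGeneric("surfaceWeights"))

#' @rdname surfaceWeights
#' @export
setMethod("surfaceWeights", "VascularSurface", function(x) x@weights)

#' Area-weighted contact-zone fraction
#'
#' @param x a [ContactZoneMap-class].
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("zoneFraction", function(x) standardGeneric("zoneFraction"))

#' @rdname zoneFraction
#' @export
setMethod("zoneFraction", "ContactZoneMap", function(x) x@zoneFraction)

#' In-zone flags per surface voxel
#'
#' @param x a [ContactZoneMap-class].
#' @return logical vector, one entry per surface voxel.
#' @export
setGeneric("inZone", function(x) standardGeneric("inZone"))

#' @rdname inZone
#' @export
setMethod("inZone", "ContactZoneMap", function(x) x@inZone)

setMethod("show", "IsletPhantom", function(object) {
    d <- dim(object@isletMask)
    cat(sprintf("IsletPhantom %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
        d[1], d[2], d[3],
        object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  lumen voxels: %d | CD11c cells: %d | T cells: %d\n",
        sum(object@lumenMask),
        length(setdiff(unique(as.vector(object@cd11cLabels)), 0L)),
        length(setdiff(unique(as.vector(object@tcellLabels)), 0L))))
})

setMethod("show", "VascularSurface", function(object) {
    cat(sprintf("VascularSurface: %d voxels, total area %.1f um^2\n",
        nrow(object@coords), sum(object@weights)))
})

setMethod("show", "ContactZoneMap", function(object) {
    cat(sprintf(
        "ContactZoneMap: %d surface voxels, deltaZ %.2f um, zone fraction %.3f\n",
        length(object@inZone), object@deltaZ, object@zoneFraction))
})
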