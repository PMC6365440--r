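#' Localize T cells relative to the vasculature and CD11c cells
#'
#' Assigns each T-cell instance a compartment by the sign of its centroid's
#' distance to the vascular surface (negative = intravascular), flags
#' intravascular cells as in/out of the CD11c-vascular contact zone by the
#' zone membership of the surface voxel nearest the centroid, and computes
#' the voxel surface-to-surface distance to the nearest CD11c cell (0 when
#' the label masks overlap). Direct contact means that distance is at most
#' \code{deltaC}.
#'
#' @param phantom an [IsletPhantom-class].
#' @param surface its [VascularSurface-class] (computed if missing).
#' @param zoneMap its [ContactZoneMap-class] (computed at \code{deltaZ = 1.5}
#'   if missing).
#' @param deltaC direct-contact threshold, um (default 1.0).
#' @param cells optional integer vector of T-cell labels to localize
#'   (default: all labels present); an absent label is an error.
#' @return data.frame with one row per cell: \code{cell_id},
#'   \code{compartment}, \code{in_zone} (NA for extravascular cells),
#'   \code{nearest_cd11c_um}, \code{direct_contact}, \code{signed_dist_um}.
#' @export
localizeCells <- function(phantom, surface = NULL, zoneMap = NULL,
                          deltaC = 1.0, cells = NULL) {
    stopifnot(is(phantom, "IsletPhantom"))
    if (is.null(surface)) surface <- extractVascularSurface(phantom)
    if (is.null(zoneMap))
        zoneMap <- computeContactZones(surface, phantom@cd11cLabels)
    sp <- phantom@spacing
    d <- dim(phantom@tcellLabels)
    present <- setdiff(sort(unique(as.vector(phantom@tcellLabels))), 0L)
    if (is.null(cells)) cells <- present
    missing <- setdiff(cells, present)
    if (length(missing))
        stop("T-cell label(s) absent from volume: ",
             paste(missing, collapse = ", "))
    surfCenters <- voxelCenters(surface@coords, sp)
    cdMask <- phantom@cd11cLabels > 0L
    haveCd <- any(cdMask)
    cdBoundary <- if (haveCd) voxelCenters(maskBoundary(cdMask)$coords, sp)
                  else NULL
    cdLinear <- if (haveCd) which(cdMask) else integer()

    if (!length(cells))
        return(data.frame(cell_id = integer(), compartment = character(),
                          in_zone = logical(), nearest_cd11c_um = numeric(),
                          direct_contact = logical(),
                          signed_dist_um = numeric()))
    lin <- which(phantom@tcellLabels > 0L)
    labOf <- phantom@tcellLabels[lin]
    voxByLab <- split(lin, labOf)
    out <- lapply(cells, function(lab) {
        vlin <- voxByLab[[as.character(lab)]]
        vox <- arrayInd(vlin, d)
        ctr <- colMeans(voxelCenters(vox, sp))
        sd0 <- distanceToSurface(ctr, surface, phantom@lumenMask)
        comp <- if (sd0 < 0) "intravascular" else "extravascular"
        nn <- nearestInSet(rbind(ctr), surfCenters)[1L]
        inz <- if (comp == "intravascular") zoneMap@inZone[nn] else NA
        cdDist <- if (!haveCd) Inf
            else if (any(vlin %in% cdLinear)) 0
            else min(minDistPrefiltered(voxelCenters(vox, sp), cdBoundary))
        data.frame(cell_id = lab, compartment = comp, in_zone = inz,
                   nearest_cd11c_um = cdDist,
                   direct_contact = cdDist <= deltaC,
                   signed_dist_um = sd0)
    })
    do.call(rbind, out)
}

#' Test enrichment of intravascular T cells in contact zones
#'
#' Compares the observed fraction of intravascular T cells inside
#' CD11c-vascular contact zones against the random-placement null, under
#' which a cell lands in zone with probability equal to the area-weighted
#' zone fraction. The binomial method computes the exact one-sided upper
#' tail P(X >= k), X ~ Binomial(n, zone fraction); the permutation method
#' places n pseudo-cells uniformly over surface voxels (area-weighted) and
#' uses the add-one estimator p = (1 + #\{perm >= obs\}) / (1 + B).
#'
#' @param localization data.frame from [localizeCells()].
#' @param zoneMap the [ContactZoneMap-class] used for localization.
#' @param surface the [VascularSurface-class] (needed for area weights when
#'   \code{method = "permutation"}).
#' @param method \code{"binomial"} or \code{"permutation"}.
#' @param nPermutations number of permutation draws (default 10000).
#' @param seed RNG seed for the permutation null (mandatory for
#'   reproducibility when \code{method = "permutation"}).
#' @return list with \code{n_intravascular}, \code{observed_in_zone_fraction},
#'   \code{expected_in_zone_fraction} (= zone fraction), \code{p_value},
#'   \code{method}, \code{n_permutations}, \code{seed}, and for the
#'   permutation method \code{perm_mean} (mean permuted in-zone fraction).
#' @export
enrichmentTest <- function(localization, zoneMap, surface = NULL,
                           method = c("binomial", "permutation"),
                           nPermutations = 10000L, seed = NULL) {
    method <- match.arg(method)
    intra <- localization[localization$compartment == "intravascular", ,
                          drop = FALSE]
    n <- nrow(intra)
    if (n == 0L) stop("no cells to test: zero intravascular cells")
    k <- sum(intra$in_zone)
    obs <- k / n
    p0 <- zoneMap@zoneFraction
    if (method == "binomial") {
        p <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
        return(list(n_intravascular = n, observed_in_zone_fraction = obs,
                    expected_in_zone_fraction = p0, p_value = p,
                    method = method, n_permutations = 0L, seed = NA_integer_))
    }
    if (is.null(surface))
        stop("permutation method needs the surface for area weights")
    if (is.null(seed))
        stop("permutation method needs an explicit seed")
    fracs <- withr::with_seed(seed, {
        draws <- sample.int(length(zoneMap@inZone), n * nPermutations,
                            replace = TRUE, prob = surface@weights)
        colMeans(matrix(zoneMap@inZone[draws], nrow = n))
    })
    p <- (1 + sum(fracs >= obs)) / (1 + nPermutations)
    list(n_intravascular = n, observed_in_zone_fraction = obs,
         expected_in_zone_fraction = p0, p_value = p, method = method,
         n_permutations = as.integer(nPermutations), seed = seed,
         perm_mean = mean(fracs))
}

#' Summarize contact-zone enrichment for one islet
#'
#' Produces the per-islet paired record (surface zone fraction vs observed
#' intravascular in-zone percentage) plus the nearest-CD11c distance
#' distribution, the form in which multiple islets are compared.
#'
#' @param localization data.frame from [localizeCells()].
#' @param zoneMap the matching [ContactZoneMap-class].
#' @return list: \code{zone_fraction_pct}, \code{observed_in_zone_pct}
#'   (NA with \code{n_intravascular = 0} when no cell is intravascular),
#'   \code{direct_contact_pct}, \code{n_intravascular},
#'   \code{nearest_cd11c_um} (per intravascular cell), \code{median_nearest_um}.
#' @export
summarizeContactEnrichment <- function(localization, zoneMap) {
    intra <- localization[localization$compartment == "intravascular", ,
                          drop = FALSE]
    n <- nrow(intra)
    list(zone_fraction_pct = 100 * zoneMap@zoneFraction,
         observed_in_zone_pct = if (n) 100 * mean(intra$in_zone) else NA_real_,
         direct_contact_pct = if (n) 100 * mean(intra$direct_contact)
                              else NA_real_,
         n_intravascular = n,
         nearest_cd11c_um = intra$nearest_cd11c_um,
         median_nearest_um = if (n) stats::median(intra$nearest_cd11c_um)
                             else NA_real_)
}
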