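# Shared fixtures, built in code and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# Small, fast geometry preset for property-style loops (explicit overrides
# win over the scaled-down defaults).
smallGeometryPreset <- function(seed = 1L, ...) {
    args <- utils::modifyList(
        list(name = "fig2_geometry", islet_radius = 32,
             vessel_segments = 3L, vessel_radius = 9, cd11c_count = 80L,
             cd11c_radius = 5, infiltration_fraction = 0.05,
             tcell_radius = 3.5, seed = seed),
        list(...))
    do.call(geometryPreset, args)
}

smallBundle <- function(seed = 1L) {
    cached(paste0("small_", seed), generateIsletPhantom(smallGeometryPreset(seed)))
}

# Full-scale advanced-infiltration phantom (contact-zone study conditions).
fig2Bundle <- function(seed) {
    cached(paste0("fig2_", seed),
           generateIsletPhantom(geometryPreset("fig2_geometry", seed = seed)))
}

# Hand-built phantom: a straight axis-aligned cylindrical vessel inside a
# box islet, with one CD11c blob touching the wall. Everything about it is
# analytically known.
cylinderPhantom <- function(dim = c(40L, 40L, 16L),
                            spacing = c(1, 1, 2), radius = 6,
                            cd11c = TRUE) {
    d <- as.integer(dim)
    islet <- array(TRUE, d)
    lumen <- array(FALSE, d)
    cx <- (d[1] / 2) * spacing[1]
    cy <- (d[2] / 2) * spacing[2]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        x <- (i - 0.5) * spacing[1] - cx
        y <- (j - 0.5) * spacing[2] - cy
        if (x^2 + y^2 <= radius^2) lumen[i, j, ] <- TRUE
    }
    cd <- array(0L, d)
    if (cd11c) {
        # a small blob pressed against the +x side of the wall, mid-z
        ctr <- c(cx + radius + 2, cy, (d[3] / 2) * spacing[3])
        for (i in seq_len(d[1])) for (j in seq_len(d[2]))
            for (k in seq_len(d[3])) {
                p <- (c(i, j, k) - 0.5) * spacing
                if (sum((p - ctr)^2) <= 3^2 && !lumen[i, j, k])
                    cd[i, j, k] <- 1L
            }
    }
    new("IsletPhantom", isletMask = islet, lumenMask = lumen,
        cd11cLabels = cd, tcellLabels = array(0L, d),
        spacing = as.numeric(spacing))
}

# Brute-force nearest-distance oracle: per query point, a direct scan over
# every reference point; shares no code with the package kernel.
bruteMinDist <- function(query, ref) {
    apply(rbind(query), 1L, function(p)
        sqrt(min((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2 +
                 (ref[, 3] - p[3])^2)))
}

# physical centers of voxel indices (1-based), duplicated here so oracle
# computations do not lean on package internals
centersOf <- function(idx, spacing) {
    cbind((idx[, 1] - 0.5) * spacing[1],
          (idx[, 2] - 0.5) * spacing[2],
          (idx[, 3] - 0.5) * spacing[3])
}

# Synthetic single-track table following a prescribed signed-distance path
# along the +x normal of the cylinder phantom wall.
trackFromPath <- function(phantom, s_um, dt = 20) {
    d <- dim(phantom@lumenMask)
    sp <- phantom@spacing
    cx <- (d[1] / 2) * sp[1]
    cy <- (d[2] / 2) * sp[2]
    zz <- (d[3] / 2) * sp[3]
    radius <- 6
    data.frame(track_id = 1L, frame = seq_along(s_um) - 1L,
               t_seconds = (seq_along(s_um) - 1L) * dt,
               x_um = cx + radius + s_um, y_um = cy, z_um = zz)
}
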