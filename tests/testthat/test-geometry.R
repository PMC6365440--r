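test_that("single-voxel lumen exposes its full closed-box area", {
    d <- c(7L, 7L, 5L)
    sp <- c(1, 1.5, 3)
    lumen <- array(FALSE, d)
    lumen[4, 4, 3] <- TRUE
    ph <- new("IsletPhantom", isletMask = array(TRUE, d), lumenMask = lumen,
              cd11cLabels = array(0L, d), tcellLabels = array(0L, d),
              spacing = sp)
    surf <- extractVascularSurface(ph)
    expect_equal(nrow(surfaceCoords(surf)), 1L)
    expect_equal(totalArea(surf),
                 2 * (sp[1] * sp[2] + sp[1] * sp[3] + sp[2] * sp[3]))
})

test_that("axis-aligned cylinder area is close to 2*pi*r*L", {
    d <- c(48L, 48L, 40L)
    sp <- c(0.5, 0.5, 0.5)
    r <- 8; L <- d[3] * sp[3]
    lumen <- array(FALSE, d)
    cx <- d[1] / 2 * sp[1]; cy <- d[2] / 2 * sp[2]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        x <- (i - 0.5) * sp[1] - cx; y <- (j - 0.5) * sp[2] - cy
        if (x^2 + y^2 <= r^2) lumen[i, j, ] <- TRUE
    }
    ph <- new("IsletPhantom", isletMask = array(TRUE, d), lumenMask = lumen,
              cd11cLabels = array(0L, d), tcellLabels = array(0L, d),
              spacing = sp)
    lateral <- totalArea(extractVascularSurface(ph)) - 2 * pi * r^2
    expect_lt(abs(lateral - 2 * pi * r * L) / (2 * pi * r * L), 0.15)
})

test_that("surface extraction is deterministic and reflection-symmetric", {
    ph <- cylinderPhantom()
    s1 <- extractVascularSurface(ph)
    s2 <- extractVascularSurface(ph)
    expect_identical(surfaceCoords(s1), surfaceCoords(s2))
    expect_identical(surfaceWeights(s1), surfaceWeights(s2))

    refl <- ph
    refl@isletMask <- ph@isletMask[dim(ph@isletMask)[1]:1, , ]
    refl@lumenMask <- ph@lumenMask[dim(ph@lumenMask)[1]:1, , ]
    refl@cd11cLabels <- ph@cd11cLabels[dim(ph@cd11cLabels)[1]:1, , ]
    refl@tcellLabels <- ph@tcellLabels[dim(ph@tcellLabels)[1]:1, , ]
    sR <- extractVascularSurface(refl)
    co <- surfaceCoords(s1)
    coR <- surfaceCoords(sR)
    coR[, 1] <- dim(ph@lumenMask)[1] + 1L - coR[, 1]
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(co), key(coR))
    expect_equal(totalArea(sR), totalArea(s1))
})

test_that("surface extraction is invariant under axis permutation", {
    ph <- cylinderPhantom(dim = c(24L, 24L, 12L), spacing = c(1, 1, 2),
                          radius = 5, cd11c = FALSE)
    perm <- c(3L, 1L, 2L)
    phP <- new("IsletPhantom",
               isletMask = aperm(ph@isletMask, perm),
               lumenMask = aperm(ph@lumenMask, perm),
               cd11cLabels = aperm(ph@cd11cLabels, perm),
               tcellLabels = aperm(ph@tcellLabels, perm),
               spacing = ph@spacing[perm])
    s <- extractVascularSurface(ph)
    sP <- extractVascularSurface(phP)
    expect_equal(totalArea(sP), totalArea(s))
    co <- surfaceCoords(s)[, perm, drop = FALSE]
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(co), key(surfaceCoords(sP)))
})

test_that("empty lumen is an explicit failure", {
    d <- c(5L, 5L, 5L)
    ph <- new("IsletPhantom", isletMask = array(TRUE, d),
              lumenMask = array(FALSE, d), cd11cLabels = array(0L, d),
              tcellLabels = array(0L, d), spacing = c(1, 1, 1))
    expect_error(extractVascularSurface(ph), "empty lumen")
})

test_that("signed distance: zero on surface, negative deep in lumen, error outside", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- extractVascularSurface(ph)
    sc <- centersOf(surfaceCoords(surf), ph@spacing)
    expect_equal(distanceToSurface(sc[1, ], surf, ph),
                 0, tolerance = 1e-12)
    deep <- c(20, 20, 16)              # on the cylinder axis
    expect_lt(distanceToSurface(deep, surf, ph), 0)
    expect_error(distanceToSurface(c(-5, 20, 16), surf, ph),
                 "outside volume")
})

test_that("signed distance matches a brute-force nearest-surface scan", {
    ph <- cylinderPhantom(dim = c(20L, 20L, 10L), spacing = c(1, 1, 2),
                          radius = 5, cd11c = FALSE)
    surf <- extractVascularSurface(ph)
    sc <- centersOf(surfaceCoords(surf), ph@spacing)
    set.seed(42)
    pts <- cbind(runif(25, 1, 19), runif(25, 1, 19), runif(25, 1, 19))
    got <- distanceToSurface(pts, surf, ph)
    want <- bruteMinDist(pts, sc)
    vox <- cbind(pmin(floor(pts[, 1]) + 1, 20),
                 pmin(floor(pts[, 2]) + 1, 20),
                 pmin(floor(pts[, 3] / 2) + 1, 10))
    inside <- ph@lumenMask[vox]
    expect_equal(got, ifelse(inside, -want, want), tolerance = 1e-10)
})

test_that("infiltration classification partitions [0, 1] with 30% advanced", {
    d <- c(10L, 10L, 10L)
    mk <- function(k) {
        tc <- array(0L, d)
        if (k > 0) tc[seq_len(k)] <- 1L
        new("IsletPhantom", isletMask = array(TRUE, d),
            lumenMask = array(FALSE, d), cd11cLabels = array(0L, d),
            tcellLabels = tc, spacing = c(1, 1, 1))
    }
    cases <- list(list(0L, "uninfiltrated", FALSE),
                  list(150L, "mild", FALSE),
                  list(299L, "mild", FALSE),
                  list(300L, "advanced", FALSE),  # boundary -> upper class
                  list(600L, "advanced", FALSE),
                  list(700L, "advanced", TRUE))   # out of range flag
    for (cs in cases) {
        st <- classifyInfiltration(mk(cs[[1]]))
        expect_equal(as.character(st$category), cs[[2]])
        expect_equal(st$out_of_range, cs[[3]])
        expect_equal(st$tcell_volume_fraction, cs[[1]] / 1000)
    }
    # sub-0.1% fraction is uninfiltrated (1000 voxels can't express 0.0005,
    # so check the boundary from below with a bigger islet)
    big <- array(TRUE, c(20L, 20L, 20L))
    tc <- array(0L, c(20L, 20L, 20L)); tc[seq_len(7L)] <- 1L  # 0.000875
    st <- classifyInfiltration(new("IsletPhantom", isletMask = big,
        lumenMask = array(FALSE, c(20L, 20L, 20L)),
        cd11cLabels = array(0L, c(20L, 20L, 20L)), tcellLabels = tc,
        spacing = c(1, 1, 1)))
    expect_equal(as.character(st$category), "uninfiltrated")
})
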