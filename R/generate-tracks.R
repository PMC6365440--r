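# Time-lapse track generator. Emits per-frame leading-edge positions for
# T cells arrested in the islet vasculature. Each track arrests at a random
# vascular surface site and then, per the drawn fate, stays arrested,
# releases back into flow (track terminates while intravascular) or
# completes extravasation (leading edge ramps outward, crossing the
# extravasation margin exactly at the drawn waiting time, then keeps moving
# away from the vessel). Positions are laid out along the local outward wall
# normal, so re-measuring the signed distance against the voxel surface
# recovers the programmed trajectory to within voxelization error.

drawWaitingTime <- function(n, median_min, family, sigma_log) {
    switch(family,
        lognormal = stats::rlnorm(n, meanlog = log(median_min),
                                  sdlog = sigma_log),
        exponential = stats::rexp(n, rate = log(2) / median_min),
        stop("unknown waiting_time_family: ", family))
}

# unit vector orthogonal to v
orthoUnit <- function(v) {
    a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- pracma_cross(v, a)
    u / sqrt(sum(u^2))
}

pracma_cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Generate arrested T-cell tracks with known fates
#'
#' Simulates a 2-h (by default) intravital imaging session of T cells
#' arrested in the islet vasculature of a phantom. Fates are drawn per track
#' (release / complete extravasation / remain arrested); waiting times from
#' arrest follow the preset's log-normal family parameterised by its median.
#' A preset fraction of tracks is left-censored: already arrested at the
#' start of imaging, with an unknown elapsed arrest time (a uniform fraction
#' of the drawn waiting time has already passed), which makes downstream
#' median event times systematic underestimates - as expected for this kind
#' of imaging window.
#'
#' @param preset a [kineticsPreset()] bundle.
#' @param phantomBundle output of [generateIsletPhantom()] (list with
#'   \code{phantom} and \code{surface}); supplies arrest sites and normals.
#' @param nTracks number of tracks to simulate.
#' @return list with \code{tracks} (data.frame: track_id, frame, t_seconds,
#'   x_um, y_um, z_um, islet_id, infiltration) and \code{ground_truth}
#'   (data.frame per track: fate observable within the imaging window,
#'   true_fate as drawn, event_time_true min from arrest, arrest_start_min,
#'   left_censored, right_censored).
#' @export
generateTracks <- function(preset, phantomBundle, nTracks = 200L) {
    stopifnot(inherits(preset, "KineticsPreset"))
    if (preset$duration * 60 < preset$frame_interval)
        stop("duration must cover at least one frame interval")
    phantom <- phantomBundle$phantom
    surface <- phantomBundle$surface
    if (is.null(surface)) surface <- extractVascularSurface(phantom)
    if (!nrow(surface@coords)) stop("phantom contains no vessel surface")
    withr::with_seed(preset$seed, {
        .generateTracksImpl(preset, phantom, surface, as.integer(nTracks))
    })
}

.generateTracksImpl <- function(preset, phantom, surface, nTracks) {
    sp <- phantom@spacing
    d <- dim(phantom@lumenMask)
    dt <- preset$frame_interval            # seconds
    tEnd <- preset$duration * 60           # seconds
    frames <- seq(0, tEnd, by = dt)
    surfCenters <- voxelCenters(surface@coords, sp)
    extentUm <- d * sp

    arrestDepth <- 2.5                     # um inside the wall
    rampMin <- 6                           # min to cross from arrest to margin
    margin <- 5                            # um, completion threshold
    postSpeed <- 2                         # um/min outward after completion
    jitterSd <- 0.12                       # um per frame, residual wobble

    fates <- sample(c("released", "extravasated", "remain_arrested"),
                    nTracks, replace = TRUE,
                    prob = c(preset$p_release, preset$p_extravasate,
                             1 - preset$p_release - preset$p_extravasate))
    leftCens <- stats::runif(nTracks) < preset$frac_left_censored

    trackRows <- vector("list", nTracks)
    gtRows <- vector("list", nTracks)
    for (i in seq_len(nTracks)) {
        # arrest site and local frame; extravasating cells need outward
        # headroom before the volume border
        for (try in 1:50) {
            pick <- sample.int(nrow(surfCenters), 1L, prob = surface@weights)
            nrm <- outwardNormal(surface@coords[pick, ], phantom@lumenMask, sp)
            base <- surfCenters[pick, ]
            sMax <- 3
            while (sMax < 40) {
                p <- base + (sMax + 2) * nrm
                if (any(p < 2) || any(p > extentUm - 2)) break
                sMax <- sMax + 1
            }
            if (fates[i] != "extravasated" || sMax >= margin + 4) break
        }
        tang <- orthoUnit(nrm)

        if (leftCens[i]) {
            arrestStart <- 0
            preFrames <- 0L
        } else {
            # appear, move briefly along the wall, then arrest
            arrestStart <- stats::runif(1, 0, 5 * 60)
            arrestStart <- round(arrestStart / dt) * dt
            preFrames <- 2L
        }
        tw <- drawWaitingTime(1, switch(fates[i],
                released = preset$median_release_time,
                extravasated = preset$median_extravasation_time,
                60), preset$waiting_time_family, preset$sigma_log)
        if (leftCens[i]) tw <- tw * (1 - stats::runif(1))  # elapsed unknown
        eventAbs <- arrestStart + tw * 60  # seconds

        fateObs <- fates[i]
        if (fates[i] == "remain_arrested" || eventAbs > tEnd) {
            fateObs <- "remain_arrested"
            eventAbs <- Inf
        }

        t0 <- max(arrestStart - preFrames * dt, 0)
        tsel <- frames[frames >= t0]
        if (fateObs == "released") tsel <- tsel[tsel <= eventAbs]
        if (length(tsel) < 2L) tsel <- frames[seq_len(2L)] + t0
        rel <- (tsel - arrestStart) / 60   # minutes since arrest

        s <- rep(-arrestDepth, length(tsel))
        if (fateObs == "extravasated") {
            tcross <- tw                   # minutes from arrest to completion
            ramp <- rel > (tcross - rampMin) & rel <= tcross
            s[ramp] <- -arrestDepth +
                (arrestDepth + margin) * (rel[ramp] - (tcross - rampMin)) / rampMin
            after <- rel > tcross
            s[after] <- pmin(margin + postSpeed * (rel[after] - tcross), sMax)
        }
        pre <- rel < 0
        pos <- matrix(base, length(tsel), 3L, byrow = TRUE) + outer(s, nrm)
        if (any(pre)) {
            # pre-arrest wall-rolling: fast (~36 um/min) tangential approach
            nPre <- sum(pre)
            for (k in seq_len(nPre))
                pos[k, ] <- pos[k, ] + tang * 12 * (nPre - k + 1)
        }
        pos <- pos + matrix(stats::rnorm(3 * length(tsel), 0, jitterSd),
                            ncol = 3L)
        # clamp to the volume interior
        for (j in 1:3) pos[, j] <- pmin(pmax(pos[, j], 0.6 * sp[j]),
                                        extentUm[j] - 0.6 * sp[j])

        trackRows[[i]] <- data.frame(
            track_id = i, frame = match(tsel, frames) - 1L, t_seconds = tsel,
            x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
            islet_id = 1L, infiltration = preset$infiltration)
        gtRows[[i]] <- data.frame(
            track_id = i, fate = fateObs, true_fate = fates[i],
            event_time_true = if (is.finite(eventAbs)) tw else NA_real_,
            arrest_start_min = arrestStart / 60,
            left_censored = leftCens[i],
            right_censored = fateObs == "remain_arrested")
    }
    list(tracks = do.call(rbind, trackRows),
         ground_truth = do.call(rbind, gtRows))
}
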