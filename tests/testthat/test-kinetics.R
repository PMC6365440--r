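cylSurface <- function(ph) extractVascularSurface(ph)

test_that("stationary intraluminal cell has a constant negative trajectory", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- cylSurface(ph)
    tr <- trackFromPath(ph, rep(-4, 20))
    traj <- leadingEdgeTrajectory(tr, surf, ph)
    expect_true(all(traj$dist_um < 0))
    expect_lt(diff(range(traj$dist_um)), 1e-9)
})

test_that("a prescribed crossing path rises through zero once", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- cylSurface(ph)
    s <- c(rep(-3, 10), seq(-3, 8, length.out = 12), rep(8, 8))
    traj <- leadingEdgeTrajectory(trackFromPath(ph, s), surf, ph)
    sgn <- sign(traj$dist_um)
    flips <- sum(diff(sgn[sgn != 0]) != 0)
    expect_equal(flips, 1L)
    expect_lt(traj$dist_um[1], 0)
    expect_gt(traj$dist_um[nrow(traj)], 5)
})

test_that("frame gaps split trajectories with a warning", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- cylSurface(ph)
    tr <- trackFromPath(ph, rep(-4, 12))
    tr <- tr[-(5:7), ]                      # 3-frame hole
    expect_warning(traj <- leadingEdgeTrajectory(tr, surf, ph), "gaps")
    expect_equal(max(traj$segment), 2)
})

test_that("fate classification matches hand-built definitional cases", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- cylSurface(ph)
    dt <- 20
    nEnd <- 360                              # 2 h at 20 s
    tEnd <- nEnd * dt

    # arrested from t = 0 through the whole window
    s <- rep(-3, nEnd + 1)
    rec <- classifyFate(leadingEdgeTrajectory(trackFromPath(ph, s), surf, ph),
                        tEnd = tEnd)
    expect_equal(rec$fate, "remain_arrested")
    expect_true(rec$right_censored)
    expect_true(rec$left_censored)

    # 40 min of arrest, then the track disappears while intravascular
    s <- rep(-3, 121)                        # frames 0..120 = 40 min
    rec <- classifyFate(leadingEdgeTrajectory(trackFromPath(ph, s), surf, ph),
                        tEnd = tEnd)
    expect_equal(rec$fate, "released")
    expect_equal(rec$event_time_min, 40, tolerance = 1e-9)

    # strict release criterion: outward drift before disappearance is
    # ambiguous ("lost"), flat termination still counts as release
    s <- c(rep(-4, 100), seq(-4, -0.5, length.out = 10))
    recStrict <- classifyFate(leadingEdgeTrajectory(trackFromPath(ph, s),
                                                    surf, ph),
                              tEnd = tEnd, requireInward = TRUE)
    expect_equal(recStrict$status, "lost")
    s2 <- rep(-4, 100)
    recFlat <- classifyFate(leadingEdgeTrajectory(trackFromPath(ph, s2),
                                                  surf, ph),
                            tEnd = tEnd, requireInward = TRUE)
    expect_equal(recFlat$fate, "released")

    # never arrested: fast wall motion for the whole (short) track
    fast <- trackFromPath(ph, rep(-3, 30))
    fast$y_um <- fast$y_um + seq(0, by = 4, length.out = 30)  # 12 um/min
    rec <- classifyFate(leadingEdgeTrajectory(fast, surf, ph), tEnd = tEnd)
    expect_equal(rec$status, "never_arrested")

    # arrest then sustained crossing of the extravasation margin
    s <- c(rep(-3, 90), seq(-3, 9, length.out = 30), rep(9, 60))
    rec <- classifyFate(leadingEdgeTrajectory(trackFromPath(ph, s), surf, ph),
                        tEnd = tEnd)
    expect_equal(rec$fate, "extravasated")
    expect_false(rec$right_censored)
})

test_that("event times are stable under frame-interval refinement", {
    ph <- cylinderPhantom(cd11c = FALSE)
    surf <- cylSurface(ph)
    path <- function(t_min) {            # continuous leading-edge path
        ifelse(t_min < 30, -3,
               ifelse(t_min < 40, -3 + (t_min - 30) * 1.1, 8))
    }
    recs <- lapply(c(20, 10), function(dt) {
        tm <- seq(0, 80, by = dt / 60)
        tr <- trackFromPath(ph, path(tm), dt = dt)
        classifyFate(leadingEdgeTrajectory(tr, surf, ph), tEnd = 80 * 60)
    })
    expect_equal(recs[[1]]$fate, recs[[2]]$fate)
    expect_lt(abs(recs[[1]]$event_time_min - recs[[2]]$event_time_min),
              20 / 60 + 1e-9)
    expect_lt(abs(recs[[1]]$arrest_start_min - recs[[2]]$arrest_start_min),
              20 / 60 + 1e-9)
})

test_that("classifier recovers generator fate labels on uncensored tracks", {
    bundle <- smallBundle(1L)
    kp <- kineticsPreset("fig1_kinetics", seed = 17L, frac_left_censored = 0.3)
    tr <- generateTracks(kp, bundle, nTracks = 500L)
    recs <- classifyFates(tr$tracks, bundle$surface, bundle$phantom)
    m <- merge(recs, tr$ground_truth, by = "track_id")
    cl <- m[m$status == "classified", ]
    expect_gt(nrow(cl) / nrow(m), 0.95)
    expect_gt(mean(cl$fate.x == cl$fate.y), 0.95)
})

test_that("fates partition and frequencies sum to one per stratum", {
    bundle <- smallBundle(1L)
    trA <- generateTracks(kineticsPreset("fig1_kinetics", seed = 19L),
                          bundle, nTracks = 120L)
    trM <- generateTracks(kineticsPreset("fig1_kinetics_mild", seed = 19L),
                          bundle, nTracks = 120L)
    trM$tracks$track_id <- trM$tracks$track_id + 1000L
    tracks <- rbind(trA$tracks, trM$tracks)
    recs <- classifyFates(tracks, bundle$surface, bundle$phantom)
    s <- summarizeKinetics(recs)
    agg <- tapply(s$frequencies$freq, s$frequencies$infiltration, sum)
    expect_true(all(abs(agg - 1) < 1e-12))
    mildRow <- s$frequencies[s$frequencies$infiltration == "mild" &
                             s$frequencies$fate == "extravasated", ]
    expect_equal(mildRow$n, 0L)
})

test_that("left-censoring biases the estimated medians downward", {
    bundle <- smallBundle(1L)
    kp <- kineticsPreset("fig1_kinetics", seed = 23L,
                         frac_left_censored = 0.6)
    tr <- generateTracks(kp, bundle, nTracks = 600L)
    recs <- classifyFates(tr$tracks, bundle$surface, bundle$phantom)
    s <- summarizeKinetics(recs)
    expect_lt(s$median_release_time, kp$median_release_time)
    expect_lt(s$median_extravasation_time, kp$median_extravasation_time)
})
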