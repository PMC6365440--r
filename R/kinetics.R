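#' Leading-edge distance trajectory of one track
#'
#' Converts a track's per-frame positions into a signed-distance time series
#' against the vascular surface (negative intravascular, positive
#' parenchymal), the representation in which arrest, release and completed
#' extravasation are defined. Frame gaps longer than two frame intervals
#' split the trajectory into segments with a warning.
#'
#' @param track data.frame for a single track with columns \code{t_seconds},
#'   \code{x_um}, \code{y_um}, \code{z_um} (a \code{frame} column is kept if
#'   present).
#' @param surface a [VascularSurface-class].
#' @param lumenMask logical 3D lumen array or an [IsletPhantom-class].
#' @return the track ordered by time with columns \code{dist_um} (signed
#'   leading-edge distance) and \code{segment}.
#' @export
leadingEdgeTrajectory <- function(track, surface, lumenMask) {
    stopifnot(all(c("t_seconds", "x_um", "y_um", "z_um") %in% names(track)))
    track <- track[order(track$t_seconds), , drop = FALSE]
    pts <- as.matrix(track[, c("x_um", "y_um", "z_um")])
    track$dist_um <- distanceToSurface(pts, surface, lumenMask)
    dtv <- diff(track$t_seconds)
    dt <- if (length(dtv)) min(dtv) else 0
    seg <- cumsum(c(1, dtv > 2 * dt + 1e-9))
    if (max(seg) > 1L)
        warning("track has frame gaps > 2 frames; split into ",
                max(seg), " segments")
    track$segment <- seg
    track
}

#' Classify the fate of one arrested-cell trajectory
#'
#' Arrest is an instantaneous 3D speed below \code{arrestSpeedThreshold}
#' sustained for at least \code{minArrestDuration}. From arrest onward the
#' cell either completes extravasation (signed distance above
#' \code{extravasationMargin} for \code{persistence} consecutive frames;
#' event time at the first frame of that run), releases back into flow (the
#' track terminates before the end of the observation window while the
#' signed distance is still negative; event time at the last frame), or
#' remains arrested (right-censored). Tracks already arrested in the first
#' frame of the session are flagged left-censored. A track that never
#' arrests is excluded with status \code{"never_arrested"}; a track that
#' disappears at positive distance without completing is status
#' \code{"lost"}.
#'
#' @param trajectory output of [leadingEdgeTrajectory()] (first segment used).
#' @param arrestSpeedThreshold um/min (default 2).
#' @param minArrestDuration minutes (default 2).
#' @param extravasationMargin um (default 5, about one cell radius: the cell
#'   body has cleared the wall).
#' @param persistence frames the margin must be exceeded (default 3).
#' @param tEnd end of the observation window in seconds (default: last frame
#'   time across the session; pass explicitly when classifying single tracks
#'   so termination can be told apart from session end).
#' @param requireInward stricter release criterion: additionally demand net
#'   inward motion (decreasing signed distance) over the final three frames
#'   before termination (default FALSE: termination while intravascular
#'   suffices, mirroring the observable of a cell swept away by flow).
#' @return one-row data.frame: \code{track_id} (if present), \code{status}
#'   ("classified", "never_arrested" or "lost"), \code{fate},
#'   \code{arrest_start_min}, \code{event_time_min}, \code{left_censored},
#'   \code{right_censored}.
#' @export
classifyFate <- function(trajectory, arrestSpeedThreshold = 2,
                         minArrestDuration = 2, extravasationMargin = 5,
                         persistence = 3L, tEnd = NULL,
                         requireInward = FALSE) {
    if (nrow(trajectory) < 2L) stop("trajectory needs at least 2 frames")
    if ("segment" %in% names(trajectory))
        trajectory <- trajectory[trajectory$segment == trajectory$segment[1L], ,
                                 drop = FALSE]
    tt <- trajectory$t_seconds
    if (is.null(tEnd)) tEnd <- max(tt)
    dt <- min(diff(tt))
    pts <- as.matrix(trajectory[, c("x_um", "y_um", "z_um")])
    step <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
    speed <- step / (diff(tt) / 60)        # um/min
    slow <- speed < arrestSpeedThreshold   # step i-1 -> i is slow
    need <- max(1L, ceiling(minArrestDuration * 60 / dt))
    runs <- rle(slow)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- which(runs$values & runs$lengths >= need)
    id <- trajectory$track_id[1L]
    if (is.null(id)) id <- NA_integer_
    if (!length(ok)) {
        return(data.frame(track_id = id, status = "never_arrested",
                          fate = NA_character_, arrest_start_min = NA_real_,
                          event_time_min = NA_real_, left_censored = NA,
                          right_censored = NA))
    }
    aIdx <- starts[ok[1L]]                 # first frame of the slow run
    arrestStart <- tt[aIdx]
    leftCens <- aIdx == 1L && tt[1L] <= dt / 2

    dist <- trajectory$dist_um
    after <- seq(aIdx, nrow(trajectory))
    above <- dist[after] > extravasationMargin
    runs2 <- rle(above)
    ends2 <- cumsum(runs2$lengths)
    starts2 <- ends2 - runs2$lengths + 1L
    ok2 <- which(runs2$values & runs2$lengths >= persistence)
    if (length(ok2)) {
        evIdx <- after[starts2[ok2[1L]]]
        return(data.frame(track_id = id, status = "classified",
                          fate = "extravasated",
                          arrest_start_min = arrestStart / 60,
                          event_time_min = (tt[evIdx] - arrestStart) / 60,
                          left_censored = leftCens, right_censored = FALSE))
    }
    terminated <- max(tt) < tEnd - 1.5 * dt
    inwardOk <- if (!requireInward || length(dist) < 4L) TRUE
        else {
            tail4 <- dist[(length(dist) - 3L):length(dist)]
            (tail4[4L] - tail4[1L]) <= 0
        }
    if (terminated && dist[length(dist)] < 0 && inwardOk) {
        return(data.frame(track_id = id, status = "classified",
                          fate = "released",
                          arrest_start_min = arrestStart / 60,
                          event_time_min = (max(tt) - arrestStart) / 60,
                          left_censored = leftCens, right_censored = FALSE))
    }
    if (terminated) {
        return(data.frame(track_id = id, status = "lost",
                          fate = NA_character_,
                          arrest_start_min = arrestStart / 60,
                          event_time_min = NA_real_,
                          left_censored = leftCens, right_censored = NA))
    }
    data.frame(track_id = id, status = "classified",
               fate = "remain_arrested", arrest_start_min = arrestStart / 60,
               event_time_min = NA_real_, left_censored = leftCens,
               right_censored = TRUE)
}

#' Classify fates for a whole track table
#'
#' Convenience wrapper: computes leading-edge trajectories and fate records
#' for every track in a session table.
#'
#' @param tracks data.frame as produced by [generateTracks()] (columns
#'   track_id, t_seconds, x_um, y_um, z_um; optional infiltration).
#' @param surface a [VascularSurface-class].
#' @param lumenMask lumen array or [IsletPhantom-class].
#' @param ... thresholds passed to [classifyFate()].
#' @return data.frame of per-track fate records (excluded tracks keep their
#'   status), with the track's infiltration category carried through.
#' @export
classifyFates <- function(tracks, surface, lumenMask, ...) {
    tEnd <- max(tracks$t_seconds)
    recs <- lapply(split(tracks, tracks$track_id), function(tr) {
        traj <- leadingEdgeTrajectory(tr, surface, lumenMask)
        rec <- classifyFate(traj, tEnd = tEnd, ...)
        if ("infiltration" %in% names(tr))
            rec$infiltration <- tr$infiltration[1L]
        rec
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
}

#' Summarize fate frequencies and event-time medians
#'
#' Frequencies are over classified tracks and sum to one within each
#' infiltration stratum; medians are computed over cells whose event was
#' observed (censored cells excluded), and are therefore underestimates in
#' the presence of left-censoring.
#'
#' @param records data.frame from [classifyFates()] / [classifyFate()].
#' @return list with \code{frequencies} (data.frame: infiltration, fate,
#'   n, freq), \code{median_release_time},
#'   \code{median_extravasation_time} (minutes), \code{n_classified}.
#' @export
summarizeKinetics <- function(records) {
    if (!nrow(records)) stop("no fate records to summarize")
    cl <- records[records$status == "classified", , drop = FALSE]
    if (!"infiltration" %in% names(cl)) cl$infiltration <- "all"
    freq <- do.call(rbind, lapply(split(cl, cl$infiltration), function(g) {
        tab <- table(factor(g$fate, levels = c("remain_arrested", "released",
                                               "extravasated")))
        data.frame(infiltration = g$infiltration[1L],
                   fate = names(tab), n = as.integer(tab),
                   freq = as.numeric(tab) / nrow(g))
    }))
    rownames(freq) <- NULL
    rel <- cl$event_time_min[cl$fate == "released"]
    ext <- cl$event_time_min[cl$fate == "extravasated"]
    list(frequencies = freq,
         median_release_time = if (length(rel)) stats::median(rel) else NA_real_,
         median_extravasation_time = if (length(ext)) stats::median(ext)
                                     else NA_real_,
         n_classified = nrow(cl))
}
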