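#' Detect puncta in one movie frame
#'
#' Applies the same detector contract as \code{\link{detectFixedPuncta}} to a
#' single frame: median background and MAD robust SD over the cluster mask,
#' threshold at background + \code{thresholdK} x MAD, connected components of
#' at least \code{minAreaPx} pixels.
#'
#' @param frame numeric intensity matrix.
#' @param clusterMask logical matrix, same shape as \code{frame}.
#' @param thresholdK threshold in robust SDs (default 3).
#' @param minAreaPx minimum component area (default 4).
#' @param pixelSize microns per pixel (for the reported max lengths).
#' @return data.frame of detections: centroid \code{row}, \code{col},
#'   \code{area_px}, \code{max_length_um}.
#' @export
detectPunctaFrame <- function(frame, clusterMask, thresholdK = 3,
                              minAreaPx = 4, pixelSize = 1) {
    if (!identical(dim(frame), dim(clusterMask)))
        stop("frame and mask must have the same shape")
    detectPunctaCore(frame, clusterMask, thresholdK, minAreaPx, pixelSize)
}

#' Detect puncta in every frame of a time-lapse
#'
#' @param movie a \linkS4class{TimeLapse}.
#' @param thresholdK,minAreaPx detector parameters (see
#'   \code{\link{detectPunctaFrame}}).
#' @return list of per-frame detection data.frames, ordered by frame.
#' @export
detectPunctaMovie <- function(movie, thresholdK = 3, minAreaPx = 4) {
    stopifnot(is(movie, "TimeLapse"))
    lapply(seq_len(nFrames(movie)), function(t)
        detectPunctaFrame(getFrame(movie, t), movie@clusterMask,
                          thresholdK, minAreaPx, pixelSize(movie)))
}

#' Link per-frame detections into gapless punctum tracks
#'
#' Greedy nearest-neighbour association between consecutive frames: the
#' closest (track, detection) pair within \code{maxLinkDistPx} is linked
#' first, then the next closest among the remaining, and so on; ties are
#' broken by the smaller distance, then the lower detection index. A track
#' with no match in frame t+1 terminates at frame t -- no gap closing, so a
#' punctum's track ends the first time it is absent, matching a lifetime
#' definition that runs until the punctum disappears completely. Unmatched
#' detections start new tracks; tracks reaching the final frame are censored.
#'
#' @param detections list of per-frame detection data.frames (from
#'   \code{\link{detectPunctaMovie}}), ordered by frame.
#' @param frameInterval seconds between frames.
#' @param maxLinkDistPx association gate in pixels (default 4).
#' @return a \linkS4class{PunctumTrackSet}.
#' @export
linkTracks <- function(detections, frameInterval = 30, maxLinkDistPx = 4) {
    T <- length(detections)
    active <- list()     # each: list(first, cents (kx2), last_pos)
    done <- list()
    for (t in seq_len(T)) {
        det <- detections[[t]]
        nd <- if (is.null(det)) 0L else nrow(det)
        assigned <- logical(nd)
        survivors <- list()
        if (length(active) && nd) {
            heads <- do.call(rbind, lapply(active, function(a) a$last_pos))
            dmat <- sqrt(outer(heads[, 1], det$row, "-")^2 +
                         outer(heads[, 2], det$col, "-")^2)
            dmat[dmat > maxLinkDistPx] <- Inf
            trackUsed <- logical(length(active))
            repeat {
                if (!any(is.finite(dmat))) break
                best <- Inf; bi <- 0L; bj <- 0L
                for (j in seq_len(nd)) {          # lower detection index wins ties
                    for (i in seq_along(active)) {
                        if (is.finite(dmat[i, j]) && dmat[i, j] < best) {
                            best <- dmat[i, j]; bi <- i; bj <- j
                        }
                    }
                }
                if (bi == 0L) break
                a <- active[[bi]]
                a$cents <- rbind(a$cents, c(det$row[bj], det$col[bj]))
                a$last_pos <- c(det$row[bj], det$col[bj])
                survivors[[length(survivors) + 1L]] <- a
                trackUsed[bi] <- TRUE; assigned[bj] <- TRUE
                dmat[bi, ] <- Inf; dmat[, bj] <- Inf
            }
            for (i in seq_along(active))
                if (!trackUsed[i]) done[[length(done) + 1L]] <- active[[i]]
        } else if (length(active)) {
            done <- c(done, active)
        }
        if (nd) {
            for (j in seq_len(nd)) {
                if (!assigned[j]) {
                    survivors[[length(survivors) + 1L]] <-
                        list(first = t,
                             cents = matrix(c(det$row[j], det$col[j]), 1L),
                             last_pos = c(det$row[j], det$col[j]))
                }
            }
        }
        active <- survivors
    }
    censoredTracks <- active                      # still alive in final frame
    buildRow <- function(a, censored) {
        nf <- nrow(a$cents)
        data.frame(first_frame = a$first, n_frames = nf,
                   lifetime_s = if (censored) NA_real_ else nf * frameInterval,
                   censored = censored)
    }
    rows <- c(lapply(done, buildRow, censored = FALSE),
              lapply(censoredTracks, buildRow, censored = TRUE))
    cents <- c(lapply(done, `[[`, "cents"), lapply(censoredTracks, `[[`, "cents"))
    if (length(rows)) {
        tab <- do.call(rbind, rows)
        ord <- order(tab$first_frame, tab$n_frames)
        tab <- tab[ord, , drop = FALSE]
        cents <- cents[ord]
        tab <- cbind(track_id = seq_len(nrow(tab)), tab)
        rownames(tab) <- NULL
    } else {
        tab <- data.frame(track_id = integer(0), first_frame = integer(0),
                          n_frames = integer(0), lifetime_s = numeric(0),
                          censored = logical(0))
    }
    new("PunctumTrackSet", tracks = tab, centroids = cents,
        frameInterval = frameInterval)
}

#' Punctum lifetimes and their mean
#'
#' A punctum's lifetime is the elapsed time from when it first appears to
#' when it first disappears completely: \code{n_frames x frameInterval}, so a
#' punctum visible in a single 30 s frame has lifetime 30 s, not 0. Censored
#' tracks (present in the final frame) are excluded from the mean, and their
#' count is reported.
#'
#' @param trackSet a \linkS4class{PunctumTrackSet} (or its tracks
#'   data.frame).
#' @param frameInterval seconds between frames; defaults to the track set's
#'   own interval.
#' @return list: \code{lifetimes_s} (uncensored, seconds),
#'   \code{mean_lifetime_s}, \code{n_uncensored}, \code{n_censored}.
#' @export
computeLifetimes <- function(trackSet, frameInterval = NULL) {
    if (is(trackSet, "PunctumTrackSet")) {
        if (is.null(frameInterval)) frameInterval <- trackSet@frameInterval
        tr <- tracks(trackSet)
    } else {
        tr <- trackSet
        if (is.null(frameInterval)) stop("frameInterval required for a plain table")
    }
    unc <- tr[!tr$censored, , drop = FALSE]
    if (nrow(unc) == 0L) stop("no complete lifetimes: all tracks are censored")
    lt <- unc$n_frames * frameInterval
    list(lifetimes_s = lt, mean_lifetime_s = mean(lt),
         n_uncensored = nrow(unc), n_censored = sum(tr$censored))
}

#' Full detect-link-lifetime chain on a movie
#'
#' @param movie a \linkS4class{TimeLapse}.
#' @param thresholdK,minAreaPx detector parameters.
#' @param maxLinkDistPx linker gate, px.
#' @return list as from \code{\link{computeLifetimes}}, plus the
#'   \code{trackSet}.
#' @export
trackPunctaLifetimes <- function(movie, thresholdK = 3, minAreaPx = 4,
                                 maxLinkDistPx = 4) {
    det <- detectPunctaMovie(movie, thresholdK, minAreaPx)
    ts <- linkTracks(det, frameInterval(movie), maxLinkDistPx)
    out <- computeLifetimes(ts)
    out$trackSet <- ts
    out
}
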