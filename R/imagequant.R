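# bilinear interpolation of matrix m at (row, col) positions
bilinear <- function(m, r, c) {
    r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
    r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
    fr <- r - r0; fc <- c - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
        m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
        m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
        m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Membrane pMRLC/phalloidin ratio along a line profile
#'
#' Samples both channels along a line segment at ~1 px spacing with bilinear
#' interpolation, smooths each profile with a moving average, locates the
#' pMRLC intensity peak, and reads the phalloidin intensity at the same
#' sample position. The ratio pMRLC peak / phalloidin-at-peak normalizes
#' staining intensity to F-actin at the same membrane point.
#'
#' @param image a \linkS4class{FollicleImage} with channels \code{pmrlc} and
#'   \code{phalloidin}.
#' @param line 2 x 2 numeric matrix: rows are the segment endpoints, columns
#'   are (row, col) pixel coordinates (1-based).
#' @param smoothWindow moving-average width in samples (default 3).
#' @return list of class \code{"lineProfileMeasurement"}: \code{endpoints},
#'   \code{peak_index}, \code{peak_pmrlc}, \code{phalloidin_at_peak},
#'   \code{ratio}.
#' @export
measureMembraneRatio <- function(image, line, smoothWindow = 3) {
    stopifnot(is(image, "FollicleImage"))
    if (!all(c("pmrlc", "phalloidin") %in% channelNames(image)))
        stop("image must carry 'pmrlc' and 'phalloidin' channels")
    line <- as.matrix(line)
    if (!identical(dim(line), c(2L, 2L))) stop("line must be a 2 x 2 endpoint matrix")
    d <- dim(channel(image, "pmrlc"))
    if (any(line[, 1] < 1) || any(line[, 1] > d[1]) ||
        any(line[, 2] < 1) || any(line[, 2] > d[2]))
        stop("line endpoints outside the image")
    len <- sqrt(sum((line[2, ] - line[1, ])^2))
    nSamp <- max(2L, ceiling(len) + 1L)
    if (nSamp < smoothWindow) stop("line shorter than the smoothing window")
    t <- seq(0, 1, length.out = nSamp)
    r <- line[1, 1] + t * (line[2, 1] - line[1, 1])
    c <- line[1, 2] + t * (line[2, 2] - line[1, 2])
    pm <- movingAverage(bilinear(channel(image, "pmrlc"), r, c), smoothWindow)
    ph <- movingAverage(bilinear(channel(image, "phalloidin"), r, c), smoothWindow)
    i <- which.max(pm)
    if (ph[i] == 0) stop("undefined ratio: phalloidin is zero at the pMRLC peak")
    structure(list(endpoints = line, peak_index = i, peak_pmrlc = pm[i],
                   phalloidin_at_peak = ph[i], ratio = pm[i] / ph[i]),
              class = "lineProfileMeasurement")
}

#' @export
print.lineProfileMeasurement <- function(x, ...) {
    cat(sprintf("line profile: pMRLC peak %.2f / phalloidin %.2f = ratio %.4f\n",
        x$peak_pmrlc, x$phalloidin_at_peak, x$ratio))
    invisible(x)
}

#' Per-follicle membrane score: mean of three line-profile ratios
#'
#' Three line measurements are taken across nurse-cell membranes per follicle
#' and their pMRLC/phalloidin peak ratios averaged into a single score.
#'
#' @param image a \linkS4class{FollicleImage}.
#' @param lines list of exactly 3 line endpoint matrices
#'   (see \code{\link{measureMembraneRatio}}).
#' @param smoothWindow moving-average width passed to each measurement.
#' @return the mean ratio (a single number). Any failing line aborts the
#'   follicle with an error, so a flagged follicle yields no score.
#' @export
follicleMembraneScore <- function(image, lines, smoothWindow = 3) {
    if (length(lines) != 3L) stop("exactly 3 membrane lines are required")
    ratios <- vapply(lines, function(l)
        measureMembraneRatio(image, l, smoothWindow)$ratio, numeric(1))
    mean(ratios)
}

#' Normalize per-follicle scores to a control group
#'
#' Divides each score by the mean of the control scores from the same
#' experimental batch, so that the control group's normalized mean is exactly
#' 1. Batches must be normalized independently (each against its own
#' control), not against a pooled control.
#'
#' @param scores numeric vector of per-follicle scores.
#' @param controlScores numeric vector of control-group scores from the same
#'   batch (non-empty, positive mean).
#' @return normalized scores.
#' @export
normalizeToControl <- function(scores, controlScores) {
    if (length(controlScores) == 0L) stop("control group is empty")
    m <- mean(controlScores)
    if (!is.finite(m) || m <= 0) stop("control mean must be positive")
    scores / m
}

#' Cluster/cytoplasm pMRLC ratio
#'
#' Mean pMRLC intensity over the border cell cluster mask divided by the mean
#' over an identically shaped mask translated into the nurse cell cytoplasm.
#' Using the same shape for numerator and denominator makes the measurement
#' robust to the region's size and form.
#'
#' @param image a \linkS4class{FollicleImage} with a \code{pmrlc} channel.
#' @param clusterMask logical matrix (defaults to the image's \code{cluster}
#'   mask).
#' @param cytoplasmOffsetPx integer c(row, col) translation moving the mask
#'   into cytoplasm.
#' @return list of class \code{"clusterMeasurement"}: \code{ratio},
#'   \code{mean_pmrlc_cluster}, \code{mean_pmrlc_cytoplasm},
#'   \code{offset_px}.
#' @export
clusterPmrlcRatio <- function(image, clusterMask = imageMask(image, "cluster"),
                              cytoplasmOffsetPx = c(0L, -95L)) {
    stopifnot(is(image, "FollicleImage"))
    if (is.null(clusterMask)) stop("no cluster mask supplied")
    pm <- channel(image, "pmrlc")
    if (!identical(dim(clusterMask), dim(pm)))
        stop("cluster mask shape does not match the image")
    idx <- which(clusterMask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("no cluster: mask is empty")
    tr <- idx
    tr[, 1] <- tr[, 1] + cytoplasmOffsetPx[1]
    tr[, 2] <- tr[, 2] + cytoplasmOffsetPx[2]
    if (any(tr[, 1] < 1 | tr[, 1] > nrow(pm) | tr[, 2] < 1 | tr[, 2] > ncol(pm)))
        stop("invalid cytoplasm placement: translated mask out of bounds")
    mem <- imageMask(image, "membranes")
    if (!is.null(mem) && any(mem[tr]))
        stop("invalid cytoplasm placement: translated mask overlaps membranes")
    mc <- mean(pm[idx]); my <- mean(pm[tr])
    structure(list(ratio = mc / my, mean_pmrlc_cluster = mc,
                   mean_pmrlc_cytoplasm = my, offset_px = cytoplasmOffsetPx),
              class = "clusterMeasurement")
}

#' @export
print.clusterMeasurement <- function(x, ...) {
    cat(sprintf("cluster/cytoplasm pMRLC ratio: %.4f (cluster %.2f / cytoplasm %.2f)\n",
        x$ratio, x$mean_pmrlc_cluster, x$mean_pmrlc_cytoplasm))
    invisible(x)
}

# core threshold + connected-component punctum detector, shared between the
# fixed-image and per-frame paths
detectPunctaCore <- function(frame, mask, thresholdK, minAreaPx, pixelSize) {
    if (is.null(mask) || !any(mask)) stop("no cluster: mask is empty")
    vals <- frame[mask]
    bg <- stats::median(vals)
    rsd <- stats::mad(vals)
    # noiseless backgrounds have zero MAD; fall back to the plain SD so the
    # threshold still scales with thresholdK
    if (rsd == 0) rsd <- stats::sd(vals)
    binary <- mask & (frame > bg + thresholdK * rsd)
    lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
    labm <- EBImage::imageData(lab)
    ids <- setdiff(unique(as.vector(labm)), 0)
    out <- data.frame(row = numeric(0), col = numeric(0), area_px = integer(0),
                      max_length_um = numeric(0))
    for (id in ids) {
        px <- which(labm == id, arr.ind = TRUE)
        if (nrow(px) < minAreaPx) next
        feret <- if (nrow(px) == 1L) 0 else max(stats::dist(px))
        out <- rbind(out, data.frame(row = mean(px[, 1]), col = mean(px[, 2]),
                                     area_px = nrow(px),
                                     max_length_um = feret * pixelSize))
    }
    rownames(out) <- NULL
    out
}

#' Detect pMRLC puncta on the border cell cluster of a fixed image
#'
#' Automated substitute for manual punctum counting: the background is the
#' median pMRLC intensity over the cluster mask and the robust SD its MAD;
#' pixels exceeding background + \code{thresholdK} x MAD form candidate
#' puncta; connected components of at least \code{minAreaPx} pixels are
#' retained. Each punctum's maximum length is its Feret diameter (largest
#' pairwise distance between member pixel centers) converted to microns.
#'
#' @param image a \linkS4class{FollicleImage}.
#' @param clusterMask logical matrix (defaults to the image's cluster mask).
#' @param thresholdK threshold in robust SDs above background (default 3).
#' @param minAreaPx minimum component area in pixels (default 4).
#' @return data.frame with one row per punctum: centroid \code{row},
#'   \code{col}, \code{area_px}, \code{max_length_um}. The punctum count is
#'   \code{nrow()} of the result.
#' @export
detectFixedPuncta <- function(image, clusterMask = imageMask(image, "cluster"),
                              thresholdK = 3, minAreaPx = 4) {
    stopifnot(is(image, "FollicleImage"))
    detectPunctaCore(channel(image, "pmrlc"), clusterMask, thresholdK,
                     minAreaPx, pixelSize(image))
}

#' Migration index of a Stage 9 follicle
#'
#' Border cell migration distance divided by the outer follicle cell front
#' distance, both measured from the anterior pole. A value of about 1 means
#' the border cell cluster has kept pace with the outer follicle cells
#' (on-time migration); values below 1 indicate delay, values above 1
#' accelerated migration.
#'
#' @param geom one follicle geometry record: a list or one-row data.frame
#'   with \code{border_cell_distance} and \code{follicle_cell_distance} (um).
#' @param onTimeTol half-width of the "on-time" band around 1 used for the
#'   qualitative call (default 0.05).
#' @return list of class \code{"migrationIndex"}: \code{value},
#'   \code{classification} ("on-time", "delayed", "accelerated").
#' @export
migrationIndex <- function(geom, onTimeTol = 0.05) {
    b <- geom$border_cell_distance; f <- geom$follicle_cell_distance
    stopifnotFinite(border_cell_distance = b, follicle_cell_distance = f)
    if (f <= 0) stop("follicle cell distance must be positive")
    if (b <= 0) stop("border cell distance must be positive")
    v <- b / f
    cls <- if (abs(v - 1) <= onTimeTol) "on-time"
           else if (v < 1) "delayed" else "accelerated"
    structure(list(value = v, classification = cls), class = "migrationIndex")
}

#' @export
print.migrationIndex <- function(x, ...) {
    cat(sprintf("migration index %.3f (%s)\n", x$value, x$classification))
    invisible(x)
}

#' Border cell cluster length
#'
#' Front-to-rear extent of the border cell cluster along the migration axis.
#'
#' @param geom a geometry record with \code{cluster_front} and
#'   \code{cluster_rear} (um, measured from the anterior pole).
#' @return cluster length in um.
#' @export
clusterLength <- function(geom) {
    fr <- geom$cluster_front; re <- geom$cluster_rear
    stopifnotFinite(cluster_front = fr, cluster_rear = re)
    if (fr < re) stop("cluster_front must be >= cluster_rear")
    fr - re
}
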