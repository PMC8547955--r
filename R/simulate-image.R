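#' Image scene parameters for the synthetic follicle generator
#'
#' Describes a two-channel fixed-image scene emulating a Stage 9 follicle
#' stained for pMRLC and phalloidin: a uniform cytoplasm background, bright
#' nurse-cell membrane segments (enriched in both channels, by independent
#' fold factors), an enriched border cell cluster region (pMRLC only), and
#' optionally Gaussian Myosin puncta inside the cluster. Noise is
#' signal-dependent (counting-like): sd = sqrt(noiseA x intensity).
#'
#' @param shape image shape c(rows, cols) in pixels.
#' @param pixelSize microns per pixel.
#' @param membraneSegments list of membrane line segments, each a list with
#'   \code{from = c(row, col)}, \code{to = c(row, col)} (1-based pixel
#'   coordinates) and \code{width} in px. \code{NULL} uses a default set of
#'   three nurse-cell membranes.
#' @param membraneFoldPmrlc fold enrichment of pMRLC on membranes (>= 1).
#' @param membraneFoldPhalloidin fold enrichment of phalloidin on membranes,
#'   independent of the pMRLC fold.
#' @param clusterMaskSpec cluster region, a list
#'   \code{list(type = "disc", center = c(row, col), radius = px)}.
#' @param clusterBoundaryFoldPmrlc fold enrichment of pMRLC over the cluster
#'   region (>= 1).
#' @param cytoplasmLevel named intensity vector
#'   \code{c(pmrlc = ..., phalloidin = ...)} in a.u.
#' @param channelGain common detector gain multiplying both channels.
#' @param noiseA counting-noise variance per intensity unit; 0 disables noise.
#' @param nPuncta number of Gaussian puncta rendered inside the cluster.
#' @param punctumAmp peak amplitude of each punctum (a.u., before gain).
#' @param punctumSigma punctum Gaussian sigma, px.
#' @param seed RNG seed.
#' @return validated list of class \code{"imageSceneParams"}.
#' @export
imageSceneParams <- function(shape = c(256L, 256L), pixelSize = 0.2,
                             membraneSegments = NULL,
                             membraneFoldPmrlc = 2.5,
                             membraneFoldPhalloidin = 3,
                             clusterMaskSpec = list(type = "disc",
                                                    center = c(190, 190),
                                                    radius = 20),
                             clusterBoundaryFoldPmrlc = 2,
                             cytoplasmLevel = c(pmrlc = 100, phalloidin = 150),
                             channelGain = 1, noiseA = 2,
                             nPuncta = 0L, punctumAmp = 300, punctumSigma = 1.5,
                             seed = NULL) {
    if (is.null(membraneSegments))
        membraneSegments <- list(
            list(from = c(20, 60), to = c(236, 70), width = 3),
            list(from = c(20, 130), to = c(236, 120), width = 3),
            list(from = c(60, 20), to = c(50, 236), width = 3))
    stopifnotFinite(pixelSize = pixelSize,
                    membraneFoldPmrlc = membraneFoldPmrlc,
                    membraneFoldPhalloidin = membraneFoldPhalloidin,
                    clusterBoundaryFoldPmrlc = clusterBoundaryFoldPmrlc,
                    cytoplasmLevel = cytoplasmLevel, channelGain = channelGain,
                    noiseA = noiseA, punctumAmp = punctumAmp,
                    punctumSigma = punctumSigma)
    if (membraneFoldPmrlc < 1 || membraneFoldPhalloidin < 1 ||
        clusterBoundaryFoldPmrlc < 1)
        stop("fold factors represent enrichment and must be >= 1")
    if (any(cytoplasmLevel < 0) || channelGain <= 0 || noiseA < 0)
        stop("intensities must be >= 0, gain > 0, noiseA >= 0")
    if (!all(c("pmrlc", "phalloidin") %in% names(cytoplasmLevel)))
        stop("cytoplasmLevel needs named entries 'pmrlc' and 'phalloidin'")
    structure(list(shape = as.integer(shape), pixelSize = pixelSize,
                   membraneSegments = membraneSegments,
                   membraneFoldPmrlc = membraneFoldPmrlc,
                   membraneFoldPhalloidin = membraneFoldPhalloidin,
                   clusterMaskSpec = clusterMaskSpec,
                   clusterBoundaryFoldPmrlc = clusterBoundaryFoldPmrlc,
                   cytoplasmLevel = cytoplasmLevel, channelGain = channelGain,
                   noiseA = noiseA, nPuncta = as.integer(nPuncta),
                   punctumAmp = punctumAmp, punctumSigma = punctumSigma,
                   seed = seed),
              class = "imageSceneParams")
}

# distance from each pixel center to a segment; returns matrix
segmentDistance <- function(shape, from, to) {
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    vx <- to[1] - from[1]; vy <- to[2] - from[2]
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((rows - from[1]) * vx + (cols - from[2]) * vy) / len2))
    sqrt((rows - (from[1] + t * vx))^2 + (cols - (from[2] + t * vy))^2)
}

# realize a mask spec into a logical matrix
maskFromSpec <- function(spec, shape) {
    if (is.logical(spec) && is.matrix(spec)) {
        if (!identical(dim(spec), as.integer(shape)))
            stop("mask shape does not match image shape")
        return(spec)
    }
    if (!is.list(spec) || is.null(spec$type))
        stop("mask spec must be a logical matrix or a list with a 'type'")
    switch(spec$type,
        disc = {
            ctr <- spec$center; r <- spec$radius
            if (ctr[1] - r < 1 || ctr[1] + r > shape[1] ||
                ctr[2] - r < 1 || ctr[2] + r > shape[2])
                stop("mask outside image bounds")
            rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
            cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
            (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
        },
        rect = {
            if (spec$rmin < 1 || spec$rmax > shape[1] ||
                spec$cmin < 1 || spec$cmax > shape[2])
                stop("mask outside image bounds")
            m <- matrix(FALSE, shape[1], shape[2])
            m[spec$rmin:spec$rmax, spec$cmin:spec$cmax] <- TRUE
            m
        },
        stop("unknown mask spec type: ", spec$type))
}

renderGaussianSpot <- function(img, center, amp, sigma) {
    ext <- ceiling(4 * sigma)
    r0 <- max(1L, floor(center[1] - ext)); r1 <- min(nrow(img), ceiling(center[1] + ext))
    c0 <- max(1L, floor(center[2] - ext)); c1 <- min(ncol(img), ceiling(center[2] + ext))
    rr <- r0:r1; cc <- c0:c1
    g <- outer(exp(-(rr - center[1])^2 / (2 * sigma^2)),
               exp(-(cc - center[2])^2 / (2 * sigma^2)))
    img[rr, cc] <- img[rr, cc] + amp * g
    img
}

#' Simulate a two-channel fixed follicle image with known ground truth
#'
#' Renders the scene described by an \code{\link{imageSceneParams}}: the pMRLC
#' channel is cytoplasm level x membrane fold (on the membrane mask) x cluster
#' fold (on the cluster mask), plus optional Gaussian puncta inside the
#' cluster; the phalloidin channel carries its own membrane enrichment and no
#' cluster signal. Both channels are multiplied by the common gain and then
#' corrupted by counting-like noise (sd = sqrt(noiseA x intensity)).
#'
#' The ground truth records the ratios a perfect measurement would return:
#' \code{membrane_ratio} (peak pMRLC over phalloidin at the same membrane
#' point) and \code{cluster_ratio} (mean noiseless pMRLC over the cluster mask
#' divided by the cytoplasm pMRLC level), both computed on the noiseless scene
#' by direct pixel arithmetic, so they are invariant to the common gain.
#'
#' @param params an \code{\link{imageSceneParams}}.
#' @return list with \code{image} (a \linkS4class{FollicleImage} with
#'   \code{cluster} and \code{membranes} masks) and \code{truth} (list:
#'   \code{membrane_ratio}, \code{cluster_ratio}, \code{n_puncta},
#'   \code{puncta} data.frame of centers).
#' @export
simulateFollicleImage <- function(params = imageSceneParams()) {
    stopifnot(inherits(params, "imageSceneParams"))
    shape <- params$shape
    memMask <- matrix(FALSE, shape[1], shape[2])
    for (seg in params$membraneSegments) {
        memMask <- memMask |
            (segmentDistance(shape, seg$from, seg$to) <= seg$width / 2)
    }
    cluMask <- maskFromSpec(params$clusterMaskSpec, shape)

    cytP <- params$cytoplasmLevel[["pmrlc"]]
    cytF <- params$cytoplasmLevel[["phalloidin"]]
    pm <- matrix(cytP, shape[1], shape[2])
    pm[memMask] <- cytP * params$membraneFoldPmrlc
    pm[cluMask] <- pm[cluMask] * params$clusterBoundaryFoldPmrlc
    ph <- matrix(cytF, shape[1], shape[2])
    ph[memMask] <- cytF * params$membraneFoldPhalloidin

    puncta <- data.frame(row = numeric(0), col = numeric(0))
    res <- withSeed(params$seed, {
        if (params$nPuncta > 0L) {
            idx <- which(cluMask)
            # keep puncta separated by more than the rendered footprint
            # (+-4 sigma square patch, hence Chebyshev distance) so each
            # stays one connected component even when a noiseless threshold
            # picks up the full Gaussian tail
            minSep <- 2 * ceiling(4 * params$punctumSigma) + 2
            rows <- numeric(0); cols <- numeric(0)
            for (i in seq_len(params$nPuncta)) {
                for (try in 1:200) {
                    pick <- sample(idx, 1L)
                    rr <- (pick - 1L) %% shape[1] + 1L
                    cc <- (pick - 1L) %/% shape[1] + 1L
                    if (!length(rows) ||
                        min(pmax(abs(rows - rr), abs(cols - cc))) >= minSep) break
                }
                rows <- c(rows, rr); cols <- c(cols, cc)
            }
            puncta <- data.frame(row = rows, col = cols)
            for (i in seq_len(nrow(puncta)))
                pm <- renderGaussianSpot(pm, c(puncta$row[i], puncta$col[i]),
                                         params$punctumAmp, params$punctumSigma)
        }
        g <- params$channelGain
        pm <- pm * g; ph <- ph * g
        truth <- list(
            membrane_ratio = (cytP * params$membraneFoldPmrlc) /
                             (cytF * params$membraneFoldPhalloidin),
            cluster_ratio = mean(pm[cluMask]) / (cytP * g),
            n_puncta = params$nPuncta,
            puncta = puncta)
        addNoise <- function(x) {
            if (params$noiseA == 0) return(x)
            pmax(0, x + stats::rnorm(length(x), 0, sqrt(params$noiseA * pmax(x, 0))))
        }
        list(pm = matrix(addNoise(pm), shape[1], shape[2]),
             ph = matrix(addNoise(ph), shape[1], shape[2]),
             truth = truth)
    })

    img <- new("FollicleImage",
               channels = list(pmrlc = res$pm, phalloidin = res$ph),
               pixelSize = params$pixelSize,
               masks = list(cluster = cluMask, membranes = memMask))
    list(image = img, truth = res$truth)
}

#' Simulate follicle geometry records
#'
#' Draws per-follicle distance records feeding the migration-index statistic:
#' border cell cluster distance, outer follicle cell front distance, and total
#' follicle length, all measured from the anterior pole in microns, plus the
#' cluster front/rear positions. Records whose front distances exceed the
#' follicle length are rejected (dropped), as they are anatomically
#' impossible.
#'
#' @param n number of follicles.
#' @param borderFront distribution spec for the border cell distance (um):
#'   either a single number (degenerate) or
#'   \code{list(mean = ..., sd = ...)} for a normal draw.
#' @param follicleFront distribution spec for the outer follicle cell front.
#' @param follicleLength distribution spec for the follicle length.
#' @param clusterLengthSpec distribution spec for the cluster front-to-rear
#'   extent (um).
#' @param seed RNG seed.
#' @return data.frame with columns \code{border_cell_distance},
#'   \code{follicle_cell_distance}, \code{follicle_length},
#'   \code{cluster_front}, \code{cluster_rear} (um), one row per accepted
#'   follicle.
#' @export
simulateFollicleGeometry <- function(n, borderFront = list(mean = 140, sd = 25),
                                     follicleFront = list(mean = 150, sd = 15),
                                     follicleLength = list(mean = 200, sd = 20),
                                     clusterLengthSpec = 20, seed = NULL) {
    stopifnot(n >= 0)
    draw <- function(spec, n) {
        if (is.numeric(spec) && length(spec) == 1L) rep(spec, n)
        else stats::rnorm(n, spec$mean, spec$sd)
    }
    withSeed(seed, {
        bf <- draw(borderFront, n)
        ff <- draw(follicleFront, n)
        fl <- draw(follicleLength, n)
        cl <- draw(clusterLengthSpec, n)
        keep <- bf > 0 & ff > 0 & fl > 0 & bf <= fl & ff <= fl & cl >= 0 &
                cl <= bf
        data.frame(border_cell_distance = bf, follicle_cell_distance = ff,
                   follicle_length = fl, cluster_front = bf,
                   cluster_rear = bf - cl)[keep, , drop = FALSE]
    })
}
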