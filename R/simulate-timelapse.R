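#' Time-lapse simulation parameters
#'
#' Describes a movie of transient Myosin puncta on the border cell cluster:
#' puncta are born at a Poisson rate inside the cluster mask, persist an
#' integer number of consecutive frames drawn from a geometric distribution,
#' and are rendered as Gaussian spots over a noisy background. The geometric
#' draw lives on the frame grid so that its mean duration
#' (frames x frame interval) equals \code{meanLifetime} exactly, and a
#' first-present-to-first-absent tracker recovers the generator mean without
#' discretization bias.
#'
#' @param nFrames number of frames (default 121, i.e. 1 h at 30 s).
#' @param frameInterval seconds between frames (default 30 s).
#' @param birthRate expected new puncta per frame (Poisson).
#' @param meanLifetime mean punctum lifetime in seconds; must be at least
#'   \code{frameInterval} (the geometric support starts at one frame).
#' @param shape frame shape c(rows, cols), px.
#' @param clusterMaskSpec cluster region spec (see
#'   \code{\link{imageSceneParams}}) or a logical matrix.
#' @param punctumIntensity peak spot amplitude, a.u.
#' @param punctumSigma spot Gaussian sigma, px.
#' @param minSeparationPx minimum distance between temporally overlapping
#'   puncta; keeps distinct puncta resolvable by the detector and unambiguous
#'   for nearest-neighbour linking.
#' @param background uniform background level, a.u.
#' @param noiseA counting-noise variance per intensity unit (0 = noiseless).
#' @param pixelSize microns per pixel.
#' @param seed RNG seed.
#' @return validated list of class \code{"timelapseParams"}.
#' @export
timelapseParams <- function(nFrames = 121L, frameInterval = 30,
                            birthRate = 2, meanLifetime = 150,
                            shape = c(128L, 128L),
                            clusterMaskSpec = list(type = "disc",
                                                   center = c(64, 64),
                                                   radius = 48),
                            punctumIntensity = 100, punctumSigma = 1.5,
                            minSeparationPx = 10, background = 10, noiseA = 1,
                            pixelSize = 0.2, seed = NULL) {
    stopifnotFinite(frameInterval = frameInterval, birthRate = birthRate,
                    meanLifetime = meanLifetime,
                    punctumIntensity = punctumIntensity,
                    punctumSigma = punctumSigma, background = background,
                    noiseA = noiseA, pixelSize = pixelSize)
    if (nFrames < 2L) stop("nFrames must be >= 2")
    if (frameInterval <= 0) stop("frameInterval must be positive")
    if (meanLifetime < frameInterval)
        stop("meanLifetime must be >= frameInterval (puncta last >= 1 frame)")
    if (birthRate < 0) stop("birthRate must be >= 0")
    structure(list(nFrames = as.integer(nFrames), frameInterval = frameInterval,
                   birthRate = birthRate, meanLifetime = meanLifetime,
                   shape = as.integer(shape), clusterMaskSpec = clusterMaskSpec,
                   punctumIntensity = punctumIntensity,
                   punctumSigma = punctumSigma,
                   minSeparationPx = minSeparationPx, background = background,
                   noiseA = noiseA, pixelSize = pixelSize, seed = seed),
              class = "timelapseParams")
}

#' Simulate a Myosin puncta time-lapse with known ground truth
#'
#' Birth frames follow a per-frame Poisson process inside the cluster mask;
#' each punctum persists \code{G} consecutive frames where \code{G} is
#' geometric on \{1, 2, ...\} with mean \code{meanLifetime / frameInterval}.
#' A punctum still present in the final frame is flagged censored in the
#' ground truth (its full duration is unobservable). Spots are rendered as
#' fixed-position Gaussians; counting-like noise is added per pixel.
#'
#' @param params a \code{\link{timelapseParams}}.
#' @return list with \code{movie} (a \linkS4class{TimeLapse}) and
#'   \code{truth} (data.frame: \code{punctum_id}, \code{row}, \code{col},
#'   \code{birth_frame} (1-based), \code{true_frames},
#'   \code{observed_frames}, \code{censored}).
#' @export
simulateTimelapse <- function(params = timelapseParams()) {
    stopifnot(inherits(params, "timelapseParams"))
    T <- params$nFrames
    shape <- params$shape
    mask <- maskFromSpec(params$clusterMaskSpec, shape)
    maskIdx <- which(mask)
    res <- withSeed(params$seed, {
        births <- stats::rpois(T, params$birthRate)
        nTot <- sum(births)
        truth <- data.frame(punctum_id = integer(0), row = numeric(0),
                            col = numeric(0), birth_frame = integer(0),
                            true_frames = integer(0),
                            observed_frames = integer(0),
                            censored = logical(0))
        if (nTot > 0) {
            birthFrame <- rep(seq_len(T), births)
            p <- params$frameInterval / params$meanLifetime
            g <- stats::rgeom(nTot, p) + 1L
            lastFrame <- birthFrame + g - 1L
            censored <- lastFrame >= T
            observed <- pmin(g, T - birthFrame + 1L)
            endFrame <- birthFrame + observed - 1L
            # rejection-sample positions so temporally overlapping puncta
            # (within one frame of coexistence) stay resolvable and linkable
            rowC <- numeric(nTot); colC <- numeric(nTot)
            minSep2 <- params$minSeparationPx^2
            for (i in seq_len(nTot)) {
                nbr <- which(seq_len(nTot) < i &
                             birthFrame <= endFrame[i] + 1L &
                             endFrame >= birthFrame[i] - 1L)
                for (try in 1:100) {
                    pick <- sample(maskIdx, 1L)
                    rr <- (pick - 1L) %% shape[1] + 1L + stats::runif(1, -0.5, 0.5)
                    cc <- (pick - 1L) %/% shape[1] + 1L + stats::runif(1, -0.5, 0.5)
                    if (!length(nbr) ||
                        min((rowC[nbr] - rr)^2 + (colC[nbr] - cc)^2) >= minSep2)
                        break
                }
                rowC[i] <- rr; colC[i] <- cc
            }
            truth <- data.frame(punctum_id = seq_len(nTot), row = rowC,
                                col = colC, birth_frame = birthFrame,
                                true_frames = g, observed_frames = observed,
                                censored = censored)
        }
        frames <- array(params$background, dim = c(T, shape[1], shape[2]))
        for (i in seq_len(nrow(truth))) {
            fr <- truth$birth_frame[i]:(truth$birth_frame[i] +
                                        truth$observed_frames[i] - 1L)
            for (t in fr) {
                frames[t, , ] <- renderGaussianSpot(
                    frames[t, , ], c(truth$row[i], truth$col[i]),
                    params$punctumIntensity, params$punctumSigma)
            }
        }
        if (params$noiseA > 0) {
            noise <- stats::rnorm(length(frames), 0,
                                  sqrt(params$noiseA * pmax(frames, 0)))
            frames <- frames + array(noise, dim = dim(frames))
            frames[frames < 0] <- 0
        }
        list(frames = frames, truth = truth)
    })
    movie <- new("TimeLapse", frames = res$frames,
                 frameInterval = params$frameInterval,
                 pixelSize = params$pixelSize, clusterMask = mask)
    list(movie = movie, truth = res$truth)
}
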