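#' @import methods
NULL

#' ForceCurve: a single AFM approach sweep
#'
#' Container for one atomic force microscopy approach curve: piezo extension
#' \code{z} (nm, increasing toward the sample), cantilever \code{deflection}
#' (nm), and the calibrated cantilever \code{springConstant} (N/m). Optional
#' acquisition metadata (approach velocity, maximum force, simulation seed)
#' lives in \code{meta}.
#'
#' @slot z numeric vector, piezo extension in nm.
#' @slot deflection numeric vector, cantilever deflection in nm.
#' @slot springConstant numeric(1), cantilever spring constant in N/m.
#' @slot meta list of free-form acquisition metadata.
#' @export
setClass("ForceCurve",
    representation(
        z = "numeric",
        deflection = "numeric",
        springConstant = "numeric",
        meta = "list"
    ),
    prototype(meta = list())
)

setValidity("ForceCurve", function(object) {
    msg <- NULL
    if (length(object@z) != length(object@deflection))
        msg <- c(msg, "z and deflection must have equal length")
    if (length(object@z) < 50L)
        msg <- c(msg, "a force curve needs at least 50 samples")
    if (length(object@springConstant) != 1L || !is.finite(object@springConstant) ||
        object@springConstant <= 0)
        msg <- c(msg, "springConstant must be a single positive number")
    if (anyNA(object@z) || anyNA(object@deflection))
        msg <- c(msg, "z and deflection must be finite")
    if (is.unsorted(object@z))
        msg <- c(msg, "z must be non-decreasing")
    if (is.null(msg)) TRUE else msg
})

#' ForceIndentation: baseline-subtracted force versus sample indentation
#'
#' The tip-sample contact geometry extracted from a \linkS4class{ForceCurve}:
#' indentation depth \code{delta} (nm, ascending, >= 0), force (nN,
#' baseline-subtracted) and the contact point \code{contactPointZ} (nm, piezo
#' coordinate at first tip-sample contact).
#'
#' @slot delta numeric vector, indentation depth in nm (sorted ascending).
#' @slot force numeric vector, force in nN.
#' @slot contactPointZ numeric(1), contact point in the piezo z coordinate (nm).
#' @slot baseline numeric(1), pre-contact deflection mean (nm) that was removed.
#' @export
setClass("ForceIndentation",
    representation(
        delta = "numeric",
        force = "numeric",
        contactPointZ = "numeric",
        baseline = "numeric"
    )
)

setValidity("ForceIndentation", function(object) {
    msg <- NULL
    if (length(object@delta) != length(object@force))
        msg <- c(msg, "delta and force must have equal length")
    if (length(object@delta) && (is.unsorted(object@delta) || any(object@delta < 0)))
        msg <- c(msg, "delta must be sorted ascending and non-negative")
    if (length(object@contactPointZ) != 1L || !is.finite(object@contactPointZ))
        msg <- c(msg, "contactPointZ must be a single finite number")
    if (is.null(msg)) TRUE else msg
})

#' HertzFit: Young's modulus from a windowed Hertz-cone fit
#'
#' Result of a zero-intercept least-squares fit of force against the square of
#' indentation depth over a stated depth window, converted to a Young's
#' modulus through the Sneddon cone contact model.
#'
#' @slot modulus numeric(1), Young's modulus E in kPa.
#' @slot window numeric(2), the indentation window (nm) used for the fit.
#' @slot nPoints integer(1), number of in-window points.
#' @slot rss numeric(1), residual sum of squares (nN^2).
#' @slot rSquared numeric(1), coefficient of determination over the window.
#' @slot poissonSample numeric(1), Poisson's ratio assumed for the sample.
#' @slot tipModel character(1), "rigid" or "finite" tip compliance treatment.
#' @export
setClass("HertzFit",
    representation(
        modulus = "numeric",
        window = "numeric",
        nPoints = "integer",
        rss = "numeric",
        rSquared = "numeric",
        poissonSample = "numeric",
        tipModel = "character"
    )
)

setValidity("HertzFit", function(object) {
    msg <- NULL
    if (object@modulus <= 0)
        msg <- c(msg, "modulus must be positive")
    if (length(object@window) != 2L || object@window[1] >= object@window[2])
        msg <- c(msg, "window must be (lower, upper) with lower < upper")
    if (object@nPoints < 5L)
        msg <- c(msg, "a Hertz fit needs at least 5 points")
    if (is.null(msg)) TRUE else msg
})

#' StiffnessCohort: per-indentation moduli for one experimental group
#'
#' One modulus per indentation (repeated curves at one position each count as
#' one indentation), with the group label. Summary statistics are available
#' via \code{cohortMean}, \code{cohortSD} and \code{cohortN}.
#'
#' @slot label character(1) group label.
#' @slot moduli numeric vector of per-indentation Young's moduli (kPa).
#' @export
setClass("StiffnessCohort",
    representation(label = "character", moduli = "numeric")
)

setValidity("StiffnessCohort", function(object) {
    if (length(object@moduli) < 1L) "cohort must contain at least one modulus"
    else if (any(object@moduli <= 0)) "moduli must be positive"
    else TRUE
})

#' FollicleImage: registered multi-channel follicle image
#'
#' A 2-D multi-channel fluorescence image (typically a maximum projection of a
#' few confocal slices) with physical pixel size and optional binary masks
#' (border cell cluster, nurse cell membranes).
#'
#' @slot channels named list of numeric matrices sharing one shape; canonical
#'   channel names are \code{"pmrlc"} and \code{"phalloidin"}.
#' @slot pixelSize numeric(1), microns per pixel.
#' @slot masks named list of logical matrices with the channel shape
#'   (e.g. \code{cluster}, \code{membranes}).
#' @export
setClass("FollicleImage",
    representation(
        channels = "list",
        pixelSize = "numeric",
        masks = "list"
    ),
    prototype(masks = list())
)

setValidity("FollicleImage", function(object) {
    msg <- NULL
    if (length(object@channels) < 1L || is.null(names(object@channels)))
        msg <- c(msg, "channels must be a named non-empty list")
    dims <- lapply(object@channels, dim)
    if (length(unique(lapply(dims, as.integer))) > 1L)
        msg <- c(msg, "all channels must share one shape")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number (um/px)")
    for (nm in names(object@masks)) {
        m <- object@masks[[nm]]
        if (!is.logical(m) || !identical(dim(m), dims[[1L]]))
            msg <- c(msg, sprintf("mask '%s' must be logical with the channel shape", nm))
    }
    if (is.null(msg)) TRUE else msg
})

#' TimeLapse: single-channel movie of the border cell cluster
#'
#' A T x rows x cols intensity array with the acquisition frame interval
#' (seconds), pixel size (um/px) and the cluster mask inside which puncta are
#' detected.
#'
#' @slot frames numeric 3-D array, frame x row x col.
#' @slot frameInterval numeric(1), seconds between frames (30 s by default
#'   throughout the package).
#' @slot pixelSize numeric(1), microns per pixel.
#' @slot clusterMask logical matrix with the frame shape.
#' @export
setClass("TimeLapse",
    representation(
        frames = "array",
        frameInterval = "numeric",
        pixelSize = "numeric",
        clusterMask = "matrix"
    )
)

setValidity("TimeLapse", function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 3L || d[1] < 2L)
        msg <- c(msg, "frames must be a T x rows x cols array with T >= 2")
    if (object@frameInterval <= 0)
        msg <- c(msg, "frameInterval must be positive")
    if (!is.logical(object@clusterMask) ||
        !identical(dim(object@clusterMask), d[2:3]))
        msg <- c(msg, "clusterMask must be logical with the frame shape")
    if (is.null(msg)) TRUE else msg
})

#' PunctumTrackSet: linked puncta trajectories
#'
#' Tracks built by gapless nearest-neighbour linking of per-frame detections.
#' Each track covers strictly consecutive frames; a track still present in the
#' final frame is censored (its full lifetime is unobservable) and is excluded
#' from lifetime means.
#'
#' @slot tracks data.frame with columns \code{track_id}, \code{first_frame}
#'   (1-based), \code{n_frames}, \code{lifetime_s}, \code{censored}.
#' @slot centroids list (one per track) of n_frames x 2 matrices of (row, col)
#'   pixel centroids.
#' @slot frameInterval numeric(1), seconds between frames.
#' @export
setClass("PunctumTrackSet",
    representation(
        tracks = "data.frame",
        centroids = "list",
        frameInterval = "numeric"
    )
)

setValidity("PunctumTrackSet", function(object) {
    msg <- NULL
    need <- c("track_id", "first_frame", "n_frames", "lifetime_s", "censored")
    if (!all(need %in% names(object@tracks)))
        msg <- c(msg, paste("tracks must have columns:", paste(need, collapse = ", ")))
    else {
        if (any(object@tracks$n_frames < 1L))
            msg <- c(msg, "every track must span at least one frame")
        ok <- object@tracks$censored | abs(object@tracks$lifetime_s -
                 object@tracks$n_frames * object@frameInterval) < 1e-9
        if (!all(ok))
            msg <- c(msg, "uncensored lifetimes must equal n_frames * frameInterval")
    }
    if (length(object@centroids) != nrow(object@tracks))
        msg <- c(msg, "one centroid matrix per track required")
    if (is.null(msg)) TRUE else msg
})
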