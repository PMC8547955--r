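#' Accessors for ForceCurve objects
#'
#' @param x a \linkS4class{ForceCurve}.
#' @return \code{piezoZ} and \code{deflection} return numeric vectors in nm;
#'   \code{springConstant} returns the spring constant in N/m.
#' @name ForceCurve-accessors
#' @aliases piezoZ deflection springConstant
NULL

#' @rdname ForceCurve-accessors
#' @export
setMethod("piezoZ", "ForceCurve", function(x) x@z)

#' @rdname ForceCurve-accessors
#' @export
setMethod("deflection", "ForceCurve", function(x) x@deflection)

#' @rdname ForceCurve-accessors
#' @export
setMethod("springConstant", "ForceCurve", function(x) x@springConstant)

setMethod("show", "ForceCurve", function(object) {
    cat("ForceCurve with", length(object@z), "samples\n")
    cat("  z range (nm):     ", format(range(object@z)), "\n")
    cat("  spring constant:  ", object@springConstant, "N/m\n")
    if (length(object@meta))
        cat("  meta:             ", paste(names(object@meta), collapse = ", "), "\n")
})

#' Accessors for ForceIndentation objects
#'
#' @param x a \linkS4class{ForceIndentation}.
#' @return \code{indentation} returns depth in nm, \code{force} force in nN,
#'   \code{contactPointZ} the contact point in the piezo coordinate (nm).
#' @name ForceIndentation-accessors
#' @aliases indentation force contactPointZ
NULL

#' @rdname ForceIndentation-accessors
#' @export
setMethod("indentation", "ForceIndentation", function(x) x@delta)

#' @rdname ForceIndentation-accessors
#' @export
setMethod("force", "ForceIndentation", function(x) x@force)

#' @rdname ForceIndentation-accessors
#' @export
setMethod("contactPointZ", "ForceIndentation", function(x) x@contactPointZ)

setMethod("show", "ForceIndentation", function(object) {
    cat("ForceIndentation with", length(object@delta), "in-contact points\n")
    cat("  depth range (nm): ", format(range(object@delta)), "\n")
    cat("  max force (nN):   ", format(max(object@force)), "\n")
    cat("  contact point z:  ", format(object@contactPointZ), "nm\n")
})

#' Accessors for HertzFit objects
#'
#' @param x a \linkS4class{HertzFit}.
#' @return \code{modulus} returns the Young's modulus in kPa; \code{fitWindow}
#'   the indentation window (nm).
#' @name HertzFit-accessors
#' @aliases modulus fitWindow
NULL

#' @rdname HertzFit-accessors
#' @export
setMethod("modulus", "HertzFit", function(x) x@modulus)

#' @rdname HertzFit-accessors
#' @export
setMethod("fitWindow", "HertzFit", function(x) x@window)

setMethod("show", "HertzFit", function(object) {
    cat(sprintf("HertzFit: E = %.3f kPa over %g-%g nm (%d points, R2 = %.4f, %s tip)\n",
        object@modulus, object@window[1], object@window[2],
        object@nPoints, object@rSquared, object@tipModel))
})

#' Accessors for StiffnessCohort objects
#'
#' @param x a \linkS4class{StiffnessCohort}.
#' @return \code{moduli} the per-indentation moduli (kPa); \code{cohortMean}
#'   their mean; \code{cohortSD} the sample (n-1) SD, \code{NA} when n = 1;
#'   \code{cohortN} the number of indentations.
#' @name StiffnessCohort-accessors
#' @aliases cohortMean cohortSD cohortN moduli
NULL

#' @rdname StiffnessCohort-accessors
#' @export
setMethod("moduli", "StiffnessCohort", function(x) x@moduli)

#' @rdname StiffnessCohort-accessors
#' @export
setMethod("cohortMean", "StiffnessCohort", function(x) mean(x@moduli))

#' @rdname StiffnessCohort-accessors
#' @export
setMethod("cohortSD", "StiffnessCohort", function(x)
    if (length(x@moduli) >= 2L) stats::sd(x@moduli) else NA_real_)

#' @rdname StiffnessCohort-accessors
#' @export
setMethod("cohortN", "StiffnessCohort", function(x) length(x@moduli))

setMethod("show", "StiffnessCohort", function(object) {
    cat(sprintf("StiffnessCohort '%s': n = %d, mean = %.3f kPa, sd = %s kPa\n",
        object@label, cohortN(object), cohortMean(object),
        format(cohortSD(object), digits = 3)))
})

#' Accessors for FollicleImage objects
#'
#' @param x a \linkS4class{FollicleImage}.
#' @param name channel or mask name.
#' @return \code{channel} returns the named intensity matrix; \code{imageMask}
#'   the named logical mask (or \code{NULL}); \code{pixelSize} microns/pixel.
#' @name FollicleImage-accessors
#' @aliases channel channelNames pixelSize imageMask
NULL

#' @rdname FollicleImage-accessors
#' @export
setMethod("channel", "FollicleImage", function(x, name) {
    if (!name %in% names(x@channels))
        stop("no channel named '", name, "'")
    x@channels[[name]]
})

#' @rdname FollicleImage-accessors
#' @export
setMethod("channelNames", "FollicleImage", function(x) names(x@channels))

#' @rdname FollicleImage-accessors
#' @export
setMethod("pixelSize", "FollicleImage", function(x) x@pixelSize)

#' @rdname FollicleImage-accessors
#' @export
setMethod("imageMask", "FollicleImage", function(x, name) x@masks[[name]])

setMethod("show", "FollicleImage", function(object) {
    d <- dim(object@channels[[1L]])
    cat(sprintf("FollicleImage %d x %d px (%.3g um/px)\n", d[1], d[2], object@pixelSize))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
    if (length(object@masks))
        cat("  masks:   ", paste(names(object@masks), collapse = ", "), "\n")
})

#' Accessors for TimeLapse objects
#'
#' @param x a \linkS4class{TimeLapse}.
#' @param i frame index (1-based).
#' @return \code{getFrame} returns one frame as a matrix; \code{nFrames} the
#'   number of frames; \code{frameInterval} seconds between frames.
#' @name TimeLapse-accessors
#' @aliases frameInterval nFrames getFrame
NULL

#' @rdname TimeLapse-accessors
#' @export
setMethod("frameInterval", "TimeLapse", function(x) x@frameInterval)

#' @rdname TimeLapse-accessors
#' @export
setMethod("nFrames", "TimeLapse", function(x) dim(x@frames)[1L])

#' @rdname TimeLapse-accessors
#' @export
setMethod("getFrame", "TimeLapse", function(x, i) x@frames[i, , ])

#' @rdname TimeLapse-accessors
#' @export
setMethod("pixelSize", "TimeLapse", function(x) x@pixelSize)

#' @rdname TimeLapse-accessors
#' @export
setMethod("imageMask", "TimeLapse", function(x, name = "cluster") x@clusterMask)

setMethod("show", "TimeLapse", function(object) {
    d <- dim(object@frames)
    cat(sprintf("TimeLapse: %d frames of %d x %d px, every %g s\n",
        d[1], d[2], d[3], object@frameInterval))
})

#' Accessors for PunctumTrackSet objects
#'
#' @param x a \linkS4class{PunctumTrackSet}.
#' @return \code{tracks} returns the per-track data.frame (track_id,
#'   first_frame, n_frames, lifetime_s, censored).
#' @name PunctumTrackSet-accessors
#' @aliases tracks
NULL

#' @rdname PunctumTrackSet-accessors
#' @export
setMethod("tracks", "PunctumTrackSet", function(x) x@tracks)

#' @rdname PunctumTrackSet-accessors
#' @export
setMethod("frameInterval", "PunctumTrackSet", function(x) x@frameInterval)

setMethod("show", "PunctumTrackSet", function(object) {
    tr <- object@tracks
    cat(sprintf("PunctumTrackSet: %d tracks (%d censored), frame interval %g s\n",
        nrow(tr), sum(tr$censored), object@frameInterval))
})
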