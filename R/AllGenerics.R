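#' @rdname ForceCurve-accessors
#' @export
setGeneric("piezoZ", function(x) standardGeneric("piezoZ"))

#' @rdname ForceCurve-accessors
#' @export
setGeneric("deflection", function(x) standardGeneric("deflection"))

#' @rdname ForceCurve-accessors
#' @export
setGeneric("springConstant", function(x) standardGeneric("springConstant"))

#' @rdname ForceIndentation-accessors
#' @export
setGeneric("indentation", function(x) standardGeneric("indentation"))

#' @rdname ForceIndentation-accessors
#' @export
setGeneric("force", function(x) standardGeneric("force"))

#' @rdname ForceIndentation-accessors
#' @export
setGeneric("contactPointZ", function(x) standardGeneric("contactPointZ"))

#' @rdname HertzFit-accessors
#' @export
setGeneric("modulus", function(x) standardGeneric("modulus"))

#' @rdname HertzFit-accessors
#' @export
setGeneric("fitWindow", function(x) standardGeneric("fitWindow"))

#' @rdname StiffnessCohort-accessors
#' @export
setGeneric("cohortMean", function(x) standardGeneric("cohortMean"))

#' @rdname StiffnessCohort-accessors
#' @export
setGeneric("cohortSD", function(x) standardGeneric("cohortSD"))

#' @rdname StiffnessCohort-accessors
#' @export
setGeneric("cohortN", function(x) standardGeneric("cohortN"))

#' @rdname StiffnessCohort-accessors
#' @export
setGeneric("moduli", function(x) standardGeneric("moduli"))

#' @rdname FollicleImage-accessors
#' @export
setGeneric("channel", function(x, name) standardGeneric("channel"))

#' @rdname FollicleImage-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FollicleImage-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FollicleImage-accessors
#' @export
setGeneric("imageMask", function(x, name) standardGeneric("imageMask"))

#' @rdname TimeLapse-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TimeLapse-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TimeLapse-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname PunctumTrackSet-accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
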