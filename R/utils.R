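# shared helpers, not exported

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
            stop("seed must be a single finite number")
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

stopifnotFinite <- function(...) {
    vals <- list(...)
    nms <- names(vals)
    for (i in seq_along(vals)) {
        v <- vals[[i]]
        if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
            stop(sprintf("'%s' must be finite numeric", nms[i]), call. = FALSE)
    }
    invisible(TRUE)
}

# Sneddon cone prefactor in mixed units: F[nN] = coneCoef * E[kPa] * delta[nm]^2
# coneCoef = (2/pi) tan(alpha) / (1 - nu^2) * 1e-6
coneCoef <- function(halfConeAngleDeg, poisson) {
    (2 / pi) * tan(halfConeAngleDeg * pi / 180) / (1 - poisson^2) * 1e-6
}

# 1-based moving average with window w (odd); edges use truncated windows.
movingAverage <- function(x, w) {
    if (w <= 1L) return(x)
    n <- length(x)
    h <- (w - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
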