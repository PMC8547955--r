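#' Two-layer elastic sample model
#'
#' Describes a sample whose apparent Young's modulus changes smoothly with
#' indentation depth: a stiff shallow shell (the basement membrane) over a
#' softer (or stiffer) deep layer (the nurse cells). The apparent modulus
#' follows a logistic blend from \code{eShallow} to \code{eDeep} between
#' \code{blendStart} and \code{blendEnd}, so that depth windows on either side
#' of the blend see an essentially constant modulus. This mirrors how layered
#' follicle indentation data are analysed: two independent Hertz fits over a
#' shallow and a deep depth window.
#'
#' @param eShallow apparent modulus (kPa) governing small indentations.
#' @param eDeep apparent modulus (kPa) governing large indentations.
#' @param blendStart,blendEnd depth range (nm) over which the modulus blends;
#'   the defaults 150-300 nm sit between the standard 20-100 nm and
#'   310-550 nm fit windows.
#' @param poissonSample Poisson's ratio of the sample (0.5 for follicles,
#'   i.e. incompressible).
#' @return a validated list of class \code{"twoLayerSample"}.
#' @examples
#' s <- twoLayerSample(eShallow = 24.2, eDeep = 10.1)
#' @export
twoLayerSample <- function(eShallow, eDeep, blendStart = 150, blendEnd = 300,
                           poissonSample = 0.5) {
    stopifnotFinite(eShallow = eShallow, eDeep = eDeep,
                    blendStart = blendStart, blendEnd = blendEnd,
                    poissonSample = poissonSample)
    if (eShallow <= 0 || eDeep <= 0) stop("moduli must be positive")
    if (blendStart < 0 || blendStart >= blendEnd)
        stop("need 0 <= blendStart < blendEnd")
    if (poissonSample < 0 || poissonSample > 0.5)
        stop("poissonSample must lie in [0, 0.5]")
    structure(list(eShallow = eShallow, eDeep = eDeep,
                   blendStart = blendStart, blendEnd = blendEnd,
                   poissonSample = poissonSample),
              class = "twoLayerSample")
}

#' AFM probe model
#'
#' Conical (Sneddon) tip description. The default values match a standard
#' silicon nitride probe: nominal spring constant 0.12 N/m, half cone angle
#' 20 degrees, tip Poisson's ratio 0.25. \code{tipModulus = "rigid"} treats
#' the tip as infinitely stiff (the usual assumption for soft tissue); a
#' finite value (kPa) switches the Hertz fit to the reduced-modulus form.
#'
#' @param springConstant cantilever spring constant, N/m.
#' @param halfConeAngle half-opening angle of the cone, degrees.
#' @param poissonTip Poisson's ratio of the tip material.
#' @param tipModulus \code{"rigid"} or a finite tip Young's modulus in kPa.
#' @return a validated list of class \code{"afmProbe"}.
#' @export
afmProbe <- function(springConstant = 0.12, halfConeAngle = 20,
                     poissonTip = 0.25, tipModulus = "rigid") {
    stopifnotFinite(springConstant = springConstant, halfConeAngle = halfConeAngle,
                    poissonTip = poissonTip)
    if (springConstant <= 0) stop("springConstant must be positive")
    if (halfConeAngle <= 0 || halfConeAngle >= 90)
        stop("halfConeAngle must lie in (0, 90) degrees")
    if (!identical(tipModulus, "rigid")) {
        stopifnotFinite(tipModulus = tipModulus)
        if (tipModulus <= 0) stop("tipModulus must be positive (kPa) or \"rigid\"")
    }
    structure(list(springConstant = springConstant, halfConeAngle = halfConeAngle,
                   poissonTip = poissonTip, tipModulus = tipModulus),
              class = "afmProbe")
}

#' Force-curve acquisition parameters
#'
#' @param zStep piezo step, nm.
#' @param maxForce stop the approach once this force (nN) is reached; typical
#'   acquisitions use 1-5 nN.
#' @param preContactSpan length (nm) of free travel recorded before contact;
#'   the default leaves comfortably more than 30\% of the sweep pre-contact,
#'   matching the default baseline fraction of the contact-point estimator.
#' @param forceNoiseSD additive zero-mean Gaussian force noise, nN. The
#'   default is 1\% of \code{maxForce}.
#' @param seed integer RNG seed for the noise draw.
#' @return a validated list of class \code{"acquisitionParams"}.
#' @export
acquisitionParams <- function(zStep = 2, maxForce = 3, preContactSpan = 600,
                              forceNoiseSD = 0.01 * maxForce, seed = NULL) {
    stopifnotFinite(zStep = zStep, maxForce = maxForce,
                    preContactSpan = preContactSpan, forceNoiseSD = forceNoiseSD)
    if (zStep <= 0) stop("zStep must be positive")
    if (maxForce <= 0) stop("maxForce must be positive")
    if (preContactSpan < 0) stop("preContactSpan must be non-negative")
    if (forceNoiseSD < 0) stop("forceNoiseSD must be non-negative")
    structure(list(zStep = zStep, maxForce = maxForce,
                   preContactSpan = preContactSpan, forceNoiseSD = forceNoiseSD,
                   seed = seed),
              class = "acquisitionParams")
}

#' Depth-dependent apparent modulus of a two-layer sample
#'
#' Logistic blend between the shallow and deep moduli. The midpoint sits
#' slightly before the centre of the blend window and the rate is the
#' window width / 5.5; this shape keeps the mean apparent modulus over
#' depth windows on either side of the blend within 1\% of the respective
#' plateau, while staying gentle enough that the forward force
#' F = c E_app(delta) delta^2 remains monotone in depth even for a stiff
#' shell over a much softer deep layer.
#'
#' @param sample a \code{\link{twoLayerSample}}.
#' @param delta indentation depth(s), nm.
#' @return apparent modulus (kPa) at each depth.
#' @export
apparentModulus <- function(sample, delta) {
    width <- sample$blendEnd - sample$blendStart
    mid <- (sample$blendStart + sample$blendEnd) / 2 - width / 10
    rate <- width / 5.5
    w <- 1 / (1 + exp(-(delta - mid) / rate))
    sample$eShallow + (sample$eDeep - sample$eShallow) * w
}

#' Forward Sneddon-cone force at a given indentation depth
#'
#' Evaluates F(delta) = (2/pi) tan(alpha) E_app(delta) / (1 - nu^2) delta^2
#' for a conical tip on the two-layer sample, in nN for depth in nm and
#' modulus in kPa.
#'
#' @param sample a \code{\link{twoLayerSample}}.
#' @param probe an \code{\link{afmProbe}} (supplies the cone angle).
#' @param delta indentation depth(s), nm.
#' @return force in nN.
#' @export
coneForce <- function(sample, probe, delta) {
    coneCoef(probe$halfConeAngle, sample$poissonSample) *
        apparentModulus(sample, delta) * delta^2
}

#' Simulate one AFM approach force curve on a two-layer sample
#'
#' Generates a piezo sweep with a flat pre-contact baseline followed by
#' contact with the two-layer sample. In contact, the true force follows the
#' Sneddon cone model with the depth-dependent apparent modulus
#' (\code{\link{coneForce}}); the indentation at each piezo position is the
#' self-consistent solution of \code{delta + F(delta)/k = z - z0} (the
#' cantilever bends by F/k, so the tip advances less than the piezo).
#' Zero-mean Gaussian force noise is added and converted to deflection via
#' Hooke's law. The sweep stops once the true force reaches
#' \code{acq$maxForce}.
#'
#' @param sample a \code{\link{twoLayerSample}}.
#' @param probe an \code{\link{afmProbe}}.
#' @param acq an \code{\link{acquisitionParams}}; its \code{seed} drives the
#'   noise draw.
#' @return a list with elements \code{curve} (a \linkS4class{ForceCurve}) and
#'   \code{truth} (one-row data.frame: \code{e_shallow_kpa}, \code{e_deep_kpa},
#'   \code{contact_z_nm}, \code{blend_start_nm}, \code{blend_end_nm},
#'   \code{max_depth_nm}).
#' @examples
#' sim <- simulateForceCurve(twoLayerSample(24.2, 10.1), afmProbe(),
#'                           acquisitionParams(seed = 1))
#' sim$curve
#' @export
noiselessSweep <- function(sample, probe, acq) {
    k <- probe$springConstant          # N/m == nN/nm
    z0 <- acq$preContactSpan
    nPre <- max(floor(z0 / acq$zStep), 25L)
    zPre <- seq(0, by = acq$zStep, length.out = nPre + 1L)
    z0 <- zPre[length(zPre)]           # contact point lands on the grid

    # grow the in-contact sweep until the true force reaches maxForce
    zContact <- numeric(0); fTrue <- numeric(0)
    z <- z0
    d <- 0
    repeat {
        z <- z + acq$zStep
        travel <- z - z0
        # solve delta + F(delta)/k = travel by damped Newton from the
        # previous depth (the map z -> delta is smooth and monotone)
        g <- function(dd) dd + coneForce(sample, probe, dd) / k - travel
        d <- min(max(d, 0), travel)
        for (it in 1:50) {
            h <- 1e-3
            gd <- g(d)
            if (abs(gd) < 1e-12) break
            slope <- (g(d + h) - gd) / h
            step <- gd / slope
            d <- d - step
            if (d < 0 || d > travel) {    # fall back to bisection bracket
                d <- stats::uniroot(g, c(0, travel), tol = 1e-12)$root
                break
            }
            if (abs(step) < 1e-12) break
        }
        f <- coneForce(sample, probe, d)
        zContact <- c(zContact, z); fTrue <- c(fTrue, f)
        if (f >= acq$maxForce) break
        if (length(zContact) > 5e4) stop("sweep failed to reach maxForce")
    }
    maxDepth <- (zContact[length(zContact)] - z0) - fTrue[length(fTrue)] / k
    list(z = c(zPre, zContact),
         f = c(numeric(length(zPre)), fTrue),
         z0 = z0, maxDepth = maxDepth)
}

simulateForceCurve <- function(sample, probe, acq = acquisitionParams(),
                               .sweep = NULL) {
    stopifnot(inherits(sample, "twoLayerSample"), inherits(probe, "afmProbe"),
              inherits(acq, "acquisitionParams"))
    k <- probe$springConstant
    if (is.null(.sweep)) .sweep <- noiselessSweep(sample, probe, acq)
    zAll <- .sweep$z
    fAll <- .sweep$f
    z0 <- .sweep$z0
    fNoisy <- withSeed(acq$seed, fAll + if (acq$forceNoiseSD > 0)
        stats::rnorm(length(fAll), 0, acq$forceNoiseSD) else 0)
    defl <- fNoisy / k

    curve <- new("ForceCurve", z = zAll, deflection = defl, springConstant = k,
                 meta = list(max_force_nN = acq$maxForce,
                             force_noise_sd_nN = acq$forceNoiseSD,
                             seed = acq$seed))
    maxDepth <- .sweep$maxDepth
    truth <- data.frame(e_shallow_kpa = sample$eShallow,
                        e_deep_kpa = sample$eDeep,
                        contact_z_nm = z0,
                        blend_start_nm = sample$blendStart,
                        blend_end_nm = sample$blendEnd,
                        max_depth_nm = maxDepth)
    list(curve = curve, truth = truth)
}

#' Simulate a cohort of approach curves
#'
#' Convenience wrapper drawing \code{n} independent curves from one sample /
#' probe configuration, with per-curve seeds derived from \code{seed}.
#'
#' @param n number of indentations.
#' @param sample,probe,acq as in \code{\link{simulateForceCurve}}; the
#'   \code{seed} inside \code{acq} is ignored in favour of \code{seed}.
#' @param seed integer seed for the cohort.
#' @return list with \code{curves} (list of \linkS4class{ForceCurve}) and
#'   \code{truth} (data.frame, one row per curve with a \code{curve_id}).
#' @export
simulateForceCurveCohort <- function(n, sample, probe = afmProbe(),
                                     acq = acquisitionParams(), seed = 1) {
    stopifnot(n >= 1)
    seeds <- withSeed(seed, sample.int(.Machine$integer.max, n))
    sweep <- noiselessSweep(sample, probe, acq)   # shared across the cohort
    out <- vector("list", n)
    for (i in seq_len(n)) {
        a <- acq; a$seed <- seeds[i]
        out[[i]] <- simulateForceCurve(sample, probe, a, .sweep = sweep)
    }
    truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    truth <- cbind(curve_id = sprintf("curve_%03d", seq_len(n)), truth)
    list(curves = lapply(out, `[[`, "curve"), truth = truth)
}
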