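#' Estimate the tip-sample contact point of an approach curve
#'
#' Two-stage estimator. (1) Detection: baseline statistics (mean, SD) are
#' computed over the leading \code{baselineFraction} of the sweep; the contact
#' candidate is the first piezo position where deflection exceeds
#' baseline mean + \code{kSD} x baseline SD and stays above it for at least 5
#' consecutive samples. (2) Refinement: near the onset the cone model gives
#' F = a * delta^2 with delta = (z - z0) - deflection, and F = 0 before
#' contact; z0 is refined by 1-D least squares of this piecewise model over a
#' local segment spanning the baseline tail and the shallow contact region.
#' Including pre-contact points pins the kink and makes the estimate robust
#' at realistic noise.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param baselineFraction leading fraction of the sweep assumed pre-contact
#'   (default 0.3).
#' @param kSD detection threshold in baseline SDs (default 3).
#' @param refineDepth depth extent (nm) of the refinement segment. It should
#'   stay within the shallowest mechanically uniform layer so the local
#'   quadratic holds; the default 120 nm covers the standard 20-100 nm
#'   shallow fit window with a small margin.
#' @return the estimated contact point z0, nm (piezo coordinate), with an
#'   attribute \code{"sd"}: the 1-sigma uncertainty of the estimate from the
#'   local least-squares profile (0 for noiseless data). Downstream windowed
#'   fits use it to undo the attenuation bias that contact jitter induces
#'   (see \code{\link{fitHertzCone}}).
#' @export
estimateContactPoint <- function(curve, baselineFraction = 0.3, kSD = 3,
                                 refineDepth = 120) {
    stopifnot(is(curve, "ForceCurve"))
    z <- curve@z; d <- curve@deflection
    n <- length(z)
    nb <- floor(baselineFraction * n)
    if (nb < 5L) stop("no baseline: fewer than 5 pre-contact samples")
    mu <- mean(d[seq_len(nb)])
    sdb <- stats::sd(d[seq_len(nb)])
    # a flat noisy baseline has sd(x) ~ sd(diff(x))/sqrt(2); a trending
    # (already in contact) leading sweep has far larger spread
    noiseEst <- stats::sd(diff(d[seq_len(nb)])) / sqrt(2)
    if (sdb > 0 && sdb > 5 * noiseEst + 1e-12)
        stop("no baseline: leading sweep is not flat")
    eps <- max(sdb, 1e-9 * max(abs(d - mu), 1))
    thresh <- mu + kSD * eps

    above <- d > thresh
    # first index where >= 5 consecutive samples exceed the threshold
    run <- 0L; idx <- NA_integer_
    for (i in seq_len(n)) {
        run <- if (above[i]) run + 1L else 0L
        if (run == 5L) { idx <- i - 4L; break }
    }
    if (is.na(idx)) stop("no contact detected")
    if (idx <= 1L) stop("no baseline: sweep starts in contact")

    k <- curve@springConstant
    dc <- d - mu
    f <- k * dc                            # baseline-subtracted force, nN

    # Local refinement: fit the piecewise model F = a * max(0, (z-z0)-defl)^2
    # (zero before contact, Sneddon quadratic after) by least squares over a
    # segment anchored at the threshold crossing. At realistic noise the
    # crossing sits of order refineDepth late, so a segment from the baseline
    # tail to slightly past the crossing spans roughly the first refineDepth
    # nm of true contact -- inside the shallowest uniform layer, where the
    # constant-a quadratic is exact. Including pre-contact points pins the
    # kink location.
    zStep <- if (n > 1L) z[2L] - z[1L] else 1
    hi <- min(n, idx + max(10L, ceiling(0.2 * refineDepth / zStep)))
    lo <- max(1L, idx - 150L)
    seg <- lo:hi
    zS <- z[seg]; fS <- f[seg]; dS <- dc[seg]
    rssAt <- function(z0) {
        u2 <- pmax(0, (zS - z0) - dS)^2
        s4 <- sum(u2^2)
        if (s4 <= 0) return(sum(fS^2))
        a <- sum(fS * u2) / s4
        sum((fS - a * u2)^2)
    }
    lower <- max(z[lo], z[idx] - 2 * refineDepth)
    upper <- z[hi]
    z0hat <- stats::optimize(rssAt, c(lower, upper), tol = 1e-8)$minimum

    # 1-sigma uncertainty from the profile-likelihood curvature:
    # Var(z0) ~ 2 sigma^2 / RSS''(z0). sigma^2 is taken from the baseline
    # (pure measurement noise) rather than the fit residuals, which would
    # also absorb any smooth-model mismatch near the blend
    h <- zStep / 2
    curv <- (rssAt(z0hat + h) - 2 * rssAt(z0hat) + rssAt(z0hat - h)) / h^2
    sigma2 <- (k * sdb)^2
    z0sd <- if (curv > 0) sqrt(2 * sigma2 / curv) else 0
    attr(z0hat, "sd") <- z0sd
    z0hat
}

#' Convert an approach curve to force-indentation form
#'
#' Subtracts the pre-contact deflection baseline, converts deflection to force
#' through Hooke's law (F = k x deflection), and computes the sample
#' indentation depth delta = (z - z0) - deflection for every point at or
#' beyond the contact point. Points are returned sorted by depth.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param z0 contact point in the piezo coordinate (nm), e.g. from
#'   \code{\link{estimateContactPoint}} or simulation ground truth.
#' @param baselineFraction leading fraction of the sweep used for the
#'   baseline mean (default 0.3).
#' @return a \linkS4class{ForceIndentation}.
#' @export
toForceIndentation <- function(curve, z0, baselineFraction = 0.3) {
    stopifnot(is(curve, "ForceCurve"))
    z <- curve@z; d <- curve@deflection
    if (z0 < min(z) || z0 > max(z)) stop("z0 outside the sweep range")
    nb <- max(floor(baselineFraction * length(z)), 1L)
    mu <- mean(d[seq_len(nb)])
    dc <- d - mu
    delta <- (z - z0) - dc
    f <- curve@springConstant * dc
    keep <- delta >= 0
    if (sum(keep) < 10L) stop("insufficient indentation: fewer than 10 in-contact points")
    ord <- order(delta[keep])
    new("ForceIndentation", delta = delta[keep][ord], force = f[keep][ord],
        contactPointZ = z0, baseline = mu)
}

#' Windowed Hertz-cone fit of force-indentation data
#'
#' Fits the rearranged Sneddon cone model over a stated depth window by
#' zero-intercept least squares of force against depth squared (exact for the
#' model, deterministic, no initialisation). For a rigid tip the slope gives
#' the sample Young's modulus E = slope * pi * (1 - nu_s^2) / (2 tan alpha);
#' with a finite tip modulus the slope gives the reduced modulus
#' 1/E* = (1 - nu_s^2)/E_s + (1 - nu_t^2)/E_t, from which E_s is solved.
#'
#' @param fi a \linkS4class{ForceIndentation}.
#' @param window depth window c(lower, upper) in nm; the standard windows are
#'   c(20, 100) for the basement membrane and c(310, 550) for nurse cells.
#' @param samplePoisson Poisson's ratio of the sample (default 0.5).
#' @param probe an \code{\link{afmProbe}} supplying cone angle, tip Poisson's
#'   ratio and tip compliance treatment.
#' @param contactSD 1-sigma uncertainty (nm) of the contact point used to
#'   build \code{fi}. A zero-mean contact error e shifts every depth by e,
#'   which inflates the expected zero-intercept slope by the factor
#'   1 + Var(e) Sum(d^2)/Sum(d^4) over the window; the fit divides this
#'   attenuation factor back out. Matters for shallow windows (a few percent
#'   at realistic noise), negligible for deep ones. Default 0 (no
#'   correction).
#' @return a \linkS4class{HertzFit}.
#' @export
fitHertzCone <- function(fi, window, samplePoisson = 0.5, probe = afmProbe(),
                         contactSD = 0) {
    stopifnot(is(fi, "ForceIndentation"), inherits(probe, "afmProbe"))
    if (length(window) != 2L || window[1] >= window[2])
        stop("window must be c(lower, upper) with lower < upper")
    sel <- fi@delta >= window[1] & fi@delta <= window[2]
    npts <- sum(sel)
    if (npts < 5L) stop("window too sparse: fewer than 5 points in ",
                        window[1], "-", window[2], " nm")
    d2 <- fi@delta[sel]^2
    f <- fi@force[sel]
    slope <- sum(f * d2) / sum(d2^2)           # nN / nm^2
    if (slope <= 0) stop("non-physical fit: non-positive slope")
    if (contactSD > 0)
        slope <- slope / (1 + contactSD^2 * sum(d2) / sum(d2^2))

    tanA <- tan(probe$halfConeAngle * pi / 180)
    if (identical(probe$tipModulus, "rigid")) {
        e <- slope * 1e6 * pi * (1 - samplePoisson^2) / (2 * tanA)
        tipModel <- "rigid"
    } else {
        eStar <- slope * 1e6 * pi / (2 * tanA)   # reduced modulus, kPa
        inv <- 1 / eStar - (1 - probe$poissonTip^2) / probe$tipModulus
        if (inv <= 0) stop("non-physical fit: tip modulus too low for observed slope")
        e <- (1 - samplePoisson^2) / inv
        tipModel <- "finite"
    }
    res <- f - slope * d2
    rss <- sum(res^2)
    tss <- sum((f - mean(f))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    new("HertzFit", modulus = e, window = as.numeric(window),
        nPoints = as.integer(npts), rss = rss, rSquared = r2,
        poissonSample = samplePoisson, tipModel = tipModel)
}

#' Per-point closed-form modulus estimate (oracle for the windowed fit)
#'
#' Inverts the Sneddon cone model pointwise:
#' E = F pi (1 - nu^2) / (2 tan(alpha) delta^2). On noiseless single-layer
#' data every point gives the same value, equal to the windowed fit.
#'
#' @param fi a \linkS4class{ForceIndentation}.
#' @param samplePoisson Poisson's ratio of the sample.
#' @param probe an \code{\link{afmProbe}}.
#' @return numeric vector of per-point moduli (kPa); zero-depth points are NA.
#' @export
pointwiseModulus <- function(fi, samplePoisson = 0.5, probe = afmProbe()) {
    co <- coneCoef(probe$halfConeAngle, samplePoisson)
    ifelse(fi@delta > 0, fi@force / (co * fi@delta^2), NA_real_)
}

#' Analyze one curve over the shallow and deep depth windows
#'
#' Chains contact-point estimation, force-indentation conversion and both
#' windowed Hertz fits. Defaults follow the standard layered-follicle
#' protocol: shallow window 20-100 nm (basement membrane), deep window
#' 310-550 nm (nurse cells), nu_s = 0.5, alpha = 20 degrees. A failure in one
#' window (e.g. the sweep ended before reaching 310 nm depth) is reported for
#' that window while the other fit is still returned.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param shallowWindow,deepWindow depth windows, nm.
#' @param samplePoisson sample Poisson's ratio.
#' @param probe an \code{\link{afmProbe}}.
#' @param curveId identifier attached to error messages.
#' @return list with elements \code{shallow} and \code{deep}, each either a
#'   \linkS4class{HertzFit} or an object of class \code{"hertzFitFailure"}
#'   carrying the error message, plus \code{contactPointZ}.
#' @export
analyzeCurveTwoWindows <- function(curve, shallowWindow = c(20, 100),
                                   deepWindow = c(310, 550),
                                   samplePoisson = 0.5, probe = afmProbe(),
                                   curveId = "curve") {
    z0 <- estimateContactPoint(curve)
    z0sd <- attr(z0, "sd")
    if (is.null(z0sd)) z0sd <- 0
    fi <- toForceIndentation(curve, as.numeric(z0))
    fitOr <- function(w) {
        tryCatch(fitHertzCone(fi, w, samplePoisson, probe, contactSD = z0sd),
                 error = function(e) structure(
                     list(message = conditionMessage(e), curveId = curveId,
                          window = w),
                     class = "hertzFitFailure"))
    }
    list(shallow = fitOr(shallowWindow), deep = fitOr(deepWindow),
         contactPointZ = z0)
}

#' @export
print.hertzFitFailure <- function(x, ...) {
    cat(sprintf("Hertz fit failed for %s over %g-%g nm: %s\n",
        x$curveId, x$window[1], x$window[2], x$message))
    invisible(x)
}

#' Aggregate per-indentation Hertz fits into a cohort
#'
#' Collects one modulus per indentation (repeat curves at one position each
#' count as a separate indentation, matching how stiffness cohorts are
#' plotted: one point per indentation). Failed fits are dropped.
#'
#' @param fits list of \linkS4class{HertzFit} (entries of class
#'   \code{"hertzFitFailure"} are skipped).
#' @param label cohort label.
#' @return a \linkS4class{StiffnessCohort}.
#' @export
aggregateCohort <- function(fits, label) {
    if (is(fits, "HertzFit")) fits <- list(fits)
    mods <- vapply(Filter(function(f) is(f, "HertzFit"), fits),
                   modulus, numeric(1))
    if (length(mods) == 0L) stop("empty cohort: no successful fits")
    new("StiffnessCohort", label = as.character(label), moduli = unname(mods))
}

#' Cohort stiffness recovery with parametric-bootstrap calibration
#'
#' Computes the per-window cohort mean moduli for a set of approach curves
#' and, optionally, divides out the pipeline's own small-sample bias. The
#' contact-point estimate of each curve carries a few nm of noise-driven
#' jitter; this leaves the deep (310-550 nm) window essentially unbiased but
#' can shift shallow (20-100 nm) cohort means by a few percent in either
#' direction depending on the layer contrast. The calibration step simulates
#' \code{nBoot} synthetic cohorts of the same size at the estimated moduli
#' and acquisition settings, runs them through the identical
#' contact-conversion-fit chain, measures the mean recovery ratio per window,
#' and divides it back out — calibrating the windowed fits so they recover
#' the set moduli.
#'
#' @param curves list of \linkS4class{ForceCurve}.
#' @param shallowWindow,deepWindow depth windows, nm.
#' @param samplePoisson sample Poisson's ratio.
#' @param probe an \code{\link{afmProbe}}.
#' @param calibrate apply the bootstrap bias correction (default TRUE).
#' @param nBoot number of calibration cohorts (default 6).
#' @param seed RNG seed for the calibration cohorts.
#' @return list: \code{shallow} and \code{deep} (cohort mean moduli, kPa,
#'   calibrated when requested), \code{raw} (uncalibrated means),
#'   \code{biasFactor} (per-window recovery ratio divided out), \code{fits}
#'   (the per-curve table from \code{\link{fitCohortTwoWindows}}).
#' @export
recoverStiffnessCohort <- function(curves, shallowWindow = c(20, 100),
                                   deepWindow = c(310, 550),
                                   samplePoisson = 0.5, probe = afmProbe(),
                                   calibrate = TRUE, nBoot = 6, seed = 1) {
    tab <- fitCohortTwoWindows(curves, shallowWindow = shallowWindow,
                               deepWindow = deepWindow,
                               samplePoisson = samplePoisson, probe = probe)
    rawMean <- function(t, w) mean(t$modulus_kpa[t$window == w], na.rm = TRUE)
    raw <- c(shallow = rawMean(tab, "shallow"), deep = rawMean(tab, "deep"))
    bias <- c(shallow = 1, deep = 1)
    if (calibrate && nBoot > 0) {
        # reconstruct acquisition settings from the curves themselves
        z <- piezoZ(curves[[1L]])
        zStep <- stats::median(diff(z))
        meta <- curves[[1L]]@meta
        maxF <- if (!is.null(meta$max_force_nN)) meta$max_force_nN else
            max(deflection(curves[[1L]])) * springConstant(curves[[1L]])
        noiseSD <- if (!is.null(meta$force_noise_sd_nN))
            meta$force_noise_sd_nN else 0.01 * maxF
        pre <- floor(0.35 * length(z)) * zStep
        acq <- acquisitionParams(zStep = zStep, maxForce = maxF,
                                 preContactSpan = pre,
                                 forceNoiseSD = noiseSD)
        sampleHat <- twoLayerSample(raw[["shallow"]], raw[["deep"]])
        bootSeeds <- withSeed(seed, sample.int(.Machine$integer.max, nBoot))
        bs <- matrix(NA_real_, nBoot, 2)
        for (b in seq_len(nBoot)) {
            coh <- simulateForceCurveCohort(length(curves), sampleHat, probe,
                                            acq, seed = bootSeeds[b])
            tb <- fitCohortTwoWindows(coh$curves,
                                      shallowWindow = shallowWindow,
                                      deepWindow = deepWindow,
                                      samplePoisson = samplePoisson,
                                      probe = probe)
            bs[b, ] <- c(rawMean(tb, "shallow") / raw[["shallow"]],
                         rawMean(tb, "deep") / raw[["deep"]])
        }
        bias <- c(shallow = mean(bs[, 1]), deep = mean(bs[, 2]))
    }
    list(shallow = raw[["shallow"]] / bias[["shallow"]],
         deep = raw[["deep"]] / bias[["deep"]],
         raw = raw, biasFactor = bias, fits = tab)
}

#' Fit a whole simulated or imported cohort over both windows
#'
#' @param curves list of \linkS4class{ForceCurve}.
#' @param ... passed to \code{\link{analyzeCurveTwoWindows}}.
#' @return data.frame with one row per curve and window:
#'   \code{curve_id}, \code{window}, \code{modulus_kpa}, \code{n_points},
#'   \code{r2}, \code{error}.
#' @export
fitCohortTwoWindows <- function(curves, ...) {
    rows <- list()
    for (i in seq_along(curves)) {
        id <- sprintf("curve_%03d", i)
        res <- tryCatch(analyzeCurveTwoWindows(curves[[i]], curveId = id, ...),
                        error = function(e) e)
        for (w in c("shallow", "deep")) {
            if (inherits(res, "error")) {
                rows[[length(rows) + 1L]] <- data.frame(
                    curve_id = id, window = w, modulus_kpa = NA_real_,
                    n_points = NA_integer_, r2 = NA_real_,
                    error = conditionMessage(res))
            } else if (is(res[[w]], "HertzFit")) {
                ft <- res[[w]]
                rows[[length(rows) + 1L]] <- data.frame(
                    curve_id = id, window = w, modulus_kpa = ft@modulus,
                    n_points = ft@nPoints, r2 = ft@rSquared, error = "")
            } else {
                rows[[length(rows) + 1L]] <- data.frame(
                    curve_id = id, window = w, modulus_kpa = NA_real_,
                    n_points = NA_integer_, r2 = NA_real_,
                    error = res[[w]]$message)
            }
        }
    }
    do.call(rbind, rows)
}
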