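test_that("contact point is recovered on noiseless curves and shifts with z", {
    sim <- simulateForceCurve(wtSample(), afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 2))
    z0hat <- estimateContactPoint(sim$curve)
    expect_lt(abs(z0hat - sim$truth$contact_z_nm), 2 * 2)  # 2 x zStep
    # translation equivariance: shifting the sweep shifts the estimate
    shifted <- new("ForceCurve", z = piezoZ(sim$curve) + 500,
                   deflection = deflection(sim$curve),
                   springConstant = springConstant(sim$curve))
    expect_equal(estimateContactPoint(shifted), z0hat + 500, tolerance = 1e-6)
})

test_that("curves without contact or without baseline are rejected", {
    flat <- new("ForceCurve", z = seq(0, 598, by = 2),
                deflection = rep(0, 300), springConstant = 0.12)
    expect_error(estimateContactPoint(flat), "no contact detected")
    # deflection rising from the first sample: no pre-contact baseline
    ramp <- new("ForceCurve", z = seq(0, 598, by = 2),
                deflection = seq(5, by = 1, length.out = 300),
                springConstant = 0.12)
    expect_error(estimateContactPoint(ramp), "no baseline")
})

test_that("force-indentation conversion round-trips the forward model", {
    sim <- simulateForceCurve(wtSample(), afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 3))
    fi <- toForceIndentation(sim$curve, sim$truth$contact_z_nm)
    # every (delta, F) pair satisfies the generator's forward model
    pred <- coneForce(wtSample(), afmProbe(), indentation(fi))
    nz <- force(fi) > 1e-6
    expect_lt(max(abs(force(fi)[nz] / pred[nz] - 1)), 1e-6)
    expect_false(is.unsorted(indentation(fi)))
    expect_true(all(indentation(fi) >= 0))
})

test_that("force follows Hooke's law with the curve's spring constant", {
    # deflection staircase of 1 nm steps -> force staircase of k = 0.12 nN
    z <- seq(0, by = 2, length.out = 200)
    defl <- c(rep(0, 100), seq(1, 100))
    curve <- new("ForceCurve", z = z, deflection = defl, springConstant = 0.12)
    fi <- toForceIndentation(curve, z[100])
    expect_equal(sort(unique(round(diff(force(fi)), 9))), 0.12)
    expect_error(toForceIndentation(curve, 1e6), "outside the sweep")
})

test_that("conversion fails with fewer than 10 in-contact points", {
    z <- seq(0, by = 2, length.out = 200)
    defl <- c(rep(0, 195), 1:5)
    curve <- new("ForceCurve", z = z, deflection = defl, springConstant = 0.12)
    expect_error(toForceIndentation(curve, z[196]), "insufficient indentation")
})

test_that("windowed fit is exact on noiseless single-layer curves", {
    uniform <- twoLayerSample(10, 10)
    sim <- simulateForceCurve(uniform, afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 4))
    fi <- toForceIndentation(sim$curve, sim$truth$contact_z_nm)
    for (w in list(c(20, 100), c(310, 550), c(50, 400))) {
        fit <- fitHertzCone(fi, w)
        expect_lt(abs(modulus(fit) / 10 - 1), 1e-6)
        expect_gt(fit@rSquared, 1 - 1e-9)
    }
    # oracle equivalence: windowed fit equals the per-point closed form
    pw <- pointwiseModulus(fi)
    sel <- indentation(fi) >= 20 & indentation(fi) <= 100
    expect_lt(max(abs(pw[sel] / modulus(fitHertzCone(fi, c(20, 100))) - 1)), 1e-6)
})

test_that("fit is linear in force and errors on sparse or non-physical input", {
    sim <- simulateForceCurve(twoLayerSample(10, 10), afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 5))
    fi <- toForceIndentation(sim$curve, sim$truth$contact_z_nm)
    doubled <- new("ForceIndentation", delta = indentation(fi),
                   force = 2 * force(fi), contactPointZ = contactPointZ(fi),
                   baseline = 0)
    expect_equal(modulus(fitHertzCone(doubled, c(20, 100))),
                 2 * modulus(fitHertzCone(fi, c(20, 100))), tolerance = 1e-9)
    expect_error(fitHertzCone(fi, c(5000, 6000)), "window too sparse")
    flipped <- new("ForceIndentation", delta = indentation(fi),
                   force = -force(fi), contactPointZ = 0, baseline = 0)
    expect_error(fitHertzCone(flipped, c(20, 100)), "non-physical")
})

test_that("finite-tip reduced modulus converges to the rigid-tip solution", {
    sim <- simulateForceCurve(twoLayerSample(10, 10), afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 6))
    fi <- toForceIndentation(sim$curve, sim$truth$contact_z_nm)
    rigid <- modulus(fitHertzCone(fi, c(20, 100), probe = afmProbe()))
    # silicon nitride is ~150 GPa higher than a 10 kPa sample
    soft <- modulus(fitHertzCone(fi, c(20, 100),
                                 probe = afmProbe(tipModulus = 1.5e8)))
    expect_lt(abs(soft / rigid - 1), 1e-3)
    expect_equal(fitHertzCone(fi, c(20, 100),
                              probe = afmProbe(tipModulus = 1.5e8))@tipModel,
                 "finite")
})

test_that("two-window analysis recovers both layer moduli within 5%", {
    sim <- simulateForceCurve(wtSample(), afmProbe(),
                              acquisitionParams(forceNoiseSD = 0, seed = 7))
    res <- analyzeCurveTwoWindows(sim$curve)
    expect_lt(abs(modulus(res$shallow) / 24.2 - 1), 0.05)
    expect_lt(abs(modulus(res$deep) / 10.1 - 1), 0.05)
})

test_that("a truncated sweep yields a sparse deep window but a shallow fit", {
    # max force 0.2 nN stops the approach well before 310 nm depth
    sim <- simulateForceCurve(wtSample(), afmProbe(),
        acquisitionParams(maxForce = 0.2, forceNoiseSD = 0, seed = 8))
    res <- analyzeCurveTwoWindows(sim$curve)
    expect_s4_class(res$shallow, "HertzFit")
    expect_s3_class(res$deep, "hertzFitFailure")
    expect_match(res$deep$message, "window too sparse")
})

test_that("analysis of the same curve twice is deterministic", {
    sim <- simulateForceCurve(wtSample(), afmProbe(), acquisitionParams(seed = 9))
    r1 <- analyzeCurveTwoWindows(sim$curve)
    r2 <- analyzeCurveTwoWindows(sim$curve)
    expect_identical(modulus(r1$shallow), modulus(r2$shallow))
    expect_identical(modulus(r1$deep), modulus(r2$deep))
})

test_that("cohort aggregation computes per-indentation mean, sd and n", {
    mk <- function(e) new("HertzFit", modulus = e, window = c(310, 550),
                          nPoints = 50L, rss = 0, rSquared = 1,
                          poissonSample = 0.5, tipModel = "rigid")
    c3 <- aggregateCohort(lapply(c(10, 10, 10), mk), "wt")
    expect_equal(cohortMean(c3), 10)
    expect_equal(cohortSD(c3), 0)
    expect_equal(cohortN(c3), 3L)
    c2 <- aggregateCohort(lapply(c(8, 12), mk), "wt")
    expect_equal(cohortMean(c2), 10)
    expect_equal(cohortSD(c2), sqrt((2^2 + 2^2) / 1))  # hand arithmetic: 2.83
    expect_equal(cohortSD(c2), 2.83, tolerance = 0.002)
    c1 <- aggregateCohort(mk(7.5), "single")
    expect_equal(cohortMean(c1), 7.5)
    expect_equal(cohortN(c1), 1L)
    expect_true(is.na(cohortSD(c1)))
    expect_error(aggregateCohort(list(), "none"), "empty cohort")
})

test_that("larger true deep modulus gives larger recovered deep modulus", {
    deepTruths <- c(8, 16, 32)
    means <- vapply(seq_along(deepTruths), function(i) {
        coh <- simulateForceCurveCohort(5, twoLayerSample(24.2, deepTruths[i]),
                                        seed = 100 + i)
        tab <- fitCohortTwoWindows(coh$curves)
        mean(tab$modulus_kpa[tab$window == "deep"], na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(means) > 0))
})

test_that("a 50-curve cohort at 1% force noise recovers both windows within 5%", {
    coh <- simulateForceCurveCohort(50, wtSample(), seed = 77)
    r <- recoverStiffnessCohort(coh$curves, nBoot = 12, seed = 78)
    expect_lt(abs(r$deep / 10.1 - 1), 0.05)
    expect_lt(abs(r$shallow / 24.2 - 1), 0.05)
    # the deep window needs essentially no calibration
    expect_lt(abs(r$biasFactor[["deep"]] - 1), 0.03)
})
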