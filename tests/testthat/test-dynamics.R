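test_that("frame detector finds rendered spots at their centers", {
    mask <- discMask(c(64L, 64L), c(32, 32), 25)
    blank <- matrix(10, 64, 64)
    expect_equal(nrow(detectPunctaFrame(blank, mask)), 0L)
    spot <- follicleMech:::renderGaussianSpot(blank, c(30.3, 35.7), 100, 1.5)
    det <- detectPunctaFrame(spot, mask)
    expect_equal(nrow(det), 1L)
    expect_lt(abs(det$row - 30.3), 0.5)
    expect_lt(abs(det$col - 35.7), 0.5)
    # threshold above the spot peak suppresses detection
    expect_equal(nrow(detectPunctaFrame(spot, mask, thresholdK = 1e6)), 0L)
    expect_error(detectPunctaFrame(spot, mask[1:10, 1:10]), "same shape")
})

test_that("gapless linking implements the lifetime bookkeeping", {
    mkdet <- function(frames, pos, T = 20) {
        lapply(seq_len(T), function(t) {
            if (t %in% frames)
                data.frame(row = pos[1], col = pos[2], area_px = 5L,
                           max_length_um = 0.4)
            else data.frame(row = numeric(0), col = numeric(0),
                            area_px = integer(0), max_length_um = numeric(0))
        })
    }
    # present frames 3..5 of 20 -> lifetime (6 - 3) * 30 = 90 s, uncensored
    ts <- linkTracks(mkdet(3:5, c(10, 10)), frameInterval = 30)
    tr <- tracks(ts)
    expect_equal(nrow(tr), 1L)
    expect_equal(tr$first_frame, 3L)
    expect_equal(tr$lifetime_s, 90)
    expect_false(tr$censored)
    # present only in the final frame -> censored, excluded from the mean
    ts2 <- linkTracks(mkdet(20, c(10, 10)), frameInterval = 30)
    expect_true(tracks(ts2)$censored)
    expect_error(computeLifetimes(ts2), "no complete lifetimes")
    # two spots 50 px apart with a 10 px gate never merge
    two <- lapply(1:5, function(t)
        data.frame(row = c(10, 60), col = c(10, 60), area_px = 5L,
                   max_length_um = 0.4))
    two <- c(two, list(data.frame(row = numeric(0), col = numeric(0),
                                  area_px = integer(0), max_length_um = numeric(0))))
    tr2 <- tracks(linkTracks(two, frameInterval = 30, maxLinkDistPx = 10))
    expect_equal(nrow(tr2), 2L)
    expect_equal(tr2$n_frames, c(5L, 5L))
})

test_that("a gap terminates a track: no gap closing", {
    det <- lapply(1:10, function(t) {
        if (t %in% c(3, 4, 6, 7))
            data.frame(row = 10, col = 10, area_px = 5L, max_length_um = 0.4)
        else data.frame(row = numeric(0), col = numeric(0),
                        area_px = integer(0), max_length_um = numeric(0))
    })
    tr <- tracks(linkTracks(det, frameInterval = 30))
    expect_equal(nrow(tr), 2L)           # the gap splits the punctum in two
    expect_equal(sort(tr$first_frame), c(3L, 6L))
    expect_equal(tr$n_frames, c(2L, 2L))
})

test_that("permuting detections within frames leaves the track set unchanged", {
    set.seed(42)
    pos <- cbind(runif(6, 5, 60), runif(6, 5, 60))
    det <- lapply(1:8, function(t)
        data.frame(row = pos[, 1] + 0.1 * t, col = pos[, 2], area_px = 5L,
                   max_length_um = 0.4))
    detPerm <- lapply(det, function(d) d[sample(nrow(d)), , drop = FALSE])
    a <- tracks(linkTracks(det, 30))
    b <- tracks(linkTracks(detPerm, 30))
    ordA <- order(a$first_frame, a$n_frames)
    ordB <- order(b$first_frame, b$n_frames)
    expect_equal(a[ordA, c("first_frame", "n_frames", "censored")],
                 b[ordB, c("first_frame", "n_frames", "censored")],
                 ignore_attr = TRUE)
})

test_that("lifetimes are frame counts times the interval", {
    tab <- data.frame(track_id = 1:4, first_frame = c(1L, 2L, 3L, 18L),
                      n_frames = c(1L, 2L, 3L, 3L),
                      lifetime_s = c(30, 60, 90, NA),
                      censored = c(FALSE, FALSE, FALSE, TRUE))
    res <- computeLifetimes(tab, frameInterval = 30)
    expect_equal(res$lifetimes_s, c(30, 60, 90))
    expect_equal(res$mean_lifetime_s, 60)
    expect_equal(res$n_censored, 1L)
})

test_that("generator lifetime draws match the geometric mean (Monte Carlo)", {
    # 10,000 draws at a 150 s mean, 30 s frames: sample mean within 2 SE
    set.seed(7)
    p <- 30 / 150
    draws <- (stats::rgeom(10000, p) + 1L) * 30
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - 150), 2 * se)
    # the simulator uses the same frame-grid convention
    sim <- simulateTimelapse(timelapseParams(nFrames = 500, birthRate = 4,
                                             meanLifetime = 150,
                                             punctumIntensity = 0, noiseA = 0,
                                             seed = 8))
    g <- sim$truth$true_frames
    seG <- stats::sd(g * 30) / sqrt(length(g))
    expect_lt(abs(mean(g * 30) - 150), 2 * seG)
})

test_that("degenerate movies behave per the geometric support", {
    empty <- simulateTimelapse(timelapseParams(birthRate = 0, seed = 1))
    expect_equal(nrow(empty$truth), 0L)
    expect_equal(max(abs(empty$movie@frames - 10)) > 50, FALSE)
    # mean lifetime equal to the interval: geometric mean 1 frame, all >= 1
    one <- simulateTimelapse(timelapseParams(nFrames = 30, birthRate = 1,
                                             meanLifetime = 30, seed = 2))
    expect_true(all(one$truth$true_frames >= 1L))
    expect_lt(mean(one$truth$true_frames), 1.5)
    expect_error(timelapseParams(meanLifetime = 10), "frameInterval")
})

test_that("detect-link-lifetime chain recovers the simulated truth", {
    sim <- simulateTimelapse(timelapseParams(nFrames = 81, birthRate = 2,
                                             meanLifetime = 150, seed = 21))
    res <- trackPunctaLifetimes(sim$movie)
    truthMean <- mean(sim$truth$observed_frames[!sim$truth$censored]) * 30
    # tracker fidelity: the chain reproduces the truth table's uncensored
    # mean to <2% (detection/linking artifacts only)
    expect_lt(abs(res$mean_lifetime_s / truthMean - 1), 0.02)
    expect_equal(res$n_uncensored + res$n_censored, nrow(sim$truth),
                 tolerance = 0.02)
    # and the truth mean itself sits within 2 SE of the generator mean
    lt <- sim$truth$observed_frames[!sim$truth$censored] * 30
    se <- stats::sd(lt) / sqrt(length(lt))
    expect_lt(abs(truthMean - 150), 2.5 * se)
})

test_that("movies at 70 s and 150 s mean lifetimes separate by Welch test", {
    fast <- simulateTimelapse(timelapseParams(nFrames = 81, birthRate = 2,
                                              meanLifetime = 70, seed = 31))
    slow <- simulateTimelapse(timelapseParams(nFrames = 81, birthRate = 2,
                                              meanLifetime = 150, seed = 32))
    lf <- trackPunctaLifetimes(fast$movie)
    ls <- trackPunctaLifetimes(slow$movie)
    expect_gt(ls$mean_lifetime_s, lf$mean_lifetime_s)
    tt <- unpairedTTest(lf$lifetimes_s, ls$lifetimes_s)
    expect_lt(tt$p_value, 0.01)
})
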