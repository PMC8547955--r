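test_that("line-profile ratio on uniform channels is exactly 1 at equal levels", {
    img <- flatImage(pmrlc = 100, phalloidin = 100)
    m <- measureMembraneRatio(img, rbind(c(10, 10), c(10, 50)))
    expect_equal(m$ratio, 1.0)
})

test_that("line-profile ratio reads phalloidin at the pMRLC peak", {
    # pMRLC plateau peak 300 (wider than the smoothing window) over baseline
    # 100; phalloidin flat 150 -> ratio 2
    pm <- matrix(100, 64, 64); pm[30, 28:34] <- 300
    ph <- matrix(150, 64, 64)
    img <- new("FollicleImage", channels = list(pmrlc = pm, phalloidin = ph),
               pixelSize = 0.2)
    m <- measureMembraneRatio(img, rbind(c(30, 5), c(30, 60)))
    expect_equal(m$ratio, 2.0, tolerance = 1e-9)
    expect_equal(m$peak_pmrlc, 300, tolerance = 1e-9)
    # homogeneity: numerator gain scales the ratio, common gain cancels
    img2 <- new("FollicleImage", channels = list(pmrlc = 2 * pm, phalloidin = ph),
                pixelSize = 0.2)
    expect_equal(measureMembraneRatio(img2, rbind(c(30, 5), c(30, 60)))$ratio,
                 4.0, tolerance = 1e-9)
    img3 <- new("FollicleImage",
                channels = list(pmrlc = 2 * pm, phalloidin = 2 * ph),
                pixelSize = 0.2)
    expect_equal(measureMembraneRatio(img3, rbind(c(30, 5), c(30, 60)))$ratio,
                 2.0, tolerance = 1e-9)
})

test_that("degenerate lines are rejected", {
    img <- flatImage()
    expect_error(measureMembraneRatio(img, rbind(c(1, 1), c(1, 2)),
                                      smoothWindow = 5), "shorter")
    expect_error(measureMembraneRatio(img, rbind(c(10, 10), c(200, 200))),
                 "outside")
    zero <- new("FollicleImage",
                channels = list(pmrlc = matrix(1, 32, 32),
                                phalloidin = matrix(0, 32, 32)),
                pixelSize = 0.2)
    expect_error(measureMembraneRatio(zero, rbind(c(10, 5), c(10, 25))),
                 "undefined ratio")
})

test_that("follicle membrane score averages exactly three line ratios", {
    img <- flatImage(pmrlc = 100, phalloidin = 100)
    same <- rbind(c(10, 5), c(10, 55))
    expect_equal(follicleMembraneScore(img, list(same, same, same)), 1.0)
    expect_error(follicleMembraneScore(img, list(same, same)), "exactly 3")
    # score = single-line ratio for identical lines; mean for distinct ones:
    # build plateaus of height 100/200/300 on three rows over phalloidin 100
    pm <- matrix(100, 64, 64)
    pm[20, 28:34] <- 100; pm[30, 28:34] <- 200; pm[40, 28:34] <- 300
    img2 <- new("FollicleImage",
                channels = list(pmrlc = pm, phalloidin = matrix(100, 64, 64)),
                pixelSize = 0.2)
    lines <- list(rbind(c(20, 5), c(20, 60)), rbind(c(30, 5), c(30, 60)),
                  rbind(c(40, 5), c(40, 60)))
    expect_equal(follicleMembraneScore(img2, lines), mean(c(1, 2, 3)),
                 tolerance = 1e-9)
})

test_that("membrane score recovers the scene truth within 5% at default noise", {
    sim <- simulateFollicleImage(imageSceneParams(seed = 31))
    score <- follicleMembraneScore(sim$image, defaultMembraneLines())
    expect_lt(abs(score / sim$truth$membrane_ratio - 1), 0.05)
})

test_that("control normalization fixes the control mean at 1 and is batch-wise", {
    expect_equal(normalizeToControl(c(2, 4), c(2, 2)), c(1, 2))
    ctrl <- c(1.2, 0.8, 1.0)
    normCtrl <- normalizeToControl(ctrl, ctrl)
    expect_equal(mean(normCtrl), 1.0)
    # idempotence on an already-normalized control
    expect_equal(normalizeToControl(normCtrl, normCtrl), normCtrl)
    expect_error(normalizeToControl(c(1, 2), numeric(0)), "empty")
    expect_error(normalizeToControl(c(1, 2), c(-3, 1)), "positive")
    # per-batch normalization then pooling differs from pooled-control
    # normalization and equals the hand-computed per-batch values
    batch1 <- list(scores = c(2, 4), control = c(2, 2))
    batch2 <- list(scores = c(30, 10), control = c(20, 20))
    pooledPerBatch <- c(normalizeToControl(batch1$scores, batch1$control),
                        normalizeToControl(batch2$scores, batch2$control))
    expect_equal(pooledPerBatch, c(1, 2, 1.5, 0.5))
    pooledControl <- normalizeToControl(c(batch1$scores, batch2$scores),
                                        c(batch1$control, batch2$control))
    expect_false(isTRUE(all.equal(pooledPerBatch, pooledControl)))
})

test_that("cluster/cytoplasm ratio handles uniform, enriched and invalid cases", {
    mask <- discMask(c(64L, 64L), c(40, 40), 8)
    img <- flatImage(masks = list(cluster = mask))
    expect_equal(clusterPmrlcRatio(img, cytoplasmOffsetPx = c(-20, -20))$ratio, 1.0)
    pm <- matrix(100, 64, 64); pm[mask] <- 200
    img2 <- new("FollicleImage",
                channels = list(pmrlc = pm, phalloidin = matrix(150, 64, 64)),
                pixelSize = 0.2, masks = list(cluster = mask))
    expect_equal(clusterPmrlcRatio(img2, cytoplasmOffsetPx = c(-20, -20))$ratio, 2.0)
    expect_error(clusterPmrlcRatio(img2, cytoplasmOffsetPx = c(-40, 0)),
                 "out of bounds")
    # translated mask must not land on membranes
    mem <- matrix(FALSE, 64, 64); mem[20, ] <- TRUE
    img3 <- new("FollicleImage", channels = img2@channels, pixelSize = 0.2,
                masks = list(cluster = mask, membranes = mem))
    expect_error(clusterPmrlcRatio(img3, cytoplasmOffsetPx = c(-20, 0)),
                 "overlaps membranes")
})

test_that("cluster ratio recovers the scene truth within 5% at default noise", {
    sim <- simulateFollicleImage(imageSceneParams(seed = 32))
    cm <- clusterPmrlcRatio(sim$image)
    expect_lt(abs(cm$ratio / sim$truth$cluster_ratio - 1), 0.05)
})

test_that("noiseless measurements equal ground truth to 1e-9 relative", {
    sim <- simulateFollicleImage(imageSceneParams(noiseA = 0, seed = 33))
    score <- follicleMembraneScore(sim$image, defaultMembraneLines())
    expect_lt(abs(score / sim$truth$membrane_ratio - 1), 1e-9)
    cm <- clusterPmrlcRatio(sim$image)
    expect_lt(abs(cm$ratio / sim$truth$cluster_ratio - 1), 1e-9)
})

test_that("fixed-image puncta detection counts and measures components", {
    mask <- discMask(c(64L, 64L), c(32, 32), 20)
    img <- flatImage(pmrlc = 100, masks = list(cluster = mask))
    expect_equal(nrow(detectFixedPuncta(img)), 0L)
    # two disjoint 3x1 bright bars; end-to-end extent 2 px -> 0.4 um
    pm <- matrix(100, 64, 64)
    pm[30:32, 25] <- 500
    pm[30:32, 40] <- 500
    img2 <- new("FollicleImage",
                channels = list(pmrlc = pm, phalloidin = matrix(1, 64, 64)),
                pixelSize = 0.2, masks = list(cluster = mask))
    det <- detectFixedPuncta(img2, minAreaPx = 3)
    expect_equal(nrow(det), 2L)
    # brute-force oracle: max pairwise distance over each bar's pixels
    bar <- rbind(c(30, 25), c(31, 25), c(32, 25))
    expect_equal(det$max_length_um, rep(max(stats::dist(bar)) * 0.2, 2))
    expect_equal(det$max_length_um, c(0.4, 0.4))
    expect_error(detectFixedPuncta(img2, clusterMask = matrix(FALSE, 64, 64)),
                 "no cluster")
})

test_that("rendered synthetic puncta are counted exactly at zero noise", {
    for (seed in c(9, 21, 33)) {
        sim <- simulateFollicleImage(imageSceneParams(noiseA = 0, nPuncta = 5,
                                                      seed = seed))
        expect_equal(nrow(detectFixedPuncta(sim$image)), 5L)
    }
})

test_that("migration index divides border by follicle-cell distance", {
    onTime <- migrationIndex(list(border_cell_distance = 150,
                                  follicle_cell_distance = 150))
    expect_identical(onTime$value, 1)
    expect_equal(onTime$classification, "on-time")
    delayed <- migrationIndex(list(border_cell_distance = 117,
                                   follicle_cell_distance = 150))
    expect_equal(delayed$value, 0.78)
    expect_equal(delayed$classification, "delayed")
    fast <- migrationIndex(list(border_cell_distance = 165,
                                follicle_cell_distance = 150))
    expect_equal(fast$value, 1.1)
    expect_equal(fast$classification, "accelerated")
    # scale invariance
    scaled <- migrationIndex(list(border_cell_distance = 117 * 3.7,
                                  follicle_cell_distance = 150 * 3.7))
    expect_equal(scaled$value, delayed$value)
    expect_error(migrationIndex(list(border_cell_distance = 10,
                                     follicle_cell_distance = 0)), "positive")
})

test_that("cluster length is the front-to-rear extent and is translation invariant", {
    expect_equal(clusterLength(list(cluster_front = 100, cluster_rear = 80)), 20)
    expect_equal(clusterLength(list(cluster_front = 55, cluster_rear = 55)), 0)
    expect_equal(clusterLength(list(cluster_front = 150, cluster_rear = 130)),
                 clusterLength(list(cluster_front = 100, cluster_rear = 80)))
    expect_error(clusterLength(list(cluster_front = 10, cluster_rear = 20)),
                 ">=")
})
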