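test_that("background rule keeps spots above mean + 2 SD and reports nets", {
    blk <- spot_block("L1", foreground = c(95, 100, 300),
                      background = c(85, 90, 95))
    out <- filterEffectiveSpots(blk)
    expect_equal(out$background_mean, 90)
    expect_equal(out$background_sd, 5)
    expect_equal(out$cutoff, 100)
    expect_equal(out$effective$net, c(10, 210))
    expect_equal(out$rejected$foreground, 95)

    ## all below cutoff
    low <- spot_block("L1", foreground = c(10, 20), background = c(100, 120))
    res <- filterEffectiveSpots(low)
    expect_equal(nrow(res$effective), 0)
    expect_equal(nrow(res$rejected), 2)

    ## zero background: cutoff 0, everything kept, net = foreground
    zb <- spot_block("L1", foreground = c(5, 7), background = c(0, 0))
    expect_equal(filterEffectiveSpots(zb)$effective$net, c(5, 7))

    expect_error(filterEffectiveSpots(data.frame()), "empty block")
})

test_that("block NFIs are median-sum normalized and sum to 1", {
    eff <- data.frame(probe = c("A", "A", "A", "B"), net = c(10, 20, 30, 80))
    expect_equal(normalizeBlock(eff), c(A = 0.2, B = 0.8))
    expect_equal(normalizeBlock(data.frame(probe = "A", net = 42)), c(A = 1))
    eff2 <- data.frame(probe = c("A", "B"), net = c(30, 70))
    expect_equal(normalizeBlock(eff2), c(A = 0.3, B = 0.7))
    expect_equal(sum(normalizeBlock(eff)), 1, tolerance = 1e-9)
    expect_error(normalizeBlock(data.frame(probe = "A", net = 0)),
                 "degenerate")
    ## controls are excluded from the denominator
    effc <- data.frame(probe = c("A", "BSA"), net = c(30, 70),
                       is_control = c(FALSE, TRUE))
    expect_equal(normalizeBlock(effc), c(A = 1))
})

test_that("NFIs are invariant under rescaling a whole block", {
    set.seed(42)
    blk <- spot_block(rep(c("A", "B", "C"), each = 3),
                      foreground = runif(9, 300, 900),
                      background = runif(9, 80, 120))
    nfi1 <- normalizeBlock(filterEffectiveSpots(blk)$effective)
    blk2 <- blk
    blk2$foreground <- blk2$foreground * 7.3
    blk2$background <- blk2$background * 7.3
    nfi2 <- normalizeBlock(filterEffectiveSpots(blk2)$effective)
    expect_equal(nfi1, nfi2, tolerance = 1e-12)
})

test_that("raising the background SD never adds effective spots", {
    set.seed(7)
    fg <- runif(12, 100, 400)
    bg <- runif(12, 80, 120)
    kept <- sapply(c(0, 1, 2, 5, 20), function(extra) {
        b <- spot_block("L1", fg, bg)
        ## inflating background spread raises the cutoff monotonically
        b$background <- mean(bg) + (bg - mean(bg)) * (1 + extra)
        nrow(filterEffectiveSpots(b)$effective)
    })
    expect_true(all(diff(kept) <= 0))
})

test_that("replicate blocks aggregate to mean/SD with coverage counts", {
    b <- c(A = 0.2, B = 0.8)
    agg <- aggregateSample(rep(list(b), 9))
    expect_equal(agg$mean_nfi, c(0.2, 0.8))
    expect_equal(agg$sd_nfi, c(0, 0))
    expect_equal(attr(agg, "n_blocks"), 9)

    agg2 <- aggregateSample(list(c(A = 0.2), c(A = 0.4)))
    expect_equal(agg2$mean_nfi, 0.3)
    expect_equal(agg2$sd_nfi, sd(c(0.2, 0.4)))

    agg3 <- aggregateSample(list(c(A = 0.1, B = 0.9), c(B = 1), c(B = 1)))
    expect_equal(agg3$n_present[agg3$lectin == "A"], 1)
    expect_equal(agg3$n_present[agg3$lectin == "B"], 3)
})

test_that("differential analysis calls direction from fold and paired p", {
    md <- data.frame(sample_id = c(paste0("TD-", 1:5), paste0("ASD-", 1:5)),
                     group = rep(c("TD", "ASD"), each = 5),
                     subgroup_index = rep(1:5, 2))
    base <- c(up = 0.03, down = 0.10, flat = 0.05)
    set.seed(1)
    prof <- t(sapply(md$sample_id, function(s) {
        f <- if (grepl("ASD", s)) c(3.33, 0.54, 1.0) else c(1, 1, 1)
        base * f * exp(rnorm(3, 0, 0.02))
    }))
    colnames(prof) <- names(base)
    d <- differentialLectins(prof, md)
    expect_equal(d$direction[d$lectin == "up"], "up")
    expect_equal(d$fold_change[d$lectin == "up"], 3.33, tolerance = 0.05)
    expect_equal(d$direction[d$lectin == "down"], "down")
    expect_equal(d$direction[d$lectin == "flat"], "unchanged")

    ## identical profiles: fold 1, degenerate p reported as 1
    same <- matrix(rep(c(0.4, 0.6), 10), ncol = 2, byrow = TRUE,
                   dimnames = list(md$sample_id, c("A", "B")))
    d0 <- differentialLectins(same, md)
    expect_equal(d0$fold_change, c(1, 1))
    expect_equal(d0$direction, c("unchanged", "unchanged"))

    ## TD mean zero is flagged infinite
    zz <- same; zz[1:5, "A"] <- 0
    expect_true(differentialLectins(zz, md)$infinite_fold[
        differentialLectins(zz, md)$lectin == "A"])

    expect_error(differentialLectins(same[c(1, 6), ], md[c(1, 6), ]),
                 "insufficient")
})

test_that("clustering matches a from-scratch UPGMA oracle and hclust", {
    set.seed(11)
    prof <- matrix(runif(4 * 6), nrow = 4,
                   dimnames = list(paste0("S", 1:4), paste0("L", 1:6)))
    d <- 1 - cor(t(prof))
    res <- hierarchicalCluster(prof)
    oracle <- upgma_oracle(d)
    expect_equal(res$samples$height, oracle$heights, tolerance = 1e-12)
    expect_equal(hclust_members(res$samples), oracle$members)
    ## independent cross-check against stats::hclust average linkage
    h <- hclust(as.dist(d), method = "average")
    expect_equal(sort(res$samples$height), sort(h$height),
                 tolerance = 1e-12)

    ## identical profiles merge at height 0, before the anti-correlated one
    prof3 <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
    res3 <- hierarchicalCluster(prof3)
    expect_equal(res3$samples$height[1], 0, tolerance = 1e-12)
    expect_equal(hclust_members(res3$samples)[[1]], c(1, 2))
    expect_match(res3$newick["samples"], "^\\(")

    ## constant profile: correlation defined as 0, with a warning
    profc <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
    expect_warning(hierarchicalCluster(profc), "constant")
})
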