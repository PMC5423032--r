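test_that("LGAM signals are filtered medians per sample and antibody", {
    md <- data.frame(sample_id = c("S1", "S2"), group = c("TD", "ASD"))
    spots <- rbind(
        spot_block(rep("APOD", 5), foreground = rep(100, 5) + 100,
                   background = rep(100, 5), sample_id = "S1"),
        spot_block(rep("APOD", 3), foreground = c(110, 120, 130) + 100,
                   background = rep(100, 3), sample_id = "S2"),
        spot_block("BSA", 5000, 100, sample_id = "S1", block_id = "B9"))
    spots$is_control <- spots$probe == "BSA"
    sig <- lgamSignals(spots, md)
    expect_equal(sig$median_signal[sig$sample_id == "S1"], 100)
    expect_equal(sig$median_signal[sig$sample_id == "S2"], 120)
    expect_false("BSA" %in% sig$antibody)

    ## all spots rejected -> missing, not zero
    low <- spot_block(rep("TF", 3), foreground = c(1, 2, 3),
                      background = c(100, 120, 140), sample_id = "S1")
    low$is_control <- FALSE
    sig2 <- lgamSignals(low, md)
    expect_true(is.na(sig2$median_signal))
    expect_equal(sig2$n_effective, 0)
})

test_that("group comparison supports paired and Welch modes", {
    set.seed(2)
    td <- c(10, 11, 12, 10.5, 11.5)
    asd <- td * 1.8 + rnorm(5, 0, 0.2)
    cmp <- groupCompare(td, asd, "paired")
    expect_lt(cmp$p_value, 0.05)
    expect_equal(cmp$fold, mean(asd) / mean(td))

    same <- groupCompare(c(1, 2, 3), c(1, 2, 3), "welch")
    expect_equal(same$p_value, 1, tolerance = 1e-12)
    expect_equal(same$fold, 1)

    degen <- groupCompare(c(1, 2, 3), c(1, 2, 3), "paired")
    expect_equal(degen$flag, "zero_variance")
    expect_true(is.na(degen$p_value))

    expect_error(groupCompare(1:3, 1:4, "paired"), "equal group sizes")
})

test_that("ROC matches pair counting, handles ties, finds Youden point", {
    r <- rocCurve(c(1, 2, 3, 2.5, 3.5, 4), rep(c("TD", "ASD"), each = 3))
    expect_equal(auc(r), 8 / 9)

    perfect <- rocCurve(c(1, 2, 10, 11), c("TD", "TD", "ASD", "ASD"))
    expect_equal(auc(perfect), 1)
    expect_equal(unname(youdenPoint(perfect)[c("sensitivity",
                                               "specificity")]), c(1, 1))

    ties <- rocCurve(rep(5, 8), rep(c("TD", "ASD"), 4))
    expect_equal(auc(ties), 0.5)

    set.seed(77)
    for (i in 1:20) {
        n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
        pos <- sample(1:20, n1, replace = TRUE)  # many ties
        neg <- sample(1:20, n0, replace = TRUE)
        r <- rocCurve(c(pos, neg), rep(c("ASD", "TD"), c(n1, n0)))
        expect_equal(auc(r), auc_oracle(pos, neg))
        ## curve shape: starts (0,0), ends (1,1), nondecreasing
        pts <- rocPoints(r)
        expect_equal(unlist(pts[1, c("fpr", "tpr")]),
                     c(fpr = 0, tpr = 0))
        expect_equal(unlist(pts[nrow(pts), c("fpr", "tpr")]),
                     c(fpr = 1, tpr = 1))
        expect_true(all(diff(pts$tpr) >= 0))
        ## Youden point dominates every threshold
        j <- pts$tpr - pts$fpr
        yp <- youdenPoint(r)
        expect_equal(yp[["sensitivity"]] + yp[["specificity"]] - 1, max(j))
    }
})

test_that("AUC is invariant under strictly increasing transforms", {
    set.seed(8)
    scores <- rnorm(40)
    groups <- rep(c("TD", "ASD"), 20)
    a1 <- auc(rocCurve(scores, groups))
    expect_equal(auc(rocCurve(exp(scores), groups)), a1)
    expect_equal(auc(rocCurve(scores^3 + 5 * scores, groups)), a1)
})

test_that("AUC agrees with the pROC reference implementation", {
    skip_if_not_installed("pROC")
    set.seed(9)
    scores <- c(rnorm(30), rnorm(30, 1))
    groups <- rep(c("TD", "ASD"), each = 30)
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = groups, predictor = scores, levels = c("TD", "ASD"),
        direction = "<", quiet = TRUE)))
    expect_equal(auc(rocCurve(scores, groups)), ref, tolerance = 1e-12)
})

test_that("serum-array comparison detects a planted lectin shift", {
    set.seed(12)
    n <- 10
    md <- data.frame(sample_id = c(paste0("TD-", 1:n), paste0("ASD-", 1:n)),
                     group = rep(c("TD", "ASD"), each = n))
    mk <- function(id, mu) {
        b <- spot_block(rep("MAL-II", 3),
                        foreground = mu * exp(rnorm(3, 0, 0.1)) + 100,
                        background = rnorm(3, 100, 5), sample_id = id)
        b$is_control <- FALSE
        b
    }
    spots <- do.call(rbind, c(lapply(md$sample_id[1:n], mk, mu = 500),
                              lapply(md$sample_id[-(1:n)], mk, mu = 1200)))
    res <- serumArrayCompare(spots, md, mode = "welch")
    expect_lt(res$p_value, 0.001)
    expect_gt(res$fold, 1.5)
    expect_error(serumArrayCompare(spots[spots$sample_id %in%
                                         c("TD-1", "ASD-1"), ], md),
                 ">= 2 samples")
})
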