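test_that("configuration is validated", {
    expect_error(simulationConfig(n_lectins = 0), "n_lectins")
    expect_error(simulationConfig(spot_noise_cv = -1), "spot_noise_cv")
    expect_error(simulationConfig(planted_lectin_folds = c(L01 = -2)),
                 "positive")
    expect_error(simulationConfig(motif_plants = data.frame(
        offset = 1, residue = "K", penetrance = 1.5)), "penetrance")
})

test_that("identical seeds give byte-identical study directories", {
    cfg <- simulationConfig(seed = 123, n_lectins = 8,
                            n_subgroups_per_group = 2,
                            blocks_per_sample = 2, n_proteins = 20,
                            fg_windows = 30, bg_windows = 60,
                            n_samples_per_group = 5,
                            planted_lectin_folds = c(L01 = 2))
    d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
    p1 <- simulateStudy(cfg, d1)
    p2 <- simulateStudy(cfg, d2)
    expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("generated tables pass the corresponding readers", {
    cfg <- simulationConfig(seed = 5, n_lectins = 6,
                            n_subgroups_per_group = 2,
                            blocks_per_sample = 2, n_proteins = 15,
                            fg_windows = 10, bg_windows = 20,
                            n_samples_per_group = 3)
    d <- file.path(tempdir(), "simio")
    simulateStudy(cfg, d)
    spots <- readSpotTable(file.path(d, "lectin_spots.tsv"))
    expect_equal(length(unique(spots$sample_id)), 4)
    md <- readSampleMetadata(file.path(d, "lectin_metadata.tsv"))
    expect_equal(nrow(md), 4)
    sce <- readCountMatrix(file.path(d, "spectral_counts.tsv"),
                           file.path(d, "spectral_runs.tsv"))
    expect_s4_class(sce, "SpectralCountExperiment")
    fg <- readLines(file.path(d, "windows_fg.txt"))
    expect_true(all(nchar(fg) == 27))
})

test_that("planted lectin fold propagates through the analysis", {
    cfg <- simulationConfig(seed = 99, planted_lectin_folds = c(L01 = 3.33))
    la <- simulateLectinArrays(cfg)
    expect_equal(la$truth$true_fold[la$truth$lectin == "L01"], 3.33)
    expect_true(all(la$truth$true_fold[la$truth$lectin != "L01"] == 1))
    d <- differentialLectins(sampleProfiles(la$spots)$profiles, la$metadata)
    expect_equal(d$direction[d$lectin == "L01"], "up")
    expect_equal(d$fold_change[d$lectin == "L01"], 3.33, tolerance = 0.15)
})

test_that("planted protein ratios and depth variation behave as designed", {
    cfg <- simulationConfig(seed = 7, planted_protein_ratios = c(P0001 = 2),
                            protein_sdlog = 0.3)
    sc <- simulateSpectralCounts(cfg)
    q <- quantifyProteins(normalizeRuns(sc$sce))
    expect_equal(q$ratio[q$protein_id == "P0001"], 2, tolerance = 0.5)
    expect_true(all(rowSums(SummarizedExperiment::assay(sc$sce,
                                                        "counts")) > 0))

    ## unequal depths with null ratios: post-normalization ratios near 1
    cfg0 <- simulationConfig(seed = 8, run_depth_multipliers = c(1, 2, 4),
                             protein_sdlog = 0.3)
    q0 <- quantifyProteins(normalizeRuns(simulateSpectralCounts(cfg0)$sce))
    expect_equal(median(q0$ratio[is.finite(q0$ratio)]), 1, tolerance = 0.1)
})

test_that("window plants hit their expected foreground frequency", {
    cfg <- simulationConfig(seed = 13, fg_windows = 4000, bg_windows = 100,
                            motif_plants = data.frame(
                                offset = -1, residue = "K",
                                penetrance = 0.8))
    wi <- simulateWindows(cfg)
    f <- positionFrequencies(wi$fg)
    expect_equal(f["K", "-1"], 0.8 + 0.2 / 20, tolerance = 0.02)

    full <- simulateWindows(simulationConfig(
        seed = 13, fg_windows = 50, bg_windows = 10,
        motif_plants = data.frame(offset = 2, residue = "W",
                                  penetrance = 1)))
    expect_true(all(substr(windowStrings(full$fg), 16, 16) == "W"))
})

test_that("binormal scores carry the closed-form truth AUC", {
    cfg0 <- simulationConfig(seed = 3, biomarker_delta = 0)
    expect_equal(simulateBiomarkerScores(cfg0)$truth_auc, 0.5)
    cfg <- simulationConfig(seed = 3, biomarker_delta = 1.664)
    bm <- simulateBiomarkerScores(cfg)
    expect_equal(bm$truth_auc, pnorm(1.664 / sqrt(2)))
    expect_equal(bm$truth_auc, 0.880, tolerance = 0.001)
    big <- simulateBiomarkerScores(simulationConfig(
        seed = 3, biomarker_delta = 8, n_samples_per_group = 50))
    expect_gt(auc(rocCurve(big$scores$score, big$scores$group)), 0.999)
})
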