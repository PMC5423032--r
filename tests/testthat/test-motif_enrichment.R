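test_that("windows are cut with X padding and center validation", {
    seqs <- c(p1 = "ANAS", p2 = "NASTL")
    w <- buildWindows(seqs, data.frame(protein_id = "p1", position = 2),
                      k = 2, center_residue = "N")
    expect_equal(windowStrings(w), "XANAS")
    w2 <- buildWindows(seqs, data.frame(protein_id = "p2", position = 1),
                       k = 3, center_residue = "N")
    expect_equal(windowStrings(w2), "XXXNAST")
    expect_error(buildWindows(seqs,
                              data.frame(protein_id = "p1", position = 1),
                              k = 2), "not 'N'")
    ## duplicates retained: each site counts once
    w3 <- buildWindows(seqs, data.frame(protein_id = c("p1", "p1"),
                                        position = c(2, 2)), k = 2)
    expect_equal(length(w3), 2L)
})

test_that("position frequencies exclude padding from denominators", {
    pws <- PeptideWindowSet(c("ANS", "CNS"), 1, "N")
    f <- positionFrequencies(pws)
    expect_equal(f["A", "-1"], 0.5)
    expect_equal(f["C", "-1"], 0.5)
    expect_equal(f["S", "1"], 1)
    expect_equal(sum(f[, "-1"]), 1)

    one <- positionFrequencies(PeptideWindowSet("KNT", 1, "N"))
    expect_true(all(one %in% c(0, 1)))

    padded <- positionFrequencies(PeptideWindowSet(c("XNS", "XNT"), 1, "N"))
    expect_equal(attr(padded, "undefined_offsets"), -1L)
    expect_true(all(is.na(padded[, "-1"])))
})

test_that("binomial tails match direct factorial summation", {
    expect_equal(binomialEnrichment(20, 10, 0.05),
                 binom_tail_oracle(20, 10, 0.05), tolerance = 1e-9)
    expect_equal(binomialEnrichment(20, 0, 0.05), 1)
    expect_equal(binomialEnrichment(10, 5, 1), 1)
    expect_equal(binomialEnrichment(10, 3, 0), 0)
    set.seed(23)
    for (i in 1:50) {
        n <- sample(1:50, 1)
        c <- sample(0:n, 1)
        q <- runif(1, 0.01, 0.99)
        o <- binom_tail_oracle(n, c, q)
        expect_lte(abs(binomialEnrichment(n, c, q) - o) / max(o, 1e-300),
                   1e-9)
    }
})

test_that("fold increase is measured on the original unreduced sets", {
    fg <- PeptideWindowSet(c(rep("KNS", 4), rep("ANS", 6)), 1, "N")
    bg <- PeptideWindowSet(c("KNT", rep("GNS", 99)), 1, "N")
    fi <- foldIncrease(-1, "K", fg, bg)
    expect_equal(fi$fold_increase, (4 / 10) / (1 / 100))  # 40
    expect_true(fi$fold_increase > 30)
    ## all wildcards -> 1; zero fg matches -> 0; zero bg matches -> Inf
    expect_equal(foldIncrease(integer(0), character(0), fg,
                              bg)$fold_increase, 1)
    expect_equal(foldIncrease(-1, "W", fg, bg)$fold_increase, 0)
    expect_equal(foldIncrease(-1, "A", fg, bg)$fold_increase, Inf)
})

test_that("identical foreground and background yield no motifs", {
    set.seed(31)
    cfg <- simulationConfig(seed = 31, fg_windows = 150, bg_windows = 150)
    wi <- simulateWindows(cfg)
    same <- PeptideWindowSet(windowStrings(wi$bg), halfWidth(wi$bg),
                             centerResidue(wi$bg), "foreground")
    expect_length(extractMotifs(same, wi$bg), 0)
})

test_that("planted enrichments are recovered with matching fold oracle", {
    cfg <- simulationConfig(seed = 41, fg_windows = 100, bg_windows = 1500,
                            motif_plants = data.frame(
                                offset = -1, residue = "K",
                                penetrance = 0.8))
    wi <- simulateWindows(cfg)
    ## one fixed position has expected fold ~16 (0.81 / 0.05)
    motifs <- extractMotifs(wi$fg, wi$bg, min_fold_increase = 10)
    expect_gte(length(motifs), 1)
    st <- motifSteps(motifs[[1]])
    expect_equal(st$position[1], -1)
    expect_equal(st$residue[1], "K")
    expect_true(all(st$fg_after <= st$fg_before))
    expect_true(all(st$bg_after <= st$bg_before))
    ## fold increase re-checkable by independent counting
    fgm <- windowStrings(wi$fg); bgm <- windowStrings(wi$bg)
    k <- halfWidth(wi$fg)
    match_all <- function(ws) {
        ok <- rep(TRUE, length(ws))
        for (i in seq_len(nrow(st)))
            ok <- ok & substr(ws, st$position[i] + k + 1,
                              st$position[i] + k + 1) == st$residue[i]
        mean(ok)
    }
    expect_equal(motifFoldIncrease(motifs[[1]]),
                 match_all(fgm) / match_all(bgm), tolerance = 1e-12)
    expect_true(motifFoldIncrease(motifs[[1]]) > 10)
})

test_that("two disjoint planted motifs come out as separate motifs", {
    set.seed(53)
    k <- 5
    draw <- function(n) {
        m <- matrix(sample(glycoprofiler:::.AA20, n * (2 * k + 1),
                           replace = TRUE), nrow = n)
        m[, k + 1] <- "N"
        m
    }
    fg <- draw(200)
    fg[1:100, k] <- "K"        # motif 1: K at -1 on first half
    fg[101:200, k + 3] <- "Y"  # motif 2: Y at +2 on second half
    bg <- draw(2000)
    tofg <- function(m) apply(m, 1, paste, collapse = "")
    motifs <- extractMotifs(
        PeptideWindowSet(tofg(fg), k, "N"),
        PeptideWindowSet(tofg(bg), k, "N", "background"),
        min_fold_increase = 5)
    got <- lapply(motifs, function(m)
        paste(motifSteps(m)$position, motifSteps(m)$residue))
    expect_true(any(vapply(got, function(g) "-1 K" %in% g, logical(1))))
    expect_true(any(vapply(got, function(g) "2 Y" %in% g, logical(1))))
})

test_that("extraction is deterministic and patterns render and merge", {
    cfg <- simulationConfig(seed = 61, fg_windows = 120, bg_windows = 1200,
                            motif_plants = data.frame(
                                offset = 2, residue = "S",
                                penetrance = 0.9))
    wi <- simulateWindows(cfg)
    m1 <- extractMotifs(wi$fg, wi$bg, min_fold_increase = 10)
    m2 <- extractMotifs(wi$fg, wi$bg, min_fold_increase = 10)
    expect_identical(lapply(m1, motifSteps), lapply(m2, motifSteps))
    pat <- motifPattern(m1[[1]])
    expect_equal(nchar(pat), 27)
    expect_equal(substr(pat, 14, 14), "N")
    expect_equal(substr(pat, 16, 16), "S")
    expect_equal(nchar(trimPattern(pat)), 13)
    expect_equal(mergeMotifPatterns(list(m1[[1]])), pat)
    expect_equal(mergeMotifPatterns(list()), character(0))
    fake <- function(p) methods::new("GlycoMotif", pattern = p,
                                     steps = data.frame(), motifScore = 1,
                                     foldIncrease = 31, fgMatches = 1L,
                                     bgMatches = 1L, fgTotal = 1L,
                                     bgTotal = 1L)
    expect_equal(mergeMotifPatterns(list(fake("xKxNx"), fake("xRxNx"))),
                 "x[KR]xNx")
})
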