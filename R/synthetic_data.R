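## Synthetic-data generators with known ground truth for every input the
## pipeline consumes: lectin-array spot tables, Poisson spectral counts,
## glycosite peptide windows and binormal biomarker scores. One master
## seed drives independent per-generator streams (fixed offsets), so
## adding a generator does not perturb the others' draws.

.STREAM_OFFSETS <- c(lectin = 11L, spectral = 23L, windows = 37L,
                     biomarker = 53L)

.setStreamSeed <- function(config, stream) {
    set.seed((config$seed + .STREAM_OFFSETS[[stream]]) %% .Machine$integer.max)
}

## multiplicative lognormal noise with a given coefficient of variation
.rlnormCV <- function(n, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Build a validated simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' mirroring the study design this package emulates: 37 lectins, 5
#' pooled subgroups per group read on 9 replicate blocks with triplicate
#' spots, triplicate LC-MS/MS runs per group, +/-13-residue glycosite
#' windows, and 15 individual samples per group for validation arrays.
#' Noise defaults (spot CV 0.15, background 200 +/- 20, lognormal
#' baseline sigma 0.5) are desk-scale realistic values; see the vignette.
#'
#' @param seed master integer seed.
#' @param n_lectins number of lectins on the array (default 37).
#' @param n_subgroups_per_group pooled subgroups per group (default 5).
#' @param blocks_per_sample replicate blocks per sample (default 9).
#' @param spots_per_lectin replicate spots per lectin per block
#'   (default 3).
#' @param planted_lectin_folds named numeric, true ASD/TD fold per
#'   planted lectin (others 1).
#' @param spot_noise_cv multiplicative spot-level CV (default 0.15).
#' @param background_mean,background_sd additive background parameters
#'   (defaults 200 and 20 fluorescence units).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline of lectin
#'   (and protein) signals (defaults log(1000) and 0.5).
#' @param subgroup_cv optional biological CV across pooled subgroups on
#'   top of the spot-level noise (default 0: pooled subgroup signals
#'   differ only through spot noise and background, matching the
#'   generator model described in the vignette).
#' @param n_proteins proteins in the spectral-count simulation
#'   (default 200).
#' @param planted_protein_ratios named numeric, true ASD/TD abundance
#'   ratio per planted protein (others 1).
#' @param runs_per_group LC-MS/MS runs per group (default 3).
#' @param run_depth_multipliers depth multipliers, recycled over the
#'   2 * runs_per_group runs (default c(1, 1.5, 0.75)).
#' @param protein_mean_count baseline expected spectral count
#'   (default 50).
#' @param protein_sdlog lognormal spread of protein baselines
#'   (default 1).
#' @param motif_plants data.frame (offset, residue, penetrance) of
#'   planted foreground enrichments (default none).
#' @param fg_windows,bg_windows window-set sizes (defaults 200, 2000).
#' @param window_halfwidth half-width k (default 13).
#' @param window_center center residue (default "N").
#' @param biomarker_delta binormal separation delta; true AUC =
#'   pnorm(delta / sqrt(2)) (default 1.664, true AUC ~= 0.880).
#' @param n_samples_per_group individual samples per group for
#'   validation arrays (default 15).
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_lectins = 37L,
                             n_subgroups_per_group = 5L,
                             blocks_per_sample = 9L,
                             spots_per_lectin = 3L,
                             planted_lectin_folds = numeric(0),
                             spot_noise_cv = 0.15,
                             background_mean = 200,
                             background_sd = 20,
                             baseline_meanlog = log(1000),
                             baseline_sdlog = 0.5,
                             subgroup_cv = 0,
                             n_proteins = 200L,
                             planted_protein_ratios = numeric(0),
                             runs_per_group = 3L,
                             run_depth_multipliers = c(1, 1.5, 0.75),
                             protein_mean_count = 50,
                             protein_sdlog = 1,
                             motif_plants = NULL,
                             fg_windows = 200L,
                             bg_windows = 2000L,
                             window_halfwidth = 13L,
                             window_center = "N",
                             biomarker_delta = 1.664,
                             n_samples_per_group = 15L) {
    config <- list(seed = as.integer(seed), n_lectins = as.integer(n_lectins),
                   n_subgroups_per_group = as.integer(n_subgroups_per_group),
                   blocks_per_sample = as.integer(blocks_per_sample),
                   spots_per_lectin = as.integer(spots_per_lectin),
                   planted_lectin_folds = planted_lectin_folds,
                   spot_noise_cv = spot_noise_cv,
                   background_mean = background_mean,
                   background_sd = background_sd,
                   baseline_meanlog = baseline_meanlog,
                   baseline_sdlog = baseline_sdlog,
                   subgroup_cv = subgroup_cv,
                   n_proteins = as.integer(n_proteins),
                   planted_protein_ratios = planted_protein_ratios,
                   runs_per_group = as.integer(runs_per_group),
                   run_depth_multipliers = run_depth_multipliers,
                   protein_mean_count = protein_mean_count,
                   protein_sdlog = protein_sdlog,
                   motif_plants = motif_plants,
                   fg_windows = as.integer(fg_windows),
                   bg_windows = as.integer(bg_windows),
                   window_halfwidth = as.integer(window_halfwidth),
                   window_center = window_center,
                   biomarker_delta = biomarker_delta,
                   n_samples_per_group = as.integer(n_samples_per_group))
    counts <- c("n_lectins", "n_subgroups_per_group", "blocks_per_sample",
                "spots_per_lectin", "n_proteins", "runs_per_group",
                "fg_windows", "bg_windows", "window_halfwidth",
                "n_samples_per_group")
    for (f in counts)
        if (config[[f]] < 1L)
            stop(sprintf("invalid config: %s must be >= 1", f),
                 call. = FALSE)
    for (f in c("spot_noise_cv", "background_mean", "background_sd"))
        if (config[[f]] <= 0)
            stop(sprintf("invalid config: %s must be positive", f),
                 call. = FALSE)
    if (!is.null(motif_plants) &&
        (any(motif_plants$penetrance <= 0) ||
         any(motif_plants$penetrance > 1)))
        stop("invalid config: penetrance must be in (0, 1]", call. = FALSE)
    if (any(config$planted_lectin_folds <= 0) ||
        any(config$planted_protein_ratios <= 0))
        stop("invalid config: planted folds/ratios must be positive",
             call. = FALSE)
    class(config) <- "SimulationConfig"
    config
}

#' Simulate lectin-microarray spot tables
#'
#' Per block and lectin, a lognormal baseline median signal (shared
#' across samples) is multiplied by the lectin's planted fold for ASD
#' samples and by a per-sample biological factor, then each replicate
#' spot receives multiplicative lognormal noise at the configured CV and
#' an additive truncated-normal background.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{spots} (spot-table data.frame),
#'   \code{metadata} (sample_id, group, subgroup_index) and \code{truth}
#'   (lectin, true_fold).
#' @export
simulateLectinArrays <- function(config) {
    .setStreamSeed(config, "lectin")
    lectins <- sprintf("L%02d", seq_len(config$n_lectins))
    folds <- stats::setNames(rep(1, config$n_lectins), lectins)
    planted <- intersect(names(config$planted_lectin_folds), lectins)
    folds[planted] <- config$planted_lectin_folds[planted]
    baseline <- stats::rlnorm(config$n_lectins, config$baseline_meanlog,
                              config$baseline_sdlog)
    names(baseline) <- lectins
    metadata <- data.frame(
        sample_id = c(sprintf("TD-%d", seq_len(config$n_subgroups_per_group)),
                      sprintf("ASD-%d", seq_len(config$n_subgroups_per_group))),
        group = rep(c("TD", "ASD"), each = config$n_subgroups_per_group),
        subgroup_index = rep(seq_len(config$n_subgroups_per_group), 2))
    n_spot <- config$spots_per_lectin
    rows <- vector("list", nrow(metadata))
    for (s in seq_len(nrow(metadata))) {
        asd <- metadata$group[s] == "ASD"
        bio <- .rlnormCV(config$n_lectins, config$subgroup_cv)
        mu <- baseline * (if (asd) folds else 1) * bio
        blk <- vector("list", config$blocks_per_sample)
        for (b in seq_len(config$blocks_per_sample)) {
            signal <- rep(mu, each = n_spot) *
                .rlnormCV(config$n_lectins * n_spot, config$spot_noise_cv)
            bg <- pmax(0, stats::rnorm(config$n_lectins * n_spot,
                                       config$background_mean,
                                       config$background_sd))
            blk[[b]] <- data.frame(
                sample_id = metadata$sample_id[s],
                block_id = sprintf("B%d", b),
                probe = rep(lectins, each = n_spot),
                replicate = rep(seq_len(n_spot), config$n_lectins),
                foreground = signal + bg,
                background = bg, stringsAsFactors = FALSE)
        }
        rows[[s]] <- do.call(rbind, blk)
    }
    spots <- do.call(rbind, rows)
    spots$is_control <- FALSE
    list(spots = spots, metadata = metadata,
         truth = data.frame(lectin = lectins, true_fold = as.numeric(folds)))
}

#' Simulate spectral-count matrices
#'
#' Protein baselines are lognormal around the configured mean count; the
#' expected count in a run is baseline x group ratio (ASD runs) x run
#' depth multiplier, and observed counts are Poisson. All-zero rows are
#' dropped.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{sce} (a
#'   \linkS4class{SpectralCountExperiment}) and \code{truth} (protein_id,
#'   true_ratio).
#' @export
simulateSpectralCounts <- function(config) {
    .setStreamSeed(config, "spectral")
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))
    ratios <- stats::setNames(rep(1, config$n_proteins), proteins)
    planted <- intersect(names(config$planted_protein_ratios), proteins)
    ratios[planted] <- config$planted_protein_ratios[planted]
    sdlog <- config$protein_sdlog
    baseline <- stats::rlnorm(config$n_proteins,
                              log(config$protein_mean_count) - sdlog^2 / 2,
                              sdlog)
    n_runs <- 2L * config$runs_per_group
    depth <- rep_len(config$run_depth_multipliers, n_runs)
    group <- rep(c("TD", "ASD"), each = config$runs_per_group)
    run_ids <- sprintf("%s_run%d", group,
                       rep(seq_len(config$runs_per_group), 2))
    lambda <- outer(baseline, depth)
    lambda[, group == "ASD"] <- lambda[, group == "ASD"] * ratios
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow = config$n_proteins,
                     dimnames = list(proteins, run_ids))
    keep <- rowSums(counts) > 0
    sce <- SpectralCountExperiment(counts[keep, , drop = FALSE],
                                   group = group)
    list(sce = sce,
         truth = data.frame(protein_id = proteins,
                            true_ratio = as.numeric(ratios))[keep, ])
}

#' Simulate foreground/background glycosite windows
#'
#' Background windows draw every non-center position i.i.d. uniform over
#' the 20 standard residues; foreground windows additionally carry each
#' planted (offset, residue) with its penetrance.
#'
#' @param config a \code{\link{simulationConfig}} (see
#'   \code{motif_plants}).
#' @return list with \code{fg}, \code{bg}
#'   (\linkS4class{PeptideWindowSet}) and \code{truth} (the plant table).
#' @export
simulateWindows <- function(config) {
    .setStreamSeed(config, "windows")
    k <- config$window_halfwidth
    w <- 2L * k + 1L
    draw <- function(n) {
        m <- matrix(sample(.AA20, n * w, replace = TRUE), nrow = n)
        m[, k + 1L] <- config$window_center
        m
    }
    bg <- draw(config$bg_windows)
    fg <- draw(config$fg_windows)
    plants <- config$motif_plants
    if (!is.null(plants)) {
        for (i in seq_len(nrow(plants))) {
            hit <- stats::runif(config$fg_windows) <= plants$penetrance[i]
            fg[hit, plants$offset[i] + k + 1L] <- plants$residue[i]
        }
    }
    collapse <- function(m) apply(m, 1, paste, collapse = "")
    list(fg = PeptideWindowSet(collapse(fg), k, config$window_center,
                               "foreground"),
         bg = PeptideWindowSet(collapse(bg), k, config$window_center,
                               "background"),
         truth = if (is.null(plants))
             data.frame(offset = integer(0), residue = character(0),
                        penetrance = numeric(0)) else plants)
}

#' Simulate binormal biomarker scores
#'
#' TD scores are Normal(0, 1), ASD scores Normal(delta, 1); the true AUC
#' of the implied ROC is pnorm(delta / sqrt(2)).
#'
#' @param config a \code{\link{simulationConfig}} (see
#'   \code{biomarker_delta}, \code{n_samples_per_group}).
#' @return list with \code{scores} (sample_id, group, score) and
#'   \code{truth_auc}.
#' @export
simulateBiomarkerScores <- function(config) {
    .setStreamSeed(config, "biomarker")
    n <- config$n_samples_per_group
    scores <- data.frame(
        sample_id = c(sprintf("TD-%02d", seq_len(n)),
                      sprintf("ASD-%02d", seq_len(n))),
        group = rep(c("TD", "ASD"), each = n),
        score = c(stats::rnorm(n, 0, 1),
                  stats::rnorm(n, config$biomarker_delta, 1)))
    list(scores = scores,
         truth_auc = stats::pnorm(config$biomarker_delta / sqrt(2)))
}

#' Write a full synthetic study to a directory
#'
#' Emits every generated table as plain text (TSV/FASTA-free formats
#' used by the readers) plus the truth tables and the resolved
#' configuration as JSON, so a complete pipeline run needs no external
#' data.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
simulateStudy <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    la <- simulateLectinArrays(config)
    writeSpotTable(la$spots, p("lectin_spots.tsv"))
    utils::write.table(la$metadata, p("lectin_metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(la$truth, p("lectin_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sc <- simulateSpectralCounts(config)
    writeCountMatrix(sc$sce, p("spectral_counts.tsv"),
                     p("spectral_runs.tsv"))
    utils::write.table(sc$truth, p("spectral_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wi <- simulateWindows(config)
    writeLines(windowStrings(wi$fg), p("windows_fg.txt"))
    writeLines(windowStrings(wi$bg), p("windows_bg.txt"))
    utils::write.table(wi$truth, p("windows_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bm <- simulateBiomarkerScores(config)
    utils::write.table(bm$scores, p("biomarker_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    cfg$motif_plants <- if (is.null(cfg$motif_plants)) NULL else
        as.list(cfg$motif_plants)
    jsonlite::write_json(c(cfg, list(truth_auc = bm$truth_auc)),
                         p("config.json"), auto_unbox = TRUE, digits = NA)
    invisible(vapply(c("lectin_spots.tsv", "lectin_metadata.tsv",
                       "lectin_truth.tsv", "spectral_counts.tsv",
                       "spectral_runs.tsv", "spectral_truth.tsv",
                       "windows_fg.txt", "windows_bg.txt",
                       "windows_truth.tsv", "biomarker_scores.tsv",
                       "config.json"), p, character(1)))
}
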