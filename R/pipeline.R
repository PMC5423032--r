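## End-to-end orchestration: each analysis stage is an ordinary exported
## function; runPipeline() wires them into the study's flow (lectin
## arrays -> spectral quantification -> glyco categories -> motifs ->
## validation/ROC), writes per-stage outputs and a combined summary, and
## logs every threshold it applied.

#' Build a pipeline configuration
#'
#' @param outdir output directory.
#' @param lectin_spots,lectin_metadata paths for the lectin-array stage.
#' @param count_matrix,run_metadata paths for the quantification stage.
#' @param annotation_flags,fasta paths for the glyco-annotation stage.
#' @param fg_windows,bg_windows paths (one window string per line) for
#'   the motif stage.
#' @param biomarker_scores path (TSV sample_id, group, score) for the
#'   validation stage.
#' @param fold_up,fold_down,alpha differential thresholds (1.5, 0.67,
#'   0.05).
#' @param motif_p,motif_min_fold,motif_min_occ motif thresholds (1e-6,
#'   30, 20).
#' @param ttest_mode "paired" or "welch".
#' @param window_halfwidth half-width of the motif windows (13).
#' @param window_center center residue of the motif windows ("N").
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outdir,
                           lectin_spots = NULL, lectin_metadata = NULL,
                           count_matrix = NULL, run_metadata = NULL,
                           annotation_flags = NULL, fasta = NULL,
                           fg_windows = NULL, bg_windows = NULL,
                           biomarker_scores = NULL,
                           fold_up = 1.5, fold_down = 0.67, alpha = 0.05,
                           motif_p = 1e-6, motif_min_fold = 30,
                           motif_min_occ = 20L,
                           ttest_mode = "paired",
                           window_halfwidth = 13L,
                           window_center = "N") {
    if (fold_up <= fold_down)
        stop("invalid config: fold_up must exceed fold_down", call. = FALSE)
    if (any(c(fold_up, fold_down, alpha, motif_p, motif_min_fold) <= 0))
        stop("invalid config: thresholds must be positive", call. = FALSE)
    structure(as.list(environment()), class = "PipelineConfig")
}

.checkInput <- function(path, stage) {
    if (!is.null(path) && !file.exists(path))
        stop(sprintf("stage %s: missing input path %s", stage, path),
             call. = FALSE)
    !is.null(path)
}

#' Run the integrated pipeline
#'
#' Executes every stage whose inputs are configured, writes per-stage
#' TSV/Newick/JSON outputs under \code{outdir} and returns the combined
#' results. A stage validation error aborts with the stage name.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) list with the per-stage results and the summary.
#' @export
runPipeline <- function(config) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    results <- list()
    log <- c(sprintf("thresholds: fold_up=%g fold_down=%g alpha=%g",
                     config$fold_up, config$fold_down, config$alpha),
             sprintf("motif: p<%g fold>%g occ>=%d", config$motif_p,
                     config$motif_min_fold, config$motif_min_occ),
             sprintf("t-test mode: %s", config$ttest_mode))

    if (.checkInput(config$lectin_spots, "lectin") &&
        .checkInput(config$lectin_metadata, "lectin")) {
        spots <- readSpotTable(config$lectin_spots)
        md <- readSampleMetadata(config$lectin_metadata)
        prof <- sampleProfiles(spots)
        diff <- differentialLectins(prof$profiles, md,
                                    fold_up = config$fold_up,
                                    fold_down = config$fold_down,
                                    alpha = config$alpha)
        cl <- hierarchicalCluster(prof$profiles)
        utils::write.table(
            data.frame(sample_id = rownames(prof$profiles),
                       prof$profiles, check.names = FALSE),
            out("nfi_profiles.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(diff, out("differential_lectins.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(cl$newick, out("dendrograms.nwk"))
        results$lectin <- list(profiles = prof, differential = diff,
                               clustering = cl)
        log <- c(log, sprintf("lectin: %d samples, %d lectins, %d differential",
                              nrow(prof$profiles), ncol(prof$profiles),
                              sum(diff$direction != "unchanged")))
    }

    if (.checkInput(config$count_matrix, "quant") &&
        .checkInput(config$run_metadata, "quant")) {
        sce <- readCountMatrix(config$count_matrix, config$run_metadata)
        sce <- normalizeRuns(sce)
        quant <- quantifyProteins(sce, up = config$fold_up,
                                  down = config$fold_down)
        grp <- SummarizedExperiment::colData(sce)$group
        m <- SummarizedExperiment::assay(sce, "counts")
        acct <- identificationAccounting(
            td = rownames(m)[rowSums(m[, grp == "TD", drop = FALSE]) > 0],
            asd = rownames(m)[rowSums(m[, grp == "ASD", drop = FALSE]) > 0])
        utils::write.table(quant, out("protein_quant.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(acct$proteins, out("accounting.json"),
                             auto_unbox = TRUE, digits = NA)
        results$quant <- list(sce = sce, quant = quant,
                              accounting = acct)
        log <- c(log, sprintf("quant: %d proteins, %d up, %d down",
                              nrow(quant),
                              sum(quant$regulation == "up"),
                              sum(quant$regulation == "down")))
    }

    if (.checkInput(config$annotation_flags, "annotate")) {
        flags <- readAnnotationFlags(config$annotation_flags)
        seqs <- if (.checkInput(config$fasta, "annotate"))
            readFastaAA(config$fasta) else NULL
        cats <- categorizeGlyco(flags, seqs)
        known <- if ("known" %in% colnames(flags)) flags$known else NULL
        tally <- tallyCategories(cats, known = known)
        utils::write.table(cats, out("glyco_categories.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(tally, out("glyco_tally.json"),
                             auto_unbox = TRUE, digits = NA)
        results$annotate <- list(categories = cats, tally = tally)
        log <- c(log, sprintf("annotate: %d proteins categorized",
                              nrow(cats)))
    }

    if (.checkInput(config$fg_windows, "motifs") &&
        .checkInput(config$bg_windows, "motifs")) {
        k <- config$window_halfwidth
        fg <- PeptideWindowSet(readLines(config$fg_windows), k,
                               config$window_center, "foreground")
        bg <- PeptideWindowSet(readLines(config$bg_windows), k,
                               config$window_center, "background")
        motifs <- extractMotifs(fg, bg, p_threshold = config$motif_p,
                                min_occurrences = config$motif_min_occ,
                                min_fold_increase = config$motif_min_fold)
        mt <- if (length(motifs)) data.frame(
            pattern = vapply(motifs, motifPattern, character(1)),
            pattern_13 = vapply(motifs, function(m)
                trimPattern(motifPattern(m)), character(1)),
            n_steps = vapply(motifs, function(m) nrow(motifSteps(m)),
                             integer(1)),
            motif_score = vapply(motifs, motifScore, numeric(1)),
            fold_increase = vapply(motifs, motifFoldIncrease, numeric(1)))
            else data.frame()
        utils::write.table(mt, out("motifs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        results$motifs <- list(motifs = motifs, table = mt)
        log <- c(log, sprintf("motifs: %d extracted", length(motifs)))
    }

    if (.checkInput(config$biomarker_scores, "validate")) {
        sc <- .read_tsv(config$biomarker_scores)
        roc <- rocCurve(sc$score, sc$group, positive = "ASD")
        cmp <- groupCompare(sc$score[sc$group == "TD"],
                            sc$score[sc$group == "ASD"],
                            mode = config$ttest_mode)
        utils::write.table(rocPoints(roc), out("roc_points.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(auc = auc(roc),
                 sensitivity = youdenPoint(roc)[["sensitivity"]],
                 specificity = youdenPoint(roc)[["specificity"]],
                 fold = cmp$fold, p_value = cmp$p_value),
            out("roc_summary.json"), auto_unbox = TRUE, digits = NA)
        results$validate <- list(roc = roc, comparison = cmp)
        log <- c(log, sprintf("validate: AUC %.3f", auc(roc)))
    }

    writeLines(log, out("run_log.txt"))
    results$log <- log
    invisible(results)
}
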