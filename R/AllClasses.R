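#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Spectral-count experiment container
#'
#' A \linkS4class{SummarizedExperiment} subclass holding raw (and, after
#' \code{\link{normalizeRuns}}, depth-normalized) spectral counts, with one
#' row per protein and one column per LC-MS/MS run. \code{colData} carries
#' the run's comparison group (\code{"TD"} or \code{"ASD"}).
#'
#' Validity requires a \code{"counts"} assay of finite, non-negative,
#' integer-valued entries in which every run has at least one nonzero
#' count, and a \code{group} column in \code{colData}.
#'
#' @aliases SpectralCountExperiment-class
#' @exportClass SpectralCountExperiment
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)))
        return("counts must be finite")
    if (any(m < 0))
        return("counts must be non-negative")
    if (any(abs(m - round(m)) > 1e-8))
        return("counts must be integer-valued")
    if (ncol(m) > 0 && any(colSums(m) == 0))
        return(sprintf("run '%s' has a zero total spectral count",
                       colnames(m)[which(colSums(m) == 0)[1]]))
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must contain a 'group' column")
    if (anyDuplicated(rownames(m)))
        return("duplicated protein identifiers")
    TRUE
})

#' Construct a SpectralCountExperiment
#'
#' @param counts integer matrix, proteins in rows, runs in columns; both
#'   dimensions named.
#' @param group character vector of group labels (one per run), typically
#'   \code{"TD"} / \code{"ASD"}.
#' @return A \linkS4class{SpectralCountExperiment}.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 10L, 2L, 1L), nrow = 3,
#'             dimnames = list(c("P1", "P2", "P3"), c("run1", "run2")))
#' SpectralCountExperiment(m, group = c("TD", "ASD"))
#' @export
SpectralCountExperiment <- function(counts, group) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       row.names = colnames(counts)))
    methods::new("SpectralCountExperiment", se)
}

#' Fixed-width peptide windows around candidate glycosites
#'
#' Holds residue windows of width \code{2k + 1} centered on a candidate
#' glycosite residue. Terminus-truncated windows are padded with
#' \code{"X"}; the padding letter never matches a fixed motif position.
#'
#' @slot windows character vector of equal-length residue strings.
#' @slot halfWidth integer half-width k (window width 2k + 1).
#' @slot centerResidue single letter every window carries at its center.
#' @slot role \code{"foreground"} or \code{"background"}.
#' @aliases PeptideWindowSet-class
#' @exportClass PeptideWindowSet
setClass("PeptideWindowSet",
         representation(windows = "character", halfWidth = "integer",
                        centerResidue = "character", role = "character"))

setValidity("PeptideWindowSet", function(object) {
    w <- 2L * object@halfWidth + 1L
    if (object@halfWidth < 1L) return("halfWidth must be >= 1")
    if (length(object@windows) &&
        !all(nchar(object@windows) == w))
        return(sprintf("all windows must have width %d", w))
    if (length(object@windows)) {
        centers <- substr(object@windows, object@halfWidth + 1L,
                          object@halfWidth + 1L)
        if (!all(centers == object@centerResidue))
            return(sprintf("all windows must carry '%s' at the center",
                           object@centerResidue))
    }
    if (!object@role %in% c("foreground", "background"))
        return("role must be 'foreground' or 'background'")
    TRUE
})

#' Construct a PeptideWindowSet from ready-made window strings
#'
#' @param windows character vector of residue windows, all of width
#'   \code{2 * halfWidth + 1}.
#' @param halfWidth integer half-width k.
#' @param centerResidue the residue fixed at the window center.
#' @param role \code{"foreground"} or \code{"background"}.
#' @return A \linkS4class{PeptideWindowSet}.
#' @export
PeptideWindowSet <- function(windows, halfWidth,
                             centerResidue = "N",
                             role = c("foreground", "background")) {
    role <- match.arg(role)
    methods::new("PeptideWindowSet", windows = as.character(windows),
                 halfWidth = as.integer(halfWidth),
                 centerResidue = centerResidue, role = role)
}

#' @export
setMethod("length", "PeptideWindowSet", function(x) length(x@windows))

setMethod("show", "PeptideWindowSet", function(object) {
    cat(sprintf("PeptideWindowSet: %d %s window(s), width %d, center '%s'\n",
                length(object@windows), object@role,
                2L * object@halfWidth + 1L, object@centerResidue))
})

#' Accessors for PeptideWindowSet
#'
#' @param x a \linkS4class{PeptideWindowSet}.
#' @return \code{windowStrings} returns the character vector of windows;
#'   \code{halfWidth} the integer half-width; \code{centerResidue} the
#'   center letter.
#' @name windowStrings
#' @export
windowStrings <- function(x) x@windows

#' @rdname windowStrings
#' @export
halfWidth <- function(x) x@halfWidth

#' @rdname windowStrings
#' @export
centerResidue <- function(x) x@centerResidue

#' An extracted sequence motif
#'
#' One over-represented consensus produced by \code{\link{extractMotifs}}:
#' an ordered list of fixed (offset, residue) steps, each with its exact
#' binomial p-value and the foreground/background window counts before and
#' after fixing the step. The motif score is the sum of -log10 p over
#' steps (tail probabilities floored at 1e-16); the fold increase is the
#' ratio of match fractions on the original, unreduced window sets.
#'
#' @slot pattern consensus rendered with fixed residues and "x" wildcards.
#' @slot steps data.frame with columns position, residue, p_value,
#'   fg_before, fg_after, bg_before, bg_after.
#' @slot motifScore numeric, sum of -log10 step p-values.
#' @slot foldIncrease numeric, foreground/background match-fraction ratio.
#' @slot fgMatches,bgMatches,fgTotal,bgTotal integer match accounting on
#'   the original sets.
#' @aliases GlycoMotif-class
#' @exportClass GlycoMotif
setClass("GlycoMotif",
         representation(pattern = "character", steps = "data.frame",
                        motifScore = "numeric", foldIncrease = "numeric",
                        fgMatches = "integer", bgMatches = "integer",
                        fgTotal = "integer", bgTotal = "integer"))

setMethod("show", "GlycoMotif", function(object) {
    cat(sprintf(
        "GlycoMotif %s | %d step(s), score %.2f, fold increase %.2f (fg %d/%d, bg %d/%d)\n",
        object@pattern, nrow(object@steps), object@motifScore,
        object@foldIncrease, object@fgMatches, object@fgTotal,
        object@bgMatches, object@bgTotal))
})

#' Accessors for GlycoMotif
#'
#' @param x a \linkS4class{GlycoMotif}.
#' @return \code{motifPattern}: the rendered consensus; \code{motifSteps}:
#'   the step table; \code{motifScore}: sum of -log10 step p-values;
#'   \code{motifFoldIncrease}: fg/bg match-fraction ratio.
#' @name motifPattern
#' @export
motifPattern <- function(x) x@pattern

#' @rdname motifPattern
#' @export
motifSteps <- function(x) x@steps

#' @rdname motifPattern
#' @export
motifScore <- function(x) x@motifScore

#' @rdname motifPattern
#' @export
motifFoldIncrease <- function(x) x@foldIncrease

#' ROC analysis result
#'
#' Empirical ROC curve for a two-group biomarker score, with AUC by the
#' Mann-Whitney identity (ties count one half) and the operating point
#' maximizing Youden's J = sensitivity + specificity - 1 (ties broken
#' toward higher specificity).
#'
#' @slot auc numeric in [0, 1].
#' @slot points data.frame with columns threshold, fpr (1 - specificity)
#'   and tpr (sensitivity), starting at (0, 0) and ending at (1, 1).
#' @slot threshold numeric score threshold at the operating point
#'   (score >= threshold calls the positive class).
#' @slot sensitivity,specificity numeric at the operating point.
#' @slot positiveClass label treated as positive (default "ASD").
#' @aliases RocResult-class
#' @exportClass RocResult
setClass("RocResult",
         representation(auc = "numeric", points = "data.frame",
                        threshold = "numeric", sensitivity = "numeric",
                        specificity = "numeric", positiveClass = "character"))

setMethod("show", "RocResult", function(object) {
    cat(sprintf(
        "RocResult: AUC %.3f (positive = %s); Youden point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
        object@auc, object@positiveClass, object@threshold,
        100 * object@sensitivity, 100 * object@specificity))
})

#' Accessors for RocResult
#'
#' @param x a \linkS4class{RocResult}.
#' @return \code{auc}: the area under the curve; \code{rocPoints}: the
#'   (threshold, fpr, tpr) table; \code{youdenPoint}: a named numeric with
#'   threshold, sensitivity, specificity.
#' @name auc
#' @export
auc <- function(x) x@auc

#' @rdname auc
#' @export
rocPoints <- function(x) x@points

#' @rdname auc
#' @export
youdenPoint <- function(x) {
    c(threshold = x@threshold, sensitivity = x@sensitivity,
      specificity = x@specificity)
}
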