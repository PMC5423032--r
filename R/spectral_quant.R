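## Label-free relative quantification by spectral counting: run-depth
## normalization N_i = R_i * (Cbar / C_i), spectral-index summaries per
## group, ASD/TD ratio classification and identification-set accounting.

#' Normalize spectral counts for run depth
#'
#' Each run's total spectral count C_i is scaled to the average total
#' Cbar over all runs under comparison: the normalized count of a protein
#' in run i is N_i = R_i * (Cbar / C_i), where R_i is the raw count.
#' After normalization every run's total equals Cbar.
#'
#' @param sce a \linkS4class{SpectralCountExperiment} with >= 2 runs.
#' @return the same object with an added \code{"normalized"} assay and a
#'   \code{runNormalization} data.frame (run_id, group, C_i, C_bar,
#'   scale) stored in \code{metadata()}.
#' @examples
#' m <- matrix(c(5L, 95L, 10L, 190L, 15L, 285L), nrow = 2,
#'             dimnames = list(c("P1", "P2"), c("r1", "r2", "r3")))
#' sce <- SpectralCountExperiment(m, group = c("TD", "TD", "ASD"))
#' SummarizedExperiment::assay(normalizeRuns(sce), "normalized")["P1", ]
#' @export
normalizeRuns <- function(sce) {
    m <- SummarizedExperiment::assay(sce, "counts")
    if (ncol(m) < 2L)
        stop("validation error: need >= 2 runs under comparison",
             call. = FALSE)
    C_i <- colSums(m)
    if (any(C_i == 0))
        stop(sprintf("validation error: run '%s' has total count 0",
                     colnames(m)[which(C_i == 0)[1]]), call. = FALSE)
    C_bar <- mean(C_i)
    scale <- C_bar / C_i
    norm <- sweep(m, 2, scale, `*`)
    SummarizedExperiment::assay(sce, "normalized") <- norm
    S4Vectors::metadata(sce)$runNormalization <- data.frame(
        run_id = colnames(m),
        group = SummarizedExperiment::colData(sce)$group,
        C_i = as.numeric(C_i), C_bar = C_bar, scale = as.numeric(scale),
        row.names = NULL)
    sce
}

#' Accessor for the run-normalization table
#'
#' @param sce a \linkS4class{SpectralCountExperiment} processed by
#'   \code{\link{normalizeRuns}}.
#' @return data.frame with run_id, group, C_i, C_bar, scale.
#' @export
runNormalization <- function(sce) S4Vectors::metadata(sce)$runNormalization

#' Spectral index of one protein in one group
#'
#' The spectral index (SI) summarizing a protein's abundance in a group
#' is the mean of its depth-normalized counts over the group's runs,
#' zero runs included; it is 0 iff the protein is absent from every run
#' of the group.
#'
#' @param normalized numeric vector of a protein's normalized counts over
#'   the group's runs (>= 1 run).
#' @return non-negative numeric scalar.
#' @examples
#' spectralIndex(c(4, 8, 0))  # 4
#' @export
spectralIndex <- function(normalized) {
    if (!length(normalized))
        stop("validation error: group has no runs", call. = FALSE)
    mean(normalized)
}

#' Classify regulation from two spectral indices
#'
#' The abundance ratio is oriented ASD / TD. A protein is \code{up} when
#' both indices are positive and the ratio >= \code{up} (boundary
#' inclusive), \code{down} when both are positive and the ratio <=
#' \code{down}, \code{asd_only} / \code{td_only} when the other group's
#' index is 0, otherwise \code{unchanged}.
#'
#' @param si_td,si_asd non-negative spectral indices (vectorized).
#' @param up,down classification thresholds (defaults 1.5 and 0.67).
#' @return data.frame (si_td, si_asd, ratio, regulation).
#' @examples
#' classifyRegulation(10, 15)$regulation  # "up" (boundary 1.5 inclusive)
#' @export
classifyRegulation <- function(si_td, si_asd, up = 1.5, down = 0.67) {
    if (any(si_td < 0 | si_asd < 0))
        stop("validation error: spectral indices must be >= 0",
             call. = FALSE)
    if (any(si_td == 0 & si_asd == 0))
        stop("undefined protein: both spectral indices are 0",
             call. = FALSE)
    ratio <- ifelse(si_td > 0, si_asd / si_td, Inf)
    regulation <- rep("unchanged", length(ratio))
    regulation[si_td > 0 & si_asd > 0 & ratio >= up] <- "up"
    regulation[si_td > 0 & si_asd > 0 & ratio <= down] <- "down"
    regulation[si_td == 0] <- "asd_only"
    regulation[si_asd == 0] <- "td_only"
    data.frame(si_td = si_td, si_asd = si_asd, ratio = ratio,
               regulation = regulation)
}

#' Quantify and classify every protein
#'
#' Runs \code{\link{normalizeRuns}} (unless already done), computes the
#' TD and ASD spectral indices of every protein and classifies its
#' regulation. Proteins supported by fewer than \code{min_peptides}
#' unique peptides (when a peptide count is supplied) are retained but
#' flagged.
#'
#' @param sce a \linkS4class{SpectralCountExperiment}.
#' @param up,down ratio thresholds (defaults 1.5 / 0.67).
#' @param peptide_counts optional named integer vector of unique-peptide
#'   counts per protein.
#' @param min_peptides minimum peptide support before flagging
#'   (default 1, i.e. nothing flagged).
#' @return data.frame (protein_id, si_td, si_asd, ratio, regulation,
#'   low_peptide_support) ordered as in the input matrix.
#' @export
quantifyProteins <- function(sce, up = 1.5, down = 0.67,
                             peptide_counts = NULL, min_peptides = 1L) {
    if (!"normalized" %in% SummarizedExperiment::assayNames(sce))
        sce <- normalizeRuns(sce)
    norm <- SummarizedExperiment::assay(sce, "normalized")
    grp <- SummarizedExperiment::colData(sce)$group
    if (!all(c("TD", "ASD") %in% grp))
        stop("validation error: both TD and ASD runs are required",
             call. = FALSE)
    si_td <- rowMeans(norm[, grp == "TD", drop = FALSE])
    si_asd <- rowMeans(norm[, grp == "ASD", drop = FALSE])
    present <- si_td > 0 | si_asd > 0
    cls <- classifyRegulation(si_td[present], si_asd[present],
                              up = up, down = down)
    out <- data.frame(protein_id = rownames(norm)[present], cls,
                      row.names = NULL, stringsAsFactors = FALSE)
    out$low_peptide_support <- FALSE
    if (!is.null(peptide_counts))
        out$low_peptide_support <-
            peptide_counts[out$protein_id] < min_peptides
    out
}

#' Identification-set accounting
#'
#' Inclusion-exclusion accounting of the protein (and optionally peptide)
#' identifier sets of the two sera: counts per group, in common, specific
#' to each group and in the union, with the common fraction reported as a
#' percentage of the union rounded to one decimal.
#'
#' @param td,asd character vectors (or sets) of protein identifiers.
#' @param td_peptides,asd_peptides optional peptide identifier sets.
#' @return list with a \code{proteins} data.frame (n_td, n_asd, n_common,
#'   n_td_only, n_asd_only, n_union, common_pct) and, when peptide sets
#'   are given, a matching \code{peptides} data.frame.
#' @examples
#' a <- identificationAccounting(td = paste0("p", 1:194),
#'                               asd = paste0("p", c(1:168, 300:348)))
#' a$proteins$n_union   # 243
#' a$proteins$common_pct  # 69.1
#' @export
identificationAccounting <- function(td, asd, td_peptides = NULL,
                                     asd_peptides = NULL) {
    one <- function(a, b) {
        a <- unique(a); b <- unique(b)
        n_common <- length(intersect(a, b))
        n_union <- length(union(a, b))
        data.frame(n_td = length(a), n_asd = length(b),
                   n_common = n_common,
                   n_td_only = length(a) - n_common,
                   n_asd_only = length(b) - n_common,
                   n_union = n_union,
                   common_pct = round(100 * n_common / n_union, 1))
    }
    out <- list(proteins = one(td, asd))
    if (!is.null(td_peptides) && !is.null(asd_peptides))
        out$peptides <- one(td_peptides, asd_peptides)
    out
}
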