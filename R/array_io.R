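## Tabular I/O for every format the pipeline consumes: spot tables
## (a minimal GPR-inspired TSV dialect), spectral-count matrices with a
## run-metadata sidecar, amino-acid FASTA, glycosylation annotation flags
## and sample metadata. All readers validate before returning.

.SPOT_COLUMNS <- c("sample_id", "block_id", "probe", "replicate",
                   "foreground", "background")

.DEFAULT_CONTROLS <- c("BSA", "buffer")

.read_tsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    if (file.size(path) == 0L)
        stop(sprintf("format error: empty file: %s", path), call. = FALSE)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}

#' Read a microarray spot table
#'
#' Reads the tab-separated spot dialect this package uses for lectin
#' microarrays, serum microarrays and lectin/glyco-antibody microarrays:
#' one row per spot with columns \code{sample_id}, \code{block_id},
#' \code{probe}, \code{replicate}, \code{foreground}, \code{background}.
#' Control probes (by default \code{"BSA"} and \code{"buffer"}) are
#' retained and flagged in an \code{is_control} column; downstream
#' normalization excludes them from denominators.
#'
#' @param path path to a UTF-8 TSV file.
#' @param control_probes character vector of probe names treated as
#'   negative controls.
#' @return A data.frame of spot records (one row per spot), with
#'   \code{foreground}/\code{background} numeric and an added logical
#'   \code{is_control} column, ordered by sample.
#' @export
readSpotTable <- function(path, control_probes = .DEFAULT_CONTROLS) {
    df <- .read_tsv(path)
    missing <- setdiff(.SPOT_COLUMNS, colnames(df))
    if (length(missing))
        stop(sprintf("format error: spot table is missing column(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    df <- df[, .SPOT_COLUMNS]
    for (col in c("foreground", "background")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(!is.finite(v))
        if (length(bad))
            stop(sprintf("validation error: non-numeric %s in row %d",
                         col, bad[1]), call. = FALSE)
        neg <- which(v < 0)
        if (length(neg))
            stop(sprintf("validation error: negative %s (%g) in row %d",
                         col, v[neg[1]], neg[1]), call. = FALSE)
        df[[col]] <- v
    }
    df$replicate <- as.integer(df$replicate)
    if (any(is.na(df$replicate)) || any(df$replicate < 1))
        stop("validation error: replicate must be a positive integer",
             call. = FALSE)
    key <- paste(df$sample_id, df$block_id, df$probe, df$replicate)
    if (anyDuplicated(key))
        stop(sprintf(
            "validation error: duplicated (sample, block, probe, replicate): %s",
            key[duplicated(key)][1]), call. = FALSE)
    df$is_control <- df$probe %in% control_probes
    df[order(match(df$sample_id, unique(df$sample_id))), , drop = FALSE]
}

#' Write a spot table
#'
#' @param spots data.frame as returned by \code{\link{readSpotTable}} (an
#'   \code{is_control} column, if present, is dropped on write).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
    utils::write.table(spots[, .SPOT_COLUMNS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a spectral-count matrix with run metadata
#'
#' The count matrix is a TSV with a \code{protein_id} first column and one
#' column per LC-MS/MS run; the sidecar metadata TSV maps \code{run_id} to
#' its comparison \code{group}.
#'
#' @param path path to the count-matrix TSV.
#' @param metadata_path path to the run-metadata TSV (columns
#'   \code{run_id}, \code{group}).
#' @return A \linkS4class{SpectralCountExperiment}.
#' @export
readCountMatrix <- function(path, metadata_path) {
    df <- .read_tsv(path)
    if (colnames(df)[1] != "protein_id")
        stop("format error: first column must be 'protein_id'",
             call. = FALSE)
    if (ncol(df) < 2L)
        stop("format error: count matrix has no run columns", call. = FALSE)
    if (anyDuplicated(df$protein_id))
        stop(sprintf("validation error: duplicated protein id '%s'",
                     df$protein_id[duplicated(df$protein_id)][1]),
             call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    if (any(!is.finite(m)))
        stop("validation error: non-numeric count cell", call. = FALSE)
    if (any(abs(m - round(m)) > 1e-8)) {
        bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
        stop(sprintf("validation error: non-integer count %g at (%s, %s)",
                     m[bad[1], bad[2]], df$protein_id[bad[1]],
                     colnames(m)[bad[2]]), call. = FALSE)
    }
    if (any(m < 0))
        stop("validation error: negative count", call. = FALSE)
    rownames(m) <- df$protein_id
    meta <- .read_tsv(metadata_path)
    if (!all(c("run_id", "group") %in% colnames(meta)))
        stop("format error: run metadata needs columns run_id, group",
             call. = FALSE)
    missing <- setdiff(colnames(m), meta$run_id)
    if (length(missing))
        stop(sprintf("validation error: run '%s' has no group label",
                     missing[1]), call. = FALSE)
    group <- meta$group[match(colnames(m), meta$run_id)]
    SpectralCountExperiment(round(m), group = group)
}

#' Write a spectral-count matrix and its run metadata
#'
#' @param sce a \linkS4class{SpectralCountExperiment}.
#' @param path output TSV path for the counts.
#' @param metadata_path output TSV path for the run metadata.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(sce, path, metadata_path) {
    m <- SummarizedExperiment::assay(sce, "counts")
    df <- data.frame(protein_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- data.frame(run_id = colnames(m),
                       group = SummarizedExperiment::colData(sce)$group)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read amino-acid sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20 standard residue
#' letters plus \code{X} (unknown). Duplicate identifiers and residues
#' outside the alphabet are rejected.
#'
#' @param path path to a FASTA file.
#' @return A named \code{Biostrings::AAStringSet}.
#' @export
readFastaAA <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    aa <- Biostrings::readAAStringSet(path)
    if (anyDuplicated(names(aa)))
        stop(sprintf("validation error: duplicate sequence id '%s'",
                     names(aa)[duplicated(names(aa))][1]), call. = FALSE)
    seqs <- toupper(as.character(aa))
    letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    illegal <- setdiff(letters_used, .AA_ALPHABET)
    if (length(illegal))
        stop(sprintf("validation error: illegal residue letter '%s'",
                     illegal[1]), call. = FALSE)
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- names(aa)
    out
}

#' Write amino-acid sequences to FASTA
#'
#' @param seqs a named \code{AAStringSet} or named character vector.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeFastaAA <- function(seqs, path) {
    if (!methods::is(seqs, "AAStringSet")) {
        nm <- names(seqs)
        seqs <- Biostrings::AAStringSet(as.character(seqs))
        names(seqs) <- nm
    }
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read glycosylation annotation flags
#'
#' TSV with \code{protein_id} plus any of the 0/1 columns \code{known_N},
#' \code{known_O}, \code{predicted_N}, \code{predicted_O} and optionally
#' \code{known} (protein present in the reference database). Absent
#' columns are filled with 0.
#'
#' @param path path to the flags TSV.
#' @return data.frame with logical flag columns, one row per protein.
#' @export
readAnnotationFlags <- function(path) {
    df <- .read_tsv(path)
    if (!"protein_id" %in% colnames(df))
        stop("format error: flags table is missing column: protein_id",
             call. = FALSE)
    if (anyDuplicated(df$protein_id))
        stop("validation error: duplicated protein id in flags table",
             call. = FALSE)
    flags <- c("known_N", "known_O", "predicted_N", "predicted_O", "known")
    for (f in flags) {
        v <- if (f %in% colnames(df)) df[[f]] else 0
        v[is.na(v)] <- 0
        if (!all(v %in% c(0, 1)))
            stop(sprintf("validation error: column %s must be 0/1", f),
                 call. = FALSE)
        df[[f]] <- as.logical(v)
    }
    df[, c("protein_id", flags)]
}

#' Read sample metadata
#'
#' TSV with columns \code{sample_id}, \code{group} (TD or ASD) and an
#' optional \code{subgroup_index} pairing key for pooled subgroups.
#'
#' @param path path to the metadata TSV.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    df <- .read_tsv(path)
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("format error: metadata needs columns sample_id, group",
             call. = FALSE)
    if (anyDuplicated(df$sample_id))
        stop("validation error: duplicated sample_id", call. = FALSE)
    if (!all(df$group %in% c("TD", "ASD")))
        stop("validation error: group must be 'TD' or 'ASD'", call. = FALSE)
    if ("subgroup_index" %in% colnames(df)) {
        df$subgroup_index <- as.integer(df$subgroup_index)
        for (g in unique(df$group)) {
            idx <- df$subgroup_index[df$group == g]
            idx <- idx[!is.na(idx)]
            if (anyDuplicated(idx))
                stop(sprintf(
                    "validation error: subgroup_index reused within group %s",
                    g), call. = FALSE)
        }
    }
    df
}
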