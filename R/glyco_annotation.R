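## Glycoprotein category classification: known/predicted N- and
## O-glycosylation flags plus a built-in N-X-S/T sequon scanner
## (X != proline). O-glycosite prediction is not reimplemented; the
## predicted_O flag must be supplied externally.

#' Scan a protein sequence for N-glycosylation sequons
#'
#' In mammals N-glycosylation occurs at N-X-S/T motifs where X cannot be
#' proline. Returns the 1-based positions p with residue(p) = N,
#' residue(p + 1) != P and residue(p + 2) in \{S, T\}. Overlapping
#' sequons (e.g. "NNSS" at 1 and 2) are all reported; positions within 2
#' of the C-terminus cannot match.
#'
#' @param sequence amino-acid string (standard letters plus X).
#' @return integer vector of sequon positions (empty for no match or an
#'   empty sequence).
#' @examples
#' scanNSequons("NAS")  # 1
#' scanNSequons("NPS")  # integer(0): X cannot be proline
#' @export
scanNSequons <- function(sequence) {
    sequence <- toupper(as.character(sequence))
    if (is.na(sequence) || nchar(sequence) < 3L) return(integer(0))
    m <- gregexpr("N(?=[^P][ST])", sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Categorize proteins into glycosylation classes
#'
#' Combines externally supplied annotation flags with the built-in sequon
#' scanner: a protein with a sequence gains \code{predicted_N} when it
#' carries at least one N-X-S/T sequon. Known annotation takes precedence
#' over prediction in the primary \code{category}; all applicable labels
#' are also reported. A protein with neither flags nor sequence is
#' \code{unknown_protein}; a protein with all flags false (and no sequon)
#' is \code{nonglyco}.
#'
#' @param flags data.frame as from \code{\link{readAnnotationFlags}}
#'   (protein_id plus logical known_N, known_O, predicted_N, predicted_O
#'   and optional known).
#' @param sequences optional named AAStringSet or character vector; used
#'   both for sequon scanning and to mark proteins as having sequence
#'   evidence.
#' @return data.frame (protein_id, known_N, known_O, predicted_N,
#'   predicted_O, category, labels, sequon_positions) where
#'   \code{sequon_positions} is a comma-joined position list.
#' @export
categorizeGlyco <- function(flags, sequences = NULL) {
    seqs <- if (is.null(sequences)) character(0) else {
        s <- as.character(sequences)
        names(s) <- names(sequences)
        s
    }
    rows <- lapply(seq_len(nrow(flags)), function(i) {
        f <- flags[i, ]
        seq <- if (f$protein_id %in% names(seqs)) seqs[[f$protein_id]]
               else NA_character_
        pos <- if (!is.na(seq)) scanNSequons(seq) else integer(0)
        predicted_N <- isTRUE(f$predicted_N) || length(pos) > 0
        has_info <- any(f$known_N, f$known_O, f$predicted_N,
                        f$predicted_O) || !is.na(seq)
        labels <- c(if (isTRUE(f$known_N)) "N_Y",
                    if (isTRUE(f$known_O)) "O_Y",
                    if (predicted_N) "N_P",
                    if (isTRUE(f$predicted_O)) "O_P")
        category <- if (!has_info) "unknown_protein"
            else if (length(labels)) labels[1] else "nonglyco"
        data.frame(protein_id = f$protein_id,
                   known_N = isTRUE(f$known_N), known_O = isTRUE(f$known_O),
                   predicted_N = predicted_N,
                   predicted_O = isTRUE(f$predicted_O),
                   category = category,
                   labels = paste(labels, collapse = ","),
                   sequon_positions = paste(pos, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Tally glycosylation categories with explicit denominators
#'
#' Reports the count and percentage (one decimal) of each glycosylation
#' label. Known-glycoprotein labels (N_Y, O_Y) are counted over the known
#' proteins; predicted labels (N_P, O_P) over the novel (non-known)
#' subset, mirroring how such studies report them. Each row records the
#' denominator it used.
#'
#' @param categories data.frame from \code{\link{categorizeGlyco}}.
#' @param known logical vector marking known proteins (same order); when
#'   NULL, a protein is known iff known_N or known_O.
#' @return data.frame (label, count, denominator, pct).
#' @examples
#' cats <- data.frame(protein_id = paste0("p", 1:4),
#'                    known_N = c(TRUE, TRUE, FALSE, FALSE),
#'                    known_O = c(FALSE, TRUE, FALSE, FALSE),
#'                    predicted_N = c(FALSE, FALSE, TRUE, FALSE),
#'                    predicted_O = FALSE)
#' tallyCategories(cats, known = c(TRUE, TRUE, FALSE, FALSE))
#' @export
tallyCategories <- function(categories, known = NULL) {
    if (is.null(known))
        known <- categories$known_N | categories$known_O
    n_known <- sum(known)
    n_novel <- sum(!known)
    pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA
    rows <- list(
        data.frame(label = "N_Y", count = sum(categories$known_N & known),
                   denominator = n_known),
        data.frame(label = "O_Y", count = sum(categories$known_O & known),
                   denominator = n_known),
        data.frame(label = "N_P",
                   count = sum(categories$predicted_N & !known),
                   denominator = n_novel),
        data.frame(label = "O_P",
                   count = sum(categories$predicted_O & !known),
                   denominator = n_novel),
        data.frame(label = "nonglyco",
                   count = sum(categories$category == "nonglyco"),
                   denominator = nrow(categories)),
        data.frame(label = "unknown_protein",
                   count = sum(categories$category == "unknown_protein"),
                   denominator = nrow(categories)))
    out <- do.call(rbind, rows)
    out$pct <- mapply(pct, out$count, out$denominator)
    out
}

#' Tally the partitioning primary categories
#'
#' Counts proteins by their single primary \code{category} (precedence
#' N_Y > O_Y > N_P > O_P > nonglyco > unknown_protein) over the full
#' protein set, so the percentages sum to 100 up to rounding.
#'
#' @param categories data.frame from \code{\link{categorizeGlyco}}.
#' @return data.frame (category, count, pct) with a common denominator.
#' @export
tallyPrimaryCategories <- function(categories) {
    lv <- c("N_Y", "O_Y", "N_P", "O_P", "nonglyco", "unknown_protein")
    counts <- table(factor(categories$category, levels = lv))
    data.frame(category = lv, count = as.integer(counts),
               pct = round(100 * as.integer(counts) / nrow(categories), 1),
               row.names = NULL)
}
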