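## Validation-stage analysis: per-sample antibody (or lectin) signals from
## lectin/glyco-antibody microarray blocks, TD-vs-ASD group comparison,
## and ROC/AUC biomarker evaluation with a Youden operating point.

#' Per-sample antibody signals from LGAM spot tables
#'
#' Applies the shared background rule (\code{\link{filterEffectiveSpots}})
#' block by block, then takes, per sample and antibody, the median net
#' intensity over all effective replicate spots across that sample's
#' blocks (the design this emulates prints each antibody in quintuplicate
#' per block with triplicate blocks). Control probes are excluded. A
#' sample-antibody pair whose spots are all rejected is reported as
#' missing (NA), not zero.
#'
#' @param spots spot-table data.frame (see \code{\link{readSpotTable}}).
#' @param metadata sample metadata data.frame (sample_id, group).
#' @return data.frame (sample_id, antibody, median_signal, n_effective,
#'   group); \code{median_signal} is NA where all spots were rejected.
#' @export
lgamSignals <- function(spots, metadata) {
    keep_ctrl <- if ("is_control" %in% colnames(spots)) !spots$is_control
                 else !(spots$probe %in% .DEFAULT_CONTROLS)
    spots <- spots[keep_ctrl, , drop = FALSE]
    eff <- do.call(rbind, lapply(
        split(spots, list(spots$sample_id, spots$block_id), drop = TRUE),
        function(b) {
            e <- filterEffectiveSpots(b)$effective
            if (nrow(e)) cbind(sample_id = b$sample_id[1], e)
            else NULL
        }))
    pairs <- unique(spots[, c("sample_id", "probe")])
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        vals <- if (is.null(eff)) numeric(0)
                else eff$net[eff$sample_id == pairs$sample_id[i] &
                             eff$probe == pairs$probe[i]]
        data.frame(sample_id = pairs$sample_id[i],
                   antibody = pairs$probe[i],
                   median_signal = if (length(vals)) stats::median(vals)
                                   else NA_real_,
                   n_effective = length(vals), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$group <- metadata$group[match(out$sample_id, metadata$sample_id)]
    out[order(out$antibody, out$sample_id), , drop = FALSE]
}

#' Compare one antibody's signals between groups
#'
#' Two-sided t-test of ASD vs TD signals: paired by sample index (the
#' default, matching how such studies report it, though the groups are
#' independent children — see the vignette for the caveat) or Welch.
#' Missing signals drop the sample (and, in paired mode, its partner).
#'
#' @param td,asd numeric signal vectors.
#' @param mode \code{"paired"} or \code{"welch"}.
#' @return list with \code{fold} (ASD mean / TD mean), \code{p_value}
#'   and \code{flag} ("" or "zero_variance" for a degenerate paired
#'   test, where p is NA).
#' @export
groupCompare <- function(td, asd, mode = c("paired", "welch")) {
    mode <- match.arg(mode)
    if (mode == "paired") {
        if (length(td) != length(asd))
            stop("validation error: paired mode needs equal group sizes",
                 call. = FALSE)
        ok <- !is.na(td) & !is.na(asd)
        td <- td[ok]; asd <- asd[ok]
    } else {
        td <- td[!is.na(td)]; asd <- asd[!is.na(asd)]
    }
    if (length(td) < 2L || length(asd) < 2L)
        stop("validation error: need >= 2 samples per group", call. = FALSE)
    fold <- mean(asd) / mean(td)
    if (mode == "paired" && all(asd - td == 0))
        return(list(fold = fold, p_value = NA_real_,
                    flag = "zero_variance"))
    p <- if (mode == "paired")
        stats::t.test(asd, td, paired = TRUE)$p.value
    else stats::t.test(asd, td, var.equal = FALSE)$p.value
    list(fold = fold, p_value = p, flag = "")
}

#' Empirical ROC curve with AUC and Youden operating point
#'
#' The curve sweeps every distinct score as a threshold (score >=
#' threshold calls the positive class), starting at (0, 0) and ending at
#' (1, 1). AUC is computed by the Mann-Whitney identity — the fraction
#' of (positive, negative) pairs in which the positive scores higher,
#' ties counting one half — and is therefore invariant under strictly
#' increasing transforms of the scores. The operating point maximizes
#' Youden's J = sensitivity + specificity - 1; ties resolve toward
#' higher specificity.
#'
#' @param scores numeric biomarker scores (higher = more positive-like).
#' @param groups group labels parallel to \code{scores}.
#' @param positive label of the positive class (default "ASD").
#' @return A \linkS4class{RocResult}.
#' @examples
#' r <- rocCurve(c(1, 2, 3, 2.5, 3.5, 4),
#'               rep(c("TD", "ASD"), each = 3))
#' auc(r)  # 8/9
#' @export
rocCurve <- function(scores, groups, positive = "ASD") {
    pos <- scores[groups == positive]
    neg <- scores[groups != positive]
    if (!length(pos) || !length(neg))
        stop("validation error: both groups must be nonempty",
             call. = FALSE)
    ## Mann-Whitney identity via midranks
    r <- rank(c(pos, neg))
    auc <- (sum(r[seq_along(pos)]) -
            length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
    points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                         tpr = c(0, tpr))
    if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
        points <- rbind(points,
                        data.frame(threshold = -Inf, fpr = 1, tpr = 1))
    j <- points$tpr - points$fpr
    spec <- 1 - points$fpr
    best <- which(j == max(j))
    best <- best[which.max(spec[best])]
    methods::new("RocResult", auc = auc, points = points,
                 threshold = points$threshold[best],
                 sensitivity = points$tpr[best],
                 specificity = spec[best],
                 positiveClass = positive)
}

#' Serum-microarray comparison of one labeled lectin across samples
#'
#' Runs the shared filter-and-median pipeline on the spot table of one
#' labeled-lectin probe read against immobilized individual sera, then
#' compares TD and ASD per-sample medians.
#'
#' @param spots spot-table data.frame containing one non-control probe.
#' @param metadata sample metadata (sample_id, group).
#' @param mode t-test mode passed to \code{\link{groupCompare}}.
#' @return list with \code{signals} (per-sample medians), \code{fold},
#'   \code{p_value}, \code{flag}.
#' @export
serumArrayCompare <- function(spots, metadata, mode = c("paired", "welch")) {
    mode <- match.arg(mode)
    probes <- unique(spots$probe[!(spots$probe %in% .DEFAULT_CONTROLS)])
    if (length(probes) != 1L)
        stop("validation error: expected exactly one labeled-lectin probe",
             call. = FALSE)
    sig <- lgamSignals(spots, metadata)
    td <- sig$median_signal[sig$group == "TD"]
    asd <- sig$median_signal[sig$group == "ASD"]
    if (length(td) < 2L || length(asd) < 2L)
        stop("validation error: need >= 2 samples per group", call. = FALSE)
    cmp <- groupCompare(td, asd, mode = mode)
    c(list(signals = sig), cmp)
}
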