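## Lectin microarray processing: background-based spot filtering, per-block
## median-sum normalization to NFIs (normalized fluorescence intensities),
## replicate aggregation, paired differential glycopattern analysis and
## average-linkage hierarchical clustering on 1 - Pearson distances.

.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Filter effective spots of one array block
#'
#' Implements the background rule applied to every block: the spot-level
#' backgrounds of the block are averaged; spots whose foreground falls
#' below mean(background) + 2 * SD(background) are removed as
#' noise-level; the surviving ("effective") spots are reported with net
#' intensity foreground - mean(background). SD uses the n - 1 denominator
#' (0 when only one background value exists). Negative nets are clamped
#' at 0 with a warning.
#'
#' @param spots data.frame of one block's spot records (columns
#'   \code{probe}, \code{replicate}, \code{foreground},
#'   \code{background}; an \code{is_control} column is carried through).
#' @return list with \code{effective} (probe, replicate, net, is_control),
#'   \code{rejected} (probe, replicate, foreground, reason),
#'   \code{background_mean}, \code{background_sd}, \code{cutoff}.
#' @examples
#' blk <- data.frame(probe = "L1", replicate = 1:3,
#'                   foreground = c(95, 100, 300),
#'                   background = c(85, 90, 95))
#' filterEffectiveSpots(blk)$effective$net  # 10, 210
#' @export
filterEffectiveSpots <- function(spots) {
    if (is.null(spots) || nrow(spots) == 0L)
        stop("validation error: empty block", call. = FALSE)
    bg_mean <- mean(spots$background)
    bg_sd <- .sd0(spots$background)
    cutoff <- bg_mean + 2 * bg_sd
    keep <- spots$foreground >= cutoff
    net <- spots$foreground[keep] - bg_mean
    if (any(net < 0)) {
        warning("negative net intensity clamped at 0")
        net[net < 0] <- 0
    }
    eff <- data.frame(probe = spots$probe[keep],
                      replicate = spots$replicate[keep],
                      net = net,
                      is_control = if ("is_control" %in% colnames(spots))
                          spots$is_control[keep] else rep(FALSE, sum(keep)),
                      stringsAsFactors = FALSE)
    rej <- data.frame(probe = spots$probe[!keep],
                      replicate = spots$replicate[!keep],
                      foreground = spots$foreground[!keep],
                      reason = rep(sprintf("foreground below cutoff %.6g",
                                           cutoff), sum(!keep)),
                      stringsAsFactors = FALSE)
    list(effective = eff, rejected = rej, background_mean = bg_mean,
         background_sd = bg_sd, cutoff = cutoff)
}

#' Normalize one block to NFIs
#'
#' The median net intensity of each lectin's effective spots is divided by
#' the sum of those medians over all (non-control) lectins in the block,
#' yielding normalized fluorescence intensities that sum to 1. Lectins
#' with no effective spots are absent from the result, not zero-filled.
#'
#' @param effective data.frame of effective spots as produced by
#'   \code{\link{filterEffectiveSpots}} (columns \code{probe}, \code{net},
#'   optionally \code{is_control}).
#' @return named numeric vector of NFIs (one entry per lectin).
#' @examples
#' eff <- data.frame(probe = c("A", "A", "A", "B"),
#'                   net = c(10, 20, 30, 80))
#' normalizeBlock(eff)  # A 0.2, B 0.8
#' @export
normalizeBlock <- function(effective) {
    if ("is_control" %in% colnames(effective))
        effective <- effective[!effective$is_control, , drop = FALSE]
    if (nrow(effective) == 0L)
        stop("degenerate block: no effective non-control spots",
             call. = FALSE)
    med <- tapply(effective$net, effective$probe, stats::median)
    med <- med[!is.na(med)]
    denom <- sum(med)
    if (denom <= 0)
        stop("degenerate block: sum of lectin medians is not positive",
             call. = FALSE)
    nfi <- med / denom
    out <- as.numeric(nfi)
    names(out) <- names(nfi)
    out
}

#' Aggregate replicate blocks of one sample
#'
#' Per lectin, the block-level NFIs are averaged over the blocks in which
#' the lectin is present, and their SD (n - 1 denominator, 0 for a single
#' block) is reported together with the coverage count.
#'
#' @param blocks list of named NFI vectors, one per replicate block (the
#'   design this emulates uses 9: 3 blocks on each of 3 slides).
#' @param sample_id optional sample label attached to the result.
#' @return data.frame (lectin, mean_nfi, sd_nfi, n_present) with
#'   attribute \code{n_blocks} and, when given, \code{sample_id}.
#' @export
aggregateSample <- function(blocks, sample_id = NULL) {
    if (!length(blocks))
        stop("validation error: no blocks to aggregate", call. = FALSE)
    lectins <- sort(unique(unlist(lapply(blocks, names))))
    vals <- vapply(blocks, function(b) b[lectins], numeric(length(lectins)))
    vals <- matrix(vals, nrow = length(lectins),
                   dimnames = list(lectins, NULL))
    out <- data.frame(
        lectin = lectins,
        mean_nfi = apply(vals, 1, function(x) mean(x, na.rm = TRUE)),
        sd_nfi = apply(vals, 1, function(x) .sd0(x[!is.na(x)])),
        n_present = rowSums(!is.na(vals)),
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "n_blocks") <- length(blocks)
    if (!is.null(sample_id)) attr(out, "sample_id") <- sample_id
    out
}

#' Run the spot-to-profile pipeline for every sample
#'
#' Convenience wrapper: splits a spot table by sample and block, applies
#' \code{\link{filterEffectiveSpots}} and \code{\link{normalizeBlock}} to
#' each block, and \code{\link{aggregateSample}} across a sample's blocks.
#'
#' @param spots spot-table data.frame (see \code{\link{readSpotTable}}).
#' @return list with \code{profiles} (matrix sample x lectin of mean
#'   NFIs; NA where a lectin was never effective for a sample),
#'   \code{sd} (matching SD matrix) and \code{per_sample} (list of
#'   \code{\link{aggregateSample}} tables).
#' @export
sampleProfiles <- function(spots) {
    per_sample <- lapply(split(spots, spots$sample_id), function(s) {
        blocks <- lapply(split(s, s$block_id), function(b) {
            normalizeBlock(filterEffectiveSpots(b)$effective)
        })
        aggregateSample(blocks, sample_id = s$sample_id[1])
    })
    lectins <- sort(unique(unlist(lapply(per_sample, `[[`, "lectin"))))
    samples <- names(per_sample)
    profiles <- matrix(NA_real_, length(samples), length(lectins),
                       dimnames = list(samples, lectins))
    sds <- profiles
    for (s in samples) {
        p <- per_sample[[s]]
        profiles[s, p$lectin] <- p$mean_nfi
        sds[s, p$lectin] <- p$sd_nfi
    }
    list(profiles = profiles, sd = sds, per_sample = per_sample)
}

#' Differential glycopattern analysis between paired subgroups
#'
#' Per lectin, computes fold change = mean over ASD subgroups / mean over
#' TD subgroups of the sample-level mean NFIs, and a two-sided paired
#' t-test p-value with TD and ASD subgroups matched by
#' \code{subgroup_index}. A lectin is called \code{up} when fold change
#' >= \code{fold_up} and p < \code{alpha}, \code{down} when fold change
#' <= \code{fold_down} and p < \code{alpha}, otherwise \code{unchanged}.
#' A lectin absent from a sample contributes 0. When every paired
#' difference is zero the test is degenerate and p is reported as 1.
#'
#' @param profiles matrix sample x lectin of mean NFIs (rownames are
#'   sample ids), as from \code{\link{sampleProfiles}}.
#' @param metadata data.frame with \code{sample_id}, \code{group}
#'   (TD/ASD) and \code{subgroup_index}.
#' @param fold_up,fold_down regulation thresholds (defaults 1.5 / 0.67).
#' @param alpha significance level for the t-test (default 0.05).
#' @param adjust p-adjustment method passed to \code{stats::p.adjust};
#'   default \code{"none"} (a \code{"BH"} option is available); the
#'   direction call always uses the raw p-value.
#' @return data.frame (lectin, td_mean, asd_mean, fold_change, p_value,
#'   p_adjusted, direction, infinite_fold) ordered by p-value.
#' @export
differentialLectins <- function(profiles, metadata, fold_up = 1.5,
                                fold_down = 0.67, alpha = 0.05,
                                adjust = "none") {
    md <- metadata[match(rownames(profiles), metadata$sample_id), ]
    if (any(is.na(md$sample_id)))
        stop("validation error: profile sample missing from metadata",
             call. = FALSE)
    td <- md$group == "TD"
    idx_td <- md$subgroup_index[td]
    idx_asd <- md$subgroup_index[!td]
    if (sum(td) != sum(!td) || !setequal(idx_td, idx_asd))
        stop("validation error: TD and ASD subgroups are not paired",
             call. = FALSE)
    if (sum(td) < 2L)
        stop("insufficient replicates: need >= 2 paired subgroups",
             call. = FALSE)
    x <- profiles
    x[is.na(x)] <- 0
    td_mat <- x[td, , drop = FALSE][order(idx_td), , drop = FALSE]
    asd_mat <- x[!td, , drop = FALSE][order(idx_asd), , drop = FALSE]
    res <- lapply(colnames(x), function(l) {
        tdv <- td_mat[, l]
        asdv <- asd_mat[, l]
        td_mean <- mean(tdv)
        asd_mean <- mean(asdv)
        inf_fold <- td_mean == 0 && asd_mean > 0
        fold <- if (td_mean > 0) asd_mean / td_mean else if (inf_fold)
            Inf else NaN
        d <- asdv - tdv
        ## degenerate paired tests: no shift at all -> p = 1; a perfectly
        ## constant nonzero shift -> p = 0
        p <- if (stats::sd(d) == 0) {
            if (all(d == 0)) 1 else 0
        } else stats::t.test(asdv, tdv, paired = TRUE)$p.value
        data.frame(lectin = l, td_mean = td_mean, asd_mean = asd_mean,
                   fold_change = fold, p_value = p,
                   infinite_fold = inf_fold, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
    out$direction <- "unchanged"
    out$direction[which(out$fold_change >= fold_up &
                        out$p_value < alpha)] <- "up"
    out$direction[which(out$fold_change <= fold_down &
                        out$p_value < alpha)] <- "down"
    out[order(out$p_value),
        c("lectin", "td_mean", "asd_mean", "fold_change", "p_value",
          "p_adjusted", "direction", "infinite_fold")]
}

## Pearson-correlation distance (1 - r) between rows; zero-variance rows
## get correlation 0 (distance 1) with a warning.
.corDist <- function(mat) {
    mat[is.na(mat)] <- 0
    v <- apply(mat, 1, stats::var)
    if (any(v == 0))
        warning(sprintf(
            "constant profile(s) %s: correlations defined as 0",
            paste(rownames(mat)[v == 0], collapse = ", ")))
    r <- suppressWarnings(stats::cor(t(mat)))
    r[!is.finite(r)] <- 0
    d <- 1 - r
    diag(d) <- 0
    d
}

## Deterministic UPGMA (unweighted average linkage) agglomeration with the
## lowest-index-pair tie-break; returns a stats::hclust object.
.agglomerate <- function(d, labels) {
    n <- nrow(d)
    if (n < 2L) stop("need >= 2 items to cluster", call. = FALSE)
    size <- rep(1L, n)
    id <- -seq_len(n)          # hclust encoding: negatives are singletons
    active <- seq_len(n)
    D <- d
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        best <- c(NA_integer_, NA_integer_)
        best_d <- Inf
        for (a in seq_along(active)[-length(active)]) {
            for (b in seq((a + 1L), length(active))) {
                dd <- D[active[a], active[b]]
                if (dd < best_d) {   # strict: first (lowest-index) pair wins
                    best_d <- dd
                    best <- c(active[a], active[b])
                }
            }
        }
        i <- best[1]; j <- best[2]
        merge[step, ] <- sort(c(id[i], id[j]))
        height[step] <- best_d
        ## UPGMA Lance-Williams update into slot i
        for (k in setdiff(active, c(i, j)))
            D[i, k] <- D[k, i] <-
                (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
        size[i] <- size[i] + size[j]
        id[i] <- step
        active <- setdiff(active, j)
    }
    ord_leaves <- function(k) {
        if (k < 0) return(-k)
        c(ord_leaves(merge[k, 1]), ord_leaves(merge[k, 2]))
    }
    structure(list(merge = merge, height = height,
                   order = ord_leaves(n - 1L), labels = labels,
                   method = "average", dist.method = "1 - Pearson"),
              class = "hclust")
}

#' Hierarchical clustering of samples and lectins
#'
#' Agglomerative clustering with distance 1 - Pearson correlation and
#' unweighted average linkage (UPGMA), applied to the rows (samples) and
#' the columns (lectins) of the NFI profile matrix. The merge sequence is
#' deterministic: ties resolve to the lowest-index pair. Dendrograms are
#' returned as \code{hclust} objects plus Newick serializations.
#'
#' @param profiles matrix sample x lectin of mean NFIs.
#' @return list with \code{samples} and \code{lectins} (each an
#'   \code{hclust}) and \code{newick} (named character vector of Newick
#'   strings).
#' @export
hierarchicalCluster <- function(profiles) {
    if (nrow(profiles) < 2L || ncol(profiles) < 2L)
        stop("validation error: need >= 2 profiles sharing >= 2 lectins",
             call. = FALSE)
    hs <- .agglomerate(.corDist(profiles), rownames(profiles))
    hl <- .agglomerate(.corDist(t(profiles)), colnames(profiles))
    to_newick <- function(h) {
        ## zero-height polytomies are fine in Newick; keep binary topology
        ape::write.tree(ape::as.phylo(h))
    }
    list(samples = hs, lectins = hl,
         newick = c(samples = to_newick(hs), lectins = to_newick(hl)))
}
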