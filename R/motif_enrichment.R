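## Iterative position-specific binomial motif extraction over fixed-width
## glycosite windows (the classical motif-x-style procedure): at each step
## the most significant (offset, residue) pair is fixed, both window sets
## are reduced to the matching windows, and the loop repeats until no pair
## clears the thresholds; emitted motifs are scored by the sum of -log10
## step p-values and filtered on the fold increase measured on the
## original, unreduced sets.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

## Floor applied to binomial tail probabilities before -log10 so motif
## scores stay finite.
.P_FLOOR <- 1e-16

#' Build peptide windows around candidate glycosites
#'
#' Cuts a window of width 2k + 1 centered on each candidate site.
#' Windows truncated by a protein terminus are padded with "X"; the
#' padding letter never matches a fixed motif position. Duplicate windows
#' are retained (each site counts once).
#'
#' @param sequences named AAStringSet or character vector of protein
#'   sequences.
#' @param sites data.frame with columns \code{protein_id} and
#'   \code{position} (1-based site positions).
#' @param k half-width (default 13, giving 27-residue windows).
#' @param center_residue residue every site must carry (default "N"; use
#'   "S" for O-glycosite centers).
#' @param role \code{"foreground"} or \code{"background"}.
#' @return A \linkS4class{PeptideWindowSet}.
#' @export
buildWindows <- function(sequences, sites, k = 13L,
                         center_residue = "N",
                         role = c("foreground", "background")) {
    role <- match.arg(role)
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
    k <- as.integer(k)
    pad <- strrep("X", k)
    windows <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
        id <- sites$protein_id[i]
        pos <- sites$position[i]
        if (!id %in% names(seqs))
            stop(sprintf("validation error: unknown protein '%s'", id),
                 call. = FALSE)
        s <- seqs[[id]]
        res <- substr(s, pos, pos)
        if (res != center_residue)
            stop(sprintf(
                "validation error: residue '%s' at %s position %d is not '%s'",
                res, id, pos, center_residue), call. = FALSE)
        padded <- paste0(pad, s, pad)
        windows[i] <- substr(padded, pos, pos + 2L * k)
    }
    PeptideWindowSet(windows, halfWidth = k,
                     centerResidue = center_residue, role = role)
}

## windows -> character matrix, one column per offset -k..k
.windowMatrix <- function(pws) {
    w <- 2L * pws@halfWidth + 1L
    m <- matrix(unlist(strsplit(pws@windows, "")), ncol = w, byrow = TRUE)
    colnames(m) <- as.character(seq(-pws@halfWidth, pws@halfWidth))
    m
}

#' Position-specific residue frequencies
#'
#' At each offset the relative frequencies over the 20 standard residues
#' are computed, excluding the "X" padding letter from the denominator.
#' An offset at which every window carries "X" is flagged undefined (all
#' NA).
#'
#' @param pws a \linkS4class{PeptideWindowSet} with >= 1 window.
#' @return numeric matrix residue x offset; attribute
#'   \code{undefined_offsets} lists all-"X" offsets.
#' @export
positionFrequencies <- function(pws) {
    if (!length(pws@windows))
        stop("validation error: empty window set", call. = FALSE)
    m <- .windowMatrix(pws)
    offs <- colnames(m)
    freq <- matrix(NA_real_, length(.AA20), length(offs),
                   dimnames = list(.AA20, offs))
    undefined <- character(0)
    for (j in seq_along(offs)) {
        col <- m[, j]
        col <- col[col != "X"]
        if (!length(col)) {
            undefined <- c(undefined, offs[j])
            next
        }
        tab <- table(factor(col, levels = .AA20))
        freq[, j] <- as.numeric(tab) / length(col)
    }
    attr(freq, "undefined_offsets") <- as.integer(undefined)
    freq
}

#' Exact binomial over-representation p-value
#'
#' Upper-tail probability P(X >= c) for X ~ Binomial(n, q): the chance of
#' seeing at least c foreground windows carrying a residue at an offset
#' when each window matches independently with the background frequency
#' q.
#'
#' @param n number of foreground windows.
#' @param c number of matching foreground windows.
#' @param q background match frequency in [0, 1].
#' @return p-value in [0, 1] (0 when q = 0 and c > 0; callers flooring
#'   for -log10 use 1e-16).
#' @examples
#' binomialEnrichment(20, 10, 0.05)
#' @export
binomialEnrichment <- function(n, c, q) {
    stopifnot(q >= 0, q <= 1, c >= 0, c <= n)
    if (c == 0) return(1)
    stats::pbinom(c - 1, size = n, prob = q, lower.tail = FALSE)
}

## count of windows matching every (position, residue) step
.matchCount <- function(mat, positions, residues) {
    ok <- rep(TRUE, nrow(mat))
    for (s in seq_along(positions))
        ok <- ok & mat[, as.character(positions[s])] == residues[s]
    sum(ok)
}

.matchMask <- function(mat, positions, residues) {
    ok <- rep(TRUE, nrow(mat))
    for (s in seq_along(positions))
        ok <- ok & mat[, as.character(positions[s])] == residues[s]
    ok
}

#' Fold increase of a motif
#'
#' Ratio of the fraction of foreground windows matching every fixed
#' (position, residue) of the motif to the matching fraction in the
#' background, both measured on the original, unreduced sets. A motif of
#' all wildcards has fold increase 1; zero background matches give Inf
#' (flagged by the caller).
#'
#' @param positions,residues parallel vectors of fixed positions
#'   (offsets, 0 = center excluded) and residues.
#' @param fg,bg \linkS4class{PeptideWindowSet} foreground / background.
#' @return list with \code{fold_increase}, \code{fg_matches},
#'   \code{bg_matches}, \code{fg_total}, \code{bg_total}.
#' @export
foldIncrease <- function(positions, residues, fg, bg) {
    fg_mat <- .windowMatrix(fg)
    bg_mat <- .windowMatrix(bg)
    fg_c <- if (length(positions)) .matchCount(fg_mat, positions, residues)
            else nrow(fg_mat)
    bg_c <- if (length(positions)) .matchCount(bg_mat, positions, residues)
            else nrow(bg_mat)
    fg_frac <- fg_c / nrow(fg_mat)
    bg_frac <- bg_c / nrow(bg_mat)
    fi <- if (bg_frac > 0) fg_frac / bg_frac
          else if (fg_frac > 0) Inf else 0
    list(fold_increase = fi, fg_matches = fg_c, bg_matches = bg_c,
         fg_total = nrow(fg_mat), bg_total = nrow(bg_mat))
}

.renderPattern <- function(k, center, positions, residues) {
    chars <- rep("x", 2L * k + 1L)
    chars[k + 1L] <- center
    chars[positions + k + 1L] <- residues
    paste(chars, collapse = "")
}

#' Trim a full-width pattern to a narrower rendering
#'
#' Collapses a width-(2k + 1) consensus to the central 2k' + 1 positions
#' (e.g. the 13-position renderings common in motif reports); fixed
#' positions outside the trimmed range are dropped.
#'
#' @param pattern full-width consensus string.
#' @param k_trim half-width of the trimmed rendering (default 6 -> 13
#'   positions).
#' @return trimmed consensus string.
#' @export
trimPattern <- function(pattern, k_trim = 6L) {
    w <- nchar(pattern)
    k <- (w - 1L) %/% 2L
    if (k_trim >= k) return(pattern)
    substr(pattern, k - k_trim + 1L, k + k_trim + 1L)
}

#' Extract over-represented motifs
#'
#' The iterative position-specific binomial procedure: for every
#' (offset, residue) pair the exact binomial tail p-value of the
#' foreground count against the current background frequency is
#' computed; the minimum-p pair with foreground count >=
#' \code{min_occurrences} and p < \code{p_threshold} is fixed into the
#' motif (ties: larger foreground count, then smaller offset magnitude,
#' then alphabetical residue); both sets are reduced to the matching
#' windows and the loop repeats. When no pair qualifies, a motif with
#' >= 1 step is emitted if its fold increase on the original sets
#' exceeds \code{min_fold_increase}; its matching foreground windows are
#' removed and the search restarts against the original background to
#' find further nonredundant motifs.
#'
#' Background frequencies count the "X" padding letter as a non-match in
#' both sets, so padding never supports enrichment. Step p-values are
#' floored at 1e-16 in the motif score.
#'
#' @param fg,bg \linkS4class{PeptideWindowSet} of equal width and center.
#' @param p_threshold step significance threshold (default 1e-6).
#' @param min_occurrences minimum foreground windows supporting a step
#'   (default 20).
#' @param min_fold_increase emission filter on the original-set fold
#'   increase (default 30).
#' @return list of \linkS4class{GlycoMotif}, in extraction order.
#' @export
extractMotifs <- function(fg, bg, p_threshold = 1e-6,
                          min_occurrences = 20L, min_fold_increase = 30) {
    if (!length(fg@windows) || !length(bg@windows))
        stop("validation error: empty foreground or background",
             call. = FALSE)
    if (fg@halfWidth != bg@halfWidth ||
        fg@centerResidue != bg@centerResidue)
        stop("validation error: foreground and background must share width and center",
             call. = FALSE)
    k <- fg@halfWidth
    offsets <- setdiff(seq(-k, k), 0L)
    fg_orig <- .windowMatrix(fg)
    bg_orig <- .windowMatrix(bg)
    fg_pool <- fg_orig
    motifs <- list()
    repeat {
        if (nrow(fg_pool) == 0L) break
        cur_fg <- fg_pool
        cur_bg <- bg_orig
        steps <- NULL
        repeat {
            best <- NULL
            n_fg <- nrow(cur_fg)
            n_bg <- nrow(cur_bg)
            if (n_fg == 0L || n_bg == 0L) break
            for (off in offsets) {
                col_fg <- cur_fg[, as.character(off)]
                col_bg <- cur_bg[, as.character(off)]
                cnt_fg <- table(factor(col_fg, levels = .AA20))
                cnt_bg <- table(factor(col_bg, levels = .AA20))
                for (r in .AA20) {
                    cc <- as.integer(cnt_fg[[r]])
                    if (cc < min_occurrences) next
                    q <- as.integer(cnt_bg[[r]]) / n_bg
                    p <- binomialEnrichment(n_fg, cc, q)
                    if (p >= p_threshold) next
                    cand <- list(position = off, residue = r, p = p,
                                 count = cc)
                    if (is.null(best) ||
                        p < best$p ||
                        (p == best$p && (cc > best$count ||
                         (cc == best$count &&
                          (abs(off) < abs(best$position) ||
                           (abs(off) == abs(best$position) &&
                            r < best$residue))))))
                        best <- cand
                }
            }
            if (is.null(best)) break
            fg_mask <- cur_fg[, as.character(best$position)] == best$residue
            bg_mask <- cur_bg[, as.character(best$position)] == best$residue
            steps <- rbind(steps, data.frame(
                position = best$position, residue = best$residue,
                p_value = best$p,
                fg_before = n_fg, fg_after = sum(fg_mask),
                bg_before = n_bg, bg_after = sum(bg_mask)))
            cur_fg <- cur_fg[fg_mask, , drop = FALSE]
            cur_bg <- cur_bg[bg_mask, , drop = FALSE]
        }
        if (is.null(steps)) break
        fi <- foldIncrease(steps$position, steps$residue, fg, bg)
        ## matching windows leave the pool whether or not the motif is
        ## emitted, so the search always progresses
        pool_mask <- .matchMask(fg_pool, steps$position, steps$residue)
        fg_pool <- fg_pool[!pool_mask, , drop = FALSE]
        if (fi$fold_increase > min_fold_increase) {
            score <- sum(-log10(pmax(steps$p_value, .P_FLOOR)))
            motifs[[length(motifs) + 1L]] <- methods::new(
                "GlycoMotif",
                pattern = .renderPattern(k, fg@centerResidue,
                                         steps$position, steps$residue),
                steps = steps, motifScore = score,
                foldIncrease = fi$fold_increase,
                fgMatches = as.integer(fi$fg_matches),
                bgMatches = as.integer(fi$bg_matches),
                fgTotal = as.integer(fi$fg_total),
                bgTotal = as.integer(fi$bg_total))
        }
    }
    motifs
}

#' Merge motif patterns that differ at a single position
#'
#' Presentation-only pass over extracted motifs: patterns identical
#' except at one fixed position are rendered as one consensus with a
#' bracketed residue class at that position (the "[KR]" style);
#' per-motif statistics are untouched.
#'
#' @param motifs list of \linkS4class{GlycoMotif}.
#' @return character vector of merged consensus renderings.
#' @export
mergeMotifPatterns <- function(motifs) {
    pats <- vapply(motifs, motifPattern, character(1))
    if (length(pats) < 2L) return(pats)
    merged <- character(0)
    used <- rep(FALSE, length(pats))
    split1 <- strsplit(pats, "")
    for (i in seq_along(pats)) {
        if (used[i]) next
        group <- i
        diff_pos <- NA_integer_
        for (j in seq_along(pats)) {
            if (j == i || used[j]) next
            diffs <- which(split1[[i]] != split1[[j]])
            if (length(diffs) == 1L &&
                (is.na(diff_pos) || diffs == diff_pos)) {
                group <- c(group, j)
                diff_pos <- diffs
            }
        }
        if (length(group) == 1L) {
            merged <- c(merged, pats[i])
            used[i] <- TRUE
            next
        }
        chars <- split1[[i]]
        cls <- sort(unique(vapply(group,
                                  function(g) split1[[g]][diff_pos],
                                  character(1))))
        chars[diff_pos] <- paste0("[", paste(cls, collapse = ""), "]")
        merged <- c(merged, paste(chars, collapse = ""))
        used[group] <- TRUE
    }
    merged
}
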