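## Shared fixtures: tiny tables written on the fly.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

spot_block <- function(probe, foreground, background,
                       sample_id = "S1", block_id = "B1") {
    data.frame(sample_id = sample_id, block_id = block_id, probe = probe,
               replicate = seq_along(foreground), foreground = foreground,
               background = background, stringsAsFactors = FALSE)
}

## brute-force UPGMA from first principles: cluster distance is the mean
## over all original cross-pairs; ties to the lowest-index pair
upgma_oracle <- function(d) {
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    members <- list()
    while (length(clusters) > 1) {
        best <- NULL; best_d <- Inf
        for (a in seq_len(length(clusters) - 1)) {
            for (b in seq(a + 1, length(clusters))) {
                dd <- mean(d[clusters[[a]], clusters[[b]]])
                if (dd < best_d) { best_d <- dd; best <- c(a, b) }
            }
        }
        heights <- c(heights, best_d)
        members[[length(members) + 1]] <-
            sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, members = members)
}

## leaves under each merge of an hclust object
hclust_members <- function(h) {
    lapply(seq_len(nrow(h$merge)), function(k) {
        leaves <- function(x) {
            if (x < 0) return(-x)
            unlist(lapply(h$merge[x, ], leaves))
        }
        sort(leaves(k))
    })
}

## direct factorial-summation binomial upper tail
binom_tail_oracle <- function(n, c, q) {
    if (c == 0) return(1)
    sum(vapply(c:n, function(j)
        choose(n, j) * q^j * (1 - q)^(n - j), numeric(1)))
}

## pair-counting AUC: fraction of (pos, neg) pairs won, ties half
auc_oracle <- function(pos, neg) {
    s <- 0
    for (p in pos) for (q in neg)
        s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
}
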