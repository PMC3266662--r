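# independent brute-force oracles used across tests

# all permutations of 1..n (n small), as a list of integer vectors
allPermutations <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in allPermutations(n - 1))
        for (i in seq_len(n))
            out[[length(out) + 1]] <- append(p, n, after = i - 1)
    out
}

# exhaustive enumeration of simple paths on exactly k nodes; returns the
# maximum total node score (edges: data.frame gene1, gene2)
bestPathExhaustive <- function(genes, edges, scores, k) {
    adj <- lapply(genes, function(g)
        unique(c(edges$gene2[edges$gene1 == g],
                 edges$gene1[edges$gene2 == g])))
    names(adj) <- genes
    best <- -Inf
    recurse <- function(path, sc) {
        if (length(path) == k) {
            best <<- max(best, sc)
            return()
        }
        for (nb in adj[[path[length(path)]]])
            if (!nb %in% path) recurse(c(path, nb), sc + scores[nb])
    }
    for (g in genes) recurse(g, scores[g])
    best
}

# hypergeometric upper tail P(X >= x) by direct summation with choose()
hyperTail <- function(x, K, N, n) {
    ks <- x:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random connected-ish small graph for path tests
randomToyGraph <- function(n = 10, p_edge = 0.35, seed = 1) {
    set.seed(seed)
    genes <- sprintf("g%02d", seq_len(n))
    cmb <- t(combn(genes, 2))
    keep <- runif(nrow(cmb)) < p_edge
    # ensure a spanning path so the graph is connected
    edges <- rbind(data.frame(gene1 = genes[-n], gene2 = genes[-1],
                              stringsAsFactors = FALSE),
                   data.frame(gene1 = cmb[keep, 1], gene2 = cmb[keep, 2],
                              stringsAsFactors = FALSE))
    edges <- unique(edges)
    edges$weight <- 1
    list(genes = genes, edges = edges)
}

# tiny deterministic annotation: one or more scaffolds, unit-spaced genes
toyAnnotation <- function(r_by_scaffold, gene_len = 100, gap = 50) {
    rows <- list()
    for (s in seq_along(r_by_scaffold)) {
        n <- length(r_by_scaffold[[s]])
        start <- (seq_len(n) - 1) * (gene_len + gap) + 1
        rows[[s]] <- data.frame(
            gene_id = sprintf("t%dg%d", s, seq_len(n)),
            scaffold_id = sprintf("toy_%d", s),
            start = start, end = start + gene_len - 1,
            strand = rep_len(c("+", "-"), n),
            length = gene_len, gc = 50, taxonomy = "Fungi",
            categories = "CAT01", domains = "",
            scaffold_length = max(start) + gene_len + gap,
            stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    ann$dist_to_end <- pmin(ann$start - 1, ann$scaffold_length - ann$end)
    ann
}

toyCorrelations <- function(annotation, r)
    data.frame(gene_id = annotation$gene_id, r = r,
               stringsAsFactors = FALSE)
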