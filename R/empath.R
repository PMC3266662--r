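# Enriched molecular path detection on the gene-projection graph via the
# color-coding algorithm with weight-shuffling significance.

#' @useDynLib spprOmics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.graphIndex <- function(projection, node_scores, lambda) {
    genes <- names(node_scores)
    ed <- projection$edges
    keep <- ed$gene1 %in% genes & ed$gene2 %in% genes
    ed <- ed[keep, , drop = FALSE]
    escore <- if (lambda != 0) lambda * log(ed$weight)
              else rep(0, nrow(ed))
    list(genes = genes,
         efrom = match(ed$gene1, genes) - 1L,
         eto = match(ed$gene2, genes) - 1L,
         escore = escore)
}

#' Best-scoring simple path of fixed length
#'
#' Color-coding search: nodes are randomly colored with k colors and a
#' dynamic program over colorful paths finds the maximum-score simple path
#' on exactly k nodes; repeating the coloring \code{n_colorings} times makes
#' the miss probability at most \eqn{(1 - k!/k^k)^{n_{colorings}}}.
#'
#' @param projection gene graph from \code{\link{geneProjection}}.
#' @param node_scores named per-gene additive scores (higher = better).
#' @param k path length in genes.
#' @param n_colorings number of random colorings.
#' @param seed integer seed.
#' @param lambda weight of the edge term \eqn{\lambda \sum \ln w_e}
#'   (default 0: node scores only).
#' @return list with \code{score} and \code{path} (gene ids; empty when the
#'   graph has no k-node path).
#' @export
bestScoringPath <- function(projection, node_scores, k, n_colorings = 300,
                            seed = 1, lambda = 0) {
    if (k < 2) stop("k must be at least 2")
    gi <- .graphIndex(projection, node_scores, lambda)
    set.seed(seed)
    res <- .colorCodingSearch(length(gi$genes), gi$efrom, gi$eto,
                              as.numeric(node_scores), gi$escore,
                              as.integer(k), as.integer(n_colorings))
    res$path <- gi$genes[res$path + 1L]
    res
}

#' Enriched molecular path detection (EMPath)
#'
#' For each path length k the maximum-score simple path in the gene
#' projection of the metabolic network is found by color coding; the path
#' score is \eqn{\sum_{nodes} \Phi^{-1}(1-p)} (optionally plus
#' \eqn{\lambda \sum_{edges} \ln w}).  Significance comes from shuffling the
#' node weights over nodes (and edge weights over edges when
#' \eqn{\lambda \neq 0}) and recording the best score of each shuffled
#' replicate; the empirical p-value uses the add-one estimator.  Significant
#' paths whose gene sets overlap are merged by union into the final reported
#' paths.
#'
#' @param projection gene graph from \code{\link{geneProjection}}.
#' @param pvals named one-sided per-gene correlation p-values in (0,1];
#'   genes absent from \code{pvals} are dropped from the graph.
#' @param k_min,k_max path-length range (default 3 to 12; truncated to the
#'   node count).
#' @param n_shuffle weight shuffles per path length (default 10000).
#' @param n_colorings colorings per search; default
#'   \eqn{\lceil \ln(1/\delta) e^k \rceil}.
#' @param delta color-coding miss probability used for the default
#'   \code{n_colorings}.
#' @param seed integer seed.
#' @param p_cut significance cut-off on the empirical p (default 0.025).
#' @param lambda edge-term weight (default 0).
#' @return list with \code{candidates} (data.frame: one row per k with
#'   \code{score}, \code{p}, \code{significant} and ';'-joined \code{genes})
#'   and \code{merged} (list of gene-id vectors, unions of overlapping
#'   significant paths).
#' @export
empath <- function(projection, pvals, k_min = 3, k_max = 12,
                   n_shuffle = 10000, n_colorings = NULL, delta = 0.05,
                   seed = 1, p_cut = 0.025, lambda = 0) {
    if (k_min < 2) stop("k_min must be at least 2")
    genes <- intersect(projection$genes, names(pvals))
    if (!length(genes)) stop("no graph gene has a p-value")
    scores <- stats::qnorm(1 - .clampP(pvals[genes]))
    gi <- .graphIndex(projection, scores, lambda)
    k_max <- min(k_max, length(genes))
    rows <- list()
    for (k in seq(k_min, k_max)) {
        nc <- if (is.null(n_colorings))
            as.integer(ceiling(log(1 / delta) * exp(k))) else n_colorings
        set.seed(seed + k)
        obs <- .colorCodingSearch(length(genes), gi$efrom, gi$eto,
                                  as.numeric(scores), gi$escore,
                                  as.integer(k), nc)
        if (!is.finite(obs$score)) next
        null <- .colorCodingNull(length(genes), gi$efrom, gi$eto,
                                 as.numeric(scores), gi$escore,
                                 lambda != 0, as.integer(k), nc,
                                 as.integer(n_shuffle))
        p <- (1 + sum(null >= obs$score - 1e-12)) / (1 + n_shuffle)
        rows[[length(rows) + 1]] <- data.frame(
            k = k, score = obs$score, p = p, significant = p < p_cut,
            genes = paste(genes[obs$path + 1L], collapse = ";"),
            stringsAsFactors = FALSE)
    }
    cand <- if (length(rows)) do.call(rbind, rows)
        else data.frame(k = integer(0), score = numeric(0), p = numeric(0),
                        significant = logical(0), genes = character(0))
    rownames(cand) <- NULL
    sig <- lapply(cand$genes[cand$significant],
                  function(g) strsplit(g, ";", fixed = TRUE)[[1]])
    merged <- list()
    for (gs in sig) {
        hit <- which(vapply(merged, function(m) length(intersect(m, gs)) > 0,
                            logical(1)))
        if (length(hit)) {
            merged[[hit[1]]] <- union(Reduce(union, merged[hit]), gs)
            merged[setdiff(hit, hit[1])] <- NULL
        } else merged[[length(merged) + 1]] <- gs
    }
    list(candidates = cand, merged = merged)
}
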