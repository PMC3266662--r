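# Metabolic-network analyses: cross-species model transfer by bidirectional
# best hits, reporter-metabolite scoring, and the gene-projection graph used
# by the enriched-path search.

#' Transfer a metabolic network by bidirectional best hits
#'
#' Maps target-species genes to source-species genes by bidirectional best
#' blastp hits: a pair is accepted when each gene is the other's unique best
#' hit and the bit score exceeds the cut-off in either direction (the strict
#' variant requires both directions).  Reactions of the mapped source gene
#' are copied to the target gene, producing the target-species bipartite
#' network.  Ties for a best hit skip the gene with a warning.
#'
#' @param scores data.frame of pairwise scores with columns \code{query},
#'   \code{subject}, \code{bitscore}; both search directions must be listed.
#' @param reactions source-species network: data.frame with columns
#'   \code{gene}, \code{metabolite} and optionally \code{reaction}.
#' @param cutoff bit-score cut-off (default 50, exclusive).
#' @param both_directions require the cut-off in both directions.
#' @return list with \code{mapping} (data.frame \code{target}, \code{source},
#'   \code{score_fwd}, \code{score_rev}) and \code{network}, a
#'   \linkS4class{MetabolicNetwork} on target genes whose per-gene
#'   \code{confidence} is the product of the two directional bit scores
#'   rescaled by its maximum to (0,1].
#' @export
bbhTransfer <- function(scores, reactions, cutoff = 50,
                        both_directions = FALSE) {
    sc <- as.data.frame(scores)
    srcGenes <- unique(reactions$gene)
    bestHit <- function(tab) {
        out <- list()
        for (q in unique(tab$query)) {
            rows <- tab[tab$query == q, , drop = FALSE]
            mx <- max(rows$bitscore)
            top <- rows$subject[rows$bitscore == mx]
            if (length(top) > 1) {
                warning("tie for best hit of ", q, "; skipped")
                next
            }
            out[[q]] <- c(subject = top, score = mx)
        }
        out
    }
    fwd <- bestHit(sc[!sc$query %in% srcGenes, , drop = FALSE])  # target->src
    rev <- bestHit(sc[sc$query %in% srcGenes, , drop = FALSE])   # src->target
    map <- list()
    for (tg in names(fwd)) {
        sg <- fwd[[tg]][["subject"]]
        if (!sg %in% names(rev)) next
        if (rev[[sg]][["subject"]] != tg) next
        s1 <- as.numeric(fwd[[tg]][["score"]])
        s2 <- as.numeric(rev[[sg]][["score"]])
        ok <- if (both_directions) (s1 > cutoff && s2 > cutoff)
              else (s1 > cutoff || s2 > cutoff)
        if (!ok) next
        map[[length(map) + 1]] <- data.frame(target = tg, source = sg,
                                             score_fwd = s1, score_rev = s2,
                                             stringsAsFactors = FALSE)
    }
    mapping <- if (length(map)) do.call(rbind, map)
        else data.frame(target = character(0), source = character(0),
                        score_fwd = numeric(0), score_rev = numeric(0))
    rownames(mapping) <- NULL
    edges <- merge(mapping[, c("target", "source")], reactions,
                   by.x = "source", by.y = "gene")
    edges <- data.frame(gene = edges$target, metabolite = edges$metabolite,
                        stringsAsFactors = FALSE)
    conf <- numeric(0)
    if (nrow(mapping)) {
        prod <- mapping$score_fwd * mapping$score_rev
        conf <- prod / max(prod)
        names(conf) <- mapping$target
    }
    net <- MetabolicNetwork(edges, confidence = conf)
    list(mapping = mapping, network = net)
}

#' Reporter metabolites
#'
#' Scores each metabolite by the collective significance of its neighbouring
#' enzyme-coding genes: \deqn{Z_{raw} = \sum_{i \in N(m)}
#' \Phi^{-1}(1-p_i)/\sqrt{k}} where the sum runs over the k adjacent genes
#' with a p-value.  The score is background-corrected by the mean and SD of
#' the same statistic over random size-k gene draws,
#' \eqn{Z_{corr} = (Z_{raw}-\mu_k)/\sigma_k}, and
#' \eqn{p = 1 - \Phi(Z_{corr})}.  Run once per correlation tail with
#' one-sided p-values (H1: r > 0 and H1: r < 0).
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param pvals named per-gene p-values in (0,1]; defaults to the network's
#'   \code{geneWeights}.  Genes without a p-value do not count as
#'   neighbours.
#' @param n_background random draws per neighbourhood size (default 1000).
#' @param seed integer seed for the background draws.
#' @param filter keep only metabolites with \code{p < p_cut} and more than
#'   one adjacent gene.
#' @param p_cut significance cut-off applied when filtering (default 0.05).
#' @return data.frame with columns \code{metabolite}, \code{k},
#'   \code{Z_raw}, \code{Z_corrected}, \code{p}, sorted by p.
#' @export
reporterMetabolites <- function(network, pvals = geneWeights(network),
                                n_background = 1000, seed = 1,
                                filter = TRUE, p_cut = 0.05) {
    if (!length(pvals)) stop("no gene p-values supplied")
    edges <- networkEdges(network)
    edges <- edges[edges$gene %in% names(pvals), , drop = FALSE]
    if (!nrow(edges)) stop("no network gene has a p-value")
    z <- stats::qnorm(1 - .clampP(pvals))
    nb <- split(edges$gene, edges$metabolite)
    nb <- lapply(nb, unique)
    k <- lengths(nb)
    zraw <- vapply(nb, function(g) sum(z[g]), numeric(1)) / sqrt(k)
    set.seed(seed)
    zpool <- z[unique(edges$gene)]
    mu <- sd <- numeric(length(k))
    for (kk in unique(k)) {
        draws <- vapply(seq_len(n_background), function(i)
            sum(zpool[sample.int(length(zpool), kk)]) / sqrt(kk), numeric(1))
        mu[k == kk] <- mean(draws)
        sd[k == kk] <- stats::sd(draws)
    }
    # degenerate backgrounds (all pool z equal) have zero spread; the
    # centred score is then 0 by convention
    zc <- ifelse(sd > 0, (zraw - mu) / sd, 0)
    out <- data.frame(metabolite = names(nb), k = as.integer(k),
                      Z_raw = unname(zraw), Z_corrected = unname(zc),
                      p = 1 - stats::pnorm(zc),
                      stringsAsFactors = FALSE, row.names = NULL)
    if (filter) out <- out[out$p < p_cut & out$k > 1, , drop = FALSE]
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Project the bipartite network onto genes
#'
#' Two genes are connected when their enzymes share at least one metabolite.
#' Edge weights are the product of the two genes' homology-confidence
#' scores (themselves products of bidirectional best-hit bit scores),
#' rescaled by the maximum so weights lie in (0,1]; genes without a
#' confidence score default to 1.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @return list with \code{genes} (node ids) and \code{edges} (data.frame
#'   \code{gene1}, \code{gene2}, \code{weight}).
#' @export
geneProjection <- function(network) {
    edges <- networkEdges(network)
    genes <- unique(edges$gene)
    conf <- rep(1, length(genes)); names(conf) <- genes
    cf <- network@confidence
    conf[names(cf)[names(cf) %in% genes]] <-
        cf[names(cf) %in% genes]
    pairs <- list()
    for (gset in split(edges$gene, edges$metabolite)) {
        gset <- unique(gset)
        if (length(gset) < 2) next
        cmb <- utils::combn(sort(gset), 2)
        pairs[[length(pairs) + 1]] <- data.frame(gene1 = cmb[1, ],
                                                 gene2 = cmb[2, ],
                                                 stringsAsFactors = FALSE)
    }
    if (!length(pairs))
        return(list(genes = genes,
                    edges = data.frame(gene1 = character(0),
                                       gene2 = character(0),
                                       weight = numeric(0))))
    ed <- unique(do.call(rbind, pairs))
    w <- conf[ed$gene1] * conf[ed$gene2]
    ed$weight <- unname(w / max(w))
    rownames(ed) <- NULL
    list(genes = genes, edges = ed)
}
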