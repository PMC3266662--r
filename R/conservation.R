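# Conservation of chromosomal clusters in other genomes: sliding windows of
# consecutive genes, InterPro domain-content matching, orthology check.

#' Sliding windows of consecutive genes along a genome
#'
#' @param order data.frame describing one genome's gene order: columns
#'   \code{species_id}, \code{scaffold_id}, \code{rank} (1-based position of
#'   the gene on its scaffold), \code{gene_id}, \code{domains}
#'   (';'-separated InterPro ids, may be empty) and \code{orthogroup}.
#' @param w window size in genes (the analysis uses 16 or 30).
#' @param step window increment (2 for w=16, 5 for w=30 by default pairing;
#'   default \code{NULL} picks the pairing from \code{w}).
#' @return list of windows, each a list with \code{species_id},
#'   \code{scaffold_id}, \code{genes}, \code{domains} (unique ids in the
#'   window).  Scaffolds shorter than \code{w} yield no windows.
#' @export
enumerateWindows <- function(order, w = 16, step = NULL) {
    if (is.null(step)) step <- if (w == 30) 5L else 2L
    if (w <= 0 || step <= 0) stop("w and step must be positive")
    out <- list()
    for (sc in split(order, order$scaffold_id)) {
        sc <- sc[order(sc$rank), , drop = FALSE]
        n <- nrow(sc)
        if (n < w) next
        starts <- seq(1L, n - w + 1L, by = step)
        doms <- .splitMulti(sc$domains)
        for (s in starts) {
            idx <- s:(s + w - 1L)
            out[[length(out) + 1]] <- list(
                species_id = sc$species_id[1],
                scaffold_id = sc$scaffold_id[1],
                start_rank = sc$rank[s],
                genes = sc$gene_id[idx],
                domains = unique(unlist(doms[idx])))
        }
    }
    out
}

#' Match a cluster's domain content against genome windows
#'
#' A window matches when it carries at least \code{min_shared} of the
#' cluster's distinct InterPro domains (set semantics: duplicate domains
#' count once).  The default, strictest criterion requires every cluster
#' domain; relax \code{min_shared} to allow partial conservation.
#'
#' @param cluster_domains character vector of the query cluster's InterPro
#'   ids.
#' @param windows list from \code{\link{enumerateWindows}}.
#' @param min_shared minimum number of distinct shared domains (default: all
#'   cluster domains).
#' @return data.frame of matches sorted by decreasing shared count, with a
#'   list-column \code{shared} and \code{window} index into \code{windows}.
#' @export
matchCluster <- function(cluster_domains, windows, min_shared = NULL) {
    cd <- unique(cluster_domains)
    if (!length(cd)) stop("cluster domain set is empty")
    if (is.null(min_shared)) min_shared <- length(cd)
    if (min_shared > length(cd))
        stop("min_shared exceeds the number of cluster domains")
    hits <- lapply(seq_along(windows), function(i) {
        sh <- intersect(windows[[i]]$domains, cd)
        if (length(sh) < min_shared) return(NULL)
        data.frame(window = i, species_id = windows[[i]]$species_id,
                   scaffold_id = windows[[i]]$scaffold_id,
                   n_shared = length(sh),
                   shared = I(list(sh)),
                   homology_confirmed = NA,
                   stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
        return(data.frame(window = integer(0), species_id = character(0),
                          scaffold_id = character(0), n_shared = integer(0),
                          shared = I(list()), homology_confirmed = logical(0)))
    hits <- hits[order(-hits$n_shared), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Verify homology of domain-matched windows
#'
#' A domain match can arise from an unrelated protein family carrying the
#' same domain; a match is confirmed only when every shared domain is
#' carried by a window gene that shares a protein-cluster (orthology group)
#' with some query-cluster gene.
#'
#' @param matches data.frame from \code{\link{matchCluster}}.
#' @param windows the window list the matches refer to.
#' @param cluster_genes gene ids of the query cluster.
#' @param orthogroups named character vector: gene id -> orthology group id,
#'   covering both genomes (missing entries leave a match unconfirmed, with
#'   a warning).
#' @param gene_domains named list: gene id -> character vector of its
#'   InterPro ids (window genes).
#' @return \code{matches} with \code{homology_confirmed} filled in.
#' @export
verifyHomology <- function(matches, windows, cluster_genes, orthogroups,
                           gene_domains) {
    qGroups <- orthogroups[cluster_genes]
    if (any(is.na(qGroups)))
        warning("query cluster gene(s) lack an orthology group")
    qGroups <- qGroups[!is.na(qGroups)]
    matches$homology_confirmed <- vapply(seq_len(nrow(matches)),
                                         function(i) {
        wgenes <- windows[[matches$window[i]]]$genes
        wog <- orthogroups[wgenes]
        if (any(is.na(wog))) {
            warning("window gene(s) lack an orthology group; ",
                    "match left unconfirmed")
            return(FALSE)
        }
        all(vapply(matches$shared[[i]], function(dom) {
            carriers <- wgenes[vapply(wgenes, function(g)
                dom %in% gene_domains[[g]], logical(1))]
            any(orthogroups[carriers] %in% qGroups)
        }, logical(1)))
    }, logical(1))
    matches
}
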