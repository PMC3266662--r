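# Chromosomal organisation of SPPR-correlated genes: adjacent qualifying
# pairs, permutation support, cluster detection and gene characteristics.

.corLookup <- function(annotation, correlations) {
    miss <- setdiff(correlations$gene_id, annotation$gene_id)
    if (length(miss))
        stop("correlation table contains gene(s) absent from annotation: ",
             paste(utils::head(miss, 5), collapse = ", "))
    r <- correlations$r[match(annotation$gene_id, correlations$gene_id)]
    r
}

#' Adjacent gene pairs co-correlated with SPPR
#'
#' Scans each scaffold for pairs of chromosomally consecutive genes whose
#' expression both exceed an absolute correlation cut-off to SPPR with the
#' same sign of correlation.  Adjacency never crosses scaffold boundaries.
#'
#' @param annotation flat annotation data.frame (see
#'   \code{\link{annotationToGRanges}}).
#' @param correlations data.frame with \code{gene_id} and \code{r} (from
#'   \code{\link{correlateToSppr}}).
#' @param r_cut absolute correlation cut-off (default 0.7).
#' @return data.frame with columns \code{scaffold_id}, \code{gene1},
#'   \code{gene2}, \code{r1}, \code{r2}, \code{sign}.
#' @export
adjacentQualifyingPairs <- function(annotation, correlations, r_cut = 0.7) {
    r <- .corLookup(annotation, correlations)
    ann <- annotation
    ann$r <- r
    out <- lapply(.scaffoldOrder(ann), function(sc) {
        if (nrow(sc) < 2) return(NULL)
        i <- seq_len(nrow(sc) - 1)
        q1 <- !is.na(sc$r[i]) & abs(sc$r[i]) > r_cut
        q2 <- !is.na(sc$r[i + 1]) & abs(sc$r[i + 1]) > r_cut
        same <- sign(sc$r[i]) == sign(sc$r[i + 1])
        keep <- which(q1 & q2 & same)
        if (!length(keep)) return(NULL)
        data.frame(scaffold_id = sc$scaffold_id[keep],
                   gene1 = sc$gene_id[keep], gene2 = sc$gene_id[keep + 1],
                   r1 = sc$r[keep], r2 = sc$r[keep + 1],
                   sign = ifelse(sc$r[keep] > 0, "+", "-"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(scaffold_id = character(0), gene1 = character(0),
                          gene2 = character(0), r1 = numeric(0),
                          r2 = numeric(0), sign = character(0))
    rownames(out) <- NULL
    out
}

# count of genes (or pairs) in >=1 qualifying adjacent pair, per sign,
# for a given assignment of r values to chromosomal positions
.pairStatistic <- function(scaffold_index, r, r_cut, statistic) {
    stat <- c(pos = 0, neg = 0)
    n <- length(r)
    i <- which(scaffold_index[-n] == scaffold_index[-1])
    q <- !is.na(r) & abs(r) > r_cut
    pairOk <- q[i] & q[i + 1] & sign(r[i]) == sign(r[i + 1])
    posPair <- pairOk & r[i] > 0
    negPair <- pairOk & r[i] < 0
    if (statistic == "pairs") {
        c(pos = sum(posPair), neg = sum(negPair))
    } else {
        c(pos = length(unique(c(i[posPair], i[posPair] + 1))),
          neg = length(unique(c(i[negPair], i[negPair] + 1))))
    }
}

#' Permutation test for adjacent co-correlated gene pairs
#'
#' Tests whether more genes belong to adjacent same-sign correlated pairs
#' than expected if correlation values were placed on the chromosome at
#' random.  Gene positions stay fixed and the correlation values are
#' shuffled over positions (scaffold gene counts are thereby preserved);
#' adjacency is evaluated within scaffolds only.  The empirical p-value uses
#' the add-one estimator \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + n_{perm})}
#' so that p is never zero.
#'
#' @inheritParams adjacentQualifyingPairs
#' @param n_perm number of permutations (the full analysis uses 1e4-1e5).
#' @param seed integer seed.
#' @param statistic \code{"genes"} (default; number of genes in at least one
#'   qualifying pair) or \code{"pairs"} (number of qualifying pairs).
#' @return data.frame with one row per sign: observed statistic and
#'   empirical p.
#' @export
pairPermutationTest <- function(annotation, correlations, r_cut = 0.7,
                                n_perm = 10000, seed = 1,
                                statistic = c("genes", "pairs")) {
    statistic <- match.arg(statistic)
    if (n_perm < 1) stop("n_perm must be at least 1")
    r <- .corLookup(annotation, correlations)
    ann <- annotation[order(annotation$scaffold_id, annotation$start), ]
    r <- r[order(annotation$scaffold_id, annotation$start)]
    scf <- ann$scaffold_id
    obs <- .pairStatistic(scf, r, r_cut, statistic)
    set.seed(seed)
    exceed <- c(pos = 0, neg = 0)
    for (b in seq_len(n_perm)) {
        stat <- .pairStatistic(scf, sample(r), r_cut, statistic)
        exceed <- exceed + (stat >= obs)
    }
    data.frame(sign = c("+", "-"), observed = as.integer(obs),
               p = (1 + exceed) / (1 + n_perm),
               n_perm = n_perm, row.names = NULL)
}

#' Detect chromosomal clusters of SPPR-correlated genes
#'
#' A cluster is seeded by three chromosomally consecutive genes, all with
#' absolute correlation above \code{r_cut} and the same sign, and extended
#' over flanking genes as long as the direction (sign) of their correlation
#' matches the cluster sign; by default extension imposes no magnitude
#' requirement (set \code{extend_r_cut} to require one).  Genes with missing
#' or exactly zero correlation terminate extension and never seed.
#'
#' @inheritParams adjacentQualifyingPairs
#' @param extend_r_cut minimum absolute correlation required of extension
#'   genes (default 0: sign match only).
#' @return data.frame, one row per cluster: \code{scaffold_id}, \code{sign},
#'   \code{start}, \code{end}, \code{n_genes}, \code{genes} and
#'   \code{seed_triplet} (';'-separated, in chromosomal order).
#' @export
detectClusters <- function(annotation, correlations, r_cut = 0.7,
                           extend_r_cut = 0) {
    r <- .corLookup(annotation, correlations)
    ann <- annotation
    ann$r <- r
    res <- list()
    for (sc in .scaffoldOrder(ann)) {
        n <- nrow(sc)
        if (n < 3) next
        s <- ifelse(is.na(sc$r) | sc$r == 0, 0, sign(sc$r))
        qual <- !is.na(sc$r) & abs(sc$r) > r_cut
        for (sg in c(1, -1)) {
            ext <- s == sg & abs(ifelse(is.na(sc$r), 0, sc$r)) > extend_r_cut
            rl <- rle(ext)
            endpos <- cumsum(rl$lengths)
            startpos <- endpos - rl$lengths + 1
            for (k in which(rl$values & rl$lengths >= 3)) {
                idx <- startpos[k]:endpos[k]
                qi <- qual[idx]
                trip <- which(qi & c(qi[-1], FALSE) & c(qi[-(1:2)], FALSE,
                                                        FALSE))
                if (!length(trip)) next
                seedIdx <- idx[trip[1] + 0:2]
                res[[length(res) + 1]] <- data.frame(
                    scaffold_id = sc$scaffold_id[1],
                    sign = if (sg > 0) "+" else "-",
                    start = min(sc$start[idx]), end = max(sc$end[idx]),
                    n_genes = length(idx),
                    genes = paste(sc$gene_id[idx], collapse = ";"),
                    seed_triplet = paste(sc$gene_id[seedIdx],
                                         collapse = ";"),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(res))
        return(data.frame(scaffold_id = character(0), sign = character(0),
                          start = integer(0), end = integer(0),
                          n_genes = integer(0), genes = character(0),
                          seed_triplet = character(0)))
    out <- do.call(rbind, res)
    out <- out[order(out$scaffold_id, out$start, out$sign), ]
    rownames(out) <- NULL
    out
}

#' Promoter-sharing potential of adjacent correlated pairs
#'
#' An adjacent pair can share a promoter when transcription is divergent:
#' the upstream (lower-coordinate) gene on the minus strand and the
#' downstream gene on the plus strand, so both transcription starts face the
#' intergenic region.  The separation is the distance between the two
#' annotated transcription start positions (for a minus-strand gene the end
#' coordinate).
#'
#' @param pairs data.frame from \code{\link{adjacentQualifyingPairs}}.
#' @param annotation flat annotation data.frame with strand.
#' @param max_gap separation threshold in bases (default 1000).
#' @return list with \code{divergent} (count), \code{within_gap} (count with
#'   separation < \code{max_gap}) and \code{detail} data.frame.
#' @export
promoterSharing <- function(pairs, annotation, max_gap = 1000) {
    idx1 <- match(pairs$gene1, annotation$gene_id)
    idx2 <- match(pairs$gene2, annotation$gene_id)
    if (any(is.na(idx1)) || any(is.na(idx2)))
        stop("pair gene missing from annotation")
    st1 <- annotation$strand[idx1]; st2 <- annotation$strand[idx2]
    if (any(!st1 %in% c("+", "-")) || any(!st2 %in% c("+", "-")))
        stop("missing strand in annotation")
    divergent <- st1 == "-" & st2 == "+"
    tss1 <- ifelse(st1 == "-", annotation$end[idx1], annotation$start[idx1])
    tss2 <- ifelse(st2 == "-", annotation$end[idx2], annotation$start[idx2])
    sep <- abs(tss2 - tss1)
    detail <- data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                         divergent = divergent, separation = sep,
                         stringsAsFactors = FALSE)
    list(divergent = sum(divergent),
         within_gap = sum(divergent & sep < max_gap),
         detail = detail)
}

#' General per-gene characteristics
#'
#' Tabulates, for every annotated gene with expression data, the maximum
#' log2 expression over all samples, the maximum absolute log2 fold change
#' over all pairwise condition contrasts, GC%, distance to the scaffold end
#' and gene length.
#'
#' @param annotation flat annotation data.frame (needs \code{gc},
#'   \code{dist_to_end}, \code{length}).
#' @param expr log2 expression matrix.
#' @param condition per-sample condition labels.
#' @return data.frame with columns \code{gene_id}, \code{max_expr},
#'   \code{max_abs_log2FC}, \code{gc}, \code{dist_to_end}, \code{length}.
#'   Genes without expression are dropped with a warning.
#' @export
geneCharacteristics <- function(annotation, expr, condition) {
    keep <- annotation$gene_id %in% rownames(expr)
    if (!all(keep))
        warning(sum(!keep), " gene(s) without expression excluded")
    ann <- annotation[keep, , drop = FALSE]
    if ("scaffold_length" %in% colnames(ann))
        ann$dist_to_end <- pmin(ann$start - 1,
                                ann$scaffold_length - ann$end)
    m <- expr[ann$gene_id, , drop = FALSE]
    lev <- unique(condition)
    means <- vapply(lev, function(cc)
        rowMeans(m[, condition == cc, drop = FALSE]), numeric(nrow(m)))
    ctr <- utils::combn(seq_along(lev), 2)
    mfc <- apply(abs(means[, ctr[1, ], drop = FALSE] -
                     means[, ctr[2, ], drop = FALSE]), 1, max)
    data.frame(gene_id = ann$gene_id,
               max_expr = apply(m, 1, max),
               max_abs_log2FC = mfc,
               gc = ann$gc, dist_to_end = ann$dist_to_end,
               length = ann$length, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Compare a gene characteristic between two gene sets
#'
#' Ordinary linear model of the characteristic on a two-level group
#' indicator; reports the coefficient (mean of set A minus mean of set B)
#' and its two-sided p-value.
#'
#' @param table data.frame from \code{\link{geneCharacteristics}}.
#' @param setA,setB disjoint gene-id vectors.
#' @param characteristic column of \code{table} to compare.
#' @return list with \code{estimate} and \code{p.value}.
#' @export
compareCharacteristics <- function(table, setA, setB, characteristic) {
    if (length(intersect(setA, setB)))
        stop("gene sets overlap")
    if (!length(setA) || !length(setB)) stop("empty gene set")
    if (!characteristic %in% colnames(table))
        stop("unknown characteristic: ", characteristic)
    sel <- table$gene_id %in% c(setA, setB)
    df <- data.frame(y = table[[characteristic]][sel],
                     g = factor(ifelse(table$gene_id[sel] %in% setA,
                                       "A", "B"), levels = c("B", "A")))
    if (nrow(df) < 3) stop("too few genes for a linear model")
    fit <- stats::lm(y ~ g, data = df)
    co <- summary(fit)$coefficients
    list(estimate = unname(co["gA", "Estimate"]),
         p.value = unname(co["gA", "Pr(>|t|)"]))
}
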