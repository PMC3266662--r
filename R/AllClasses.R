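#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomeInfoDb seqlengths seqnames seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges rowData
NULL

#' Chemostat expression experiment
#'
#' An extension of \linkS4class{RangedSummarizedExperiment} holding a log2
#' expression matrix (genes x samples) together with per-sample chemostat
#' physiology.  The \code{colData} must carry a \code{condition} factor (the
#' cultivation condition, e.g. D03/D06/HD) and a numeric \code{sppr} column,
#' the specific extracellular protein production rate in
#' mg protein / g biomass / h.  Gene annotation (coordinates, strand, GC%,
#' taxonomic specificity, functional categories, InterPro domains) lives in
#' \code{rowRanges}.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}
#' @export
setClass("SpprExperiment", contains = "RangedSummarizedExperiment")

setValidity("SpprExperiment", function(object) {
    msg <- NULL
    if (!("log2" %in% names(SummarizedExperiment::assays(object))))
        msg <- c(msg, "assay 'log2' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("condition", "sppr") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'condition' and 'sppr'")
    else {
        if (!is.numeric(cd$sppr))
            msg <- c(msg, "'sppr' must be numeric")
        else if (any(!is.finite(cd$sppr)) || any(cd$sppr < 0))
            msg <- c(msg, "'sppr' must be finite and non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpprExperiment
#'
#' @param expr numeric matrix of log2 expression values, genes in rows,
#'   samples in columns; rownames are gene ids, colnames sample ids.
#' @param annotation gene annotation as returned by
#'   \code{\link{simulateGenome}} or \code{\link{readAnnotation}}: a
#'   data.frame with columns \code{gene_id}, \code{scaffold_id}, \code{start},
#'   \code{end}, \code{strand}, \code{gc}, \code{taxonomy},
#'   \code{scaffold_length} and optionally \code{categories}/\code{domains}
#'   (';'-separated), or a \code{GRanges} with those mcols.  May be
#'   \code{NULL} when no genomic analysis is intended.
#' @param condition character or factor of per-sample conditions.
#' @param sppr numeric per-sample SPPR values (mg/g/h).
#' @return A \code{SpprExperiment}.
#' @examples
#' sim <- simulateExperiment(syntheticSpec(seed = 1))
#' sim$experiment
#' @export
SpprExperiment <- function(expr, annotation = NULL, condition, sppr) {
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)))
        stop("expression matrix must have gene ids as rownames")
    if (length(condition) != ncol(expr) || length(sppr) != ncol(expr))
        stop("'condition' and 'sppr' must have one entry per sample")
    cd <- S4Vectors::DataFrame(condition = factor(condition), sppr = sppr,
                               row.names = colnames(expr))
    if (is.null(annotation)) {
        rr <- GenomicRanges::GRanges(rep("unplaced", nrow(expr)),
                                     IRanges::IRanges(seq_len(nrow(expr)),
                                                      width = 1L))
        names(rr) <- rownames(expr)
    } else {
        rr <- annotationToGRanges(annotation)
        missing <- setdiff(rownames(expr), names(rr))
        if (length(missing))
            stop("genes absent from annotation: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        rr <- rr[rownames(expr)]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = expr), rowRanges = rr, colData = cd)
    new("SpprExperiment", se)
}

#' @describeIn SpprExperiment per-sample SPPR values
#' @param object a \code{SpprExperiment}
#' @export
setGeneric("sppr", function(object) standardGeneric("sppr"))

#' @rdname SpprExperiment
#' @export
setMethod("sppr", "SpprExperiment",
          function(object) {
              v <- SummarizedExperiment::colData(object)$sppr
              names(v) <- colnames(object)
              v
          })

#' @describeIn SpprExperiment per-sample condition factor
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname SpprExperiment
#' @export
setMethod("conditions", "SpprExperiment",
          function(object) {
              v <- SummarizedExperiment::colData(object)$condition
              names(v) <- colnames(object)
              v
          })

#' @describeIn SpprExperiment the log2 expression matrix
#' @export
setGeneric("log2Expr", function(object) standardGeneric("log2Expr"))

#' @rdname SpprExperiment
#' @export
setMethod("log2Expr", "SpprExperiment",
          function(object) SummarizedExperiment::assay(object, "log2"))

#' @describeIn SpprExperiment gene annotation as a flat data.frame
#' @export
setGeneric("geneAnnotation", function(object) standardGeneric("geneAnnotation"))

#' @rdname SpprExperiment
#' @export
setMethod("geneAnnotation", "SpprExperiment",
          function(object) grangesToAnnotation(
              SummarizedExperiment::rowRanges(object)))

setMethod("show", "SpprExperiment", function(object) {
    callNextMethod()
    cond <- table(SummarizedExperiment::colData(object)$condition)
    cat("conditions:", paste(names(cond), cond, sep = "=", collapse = " "),
        "\n")
    cat("sppr range:",
        paste(signif(range(SummarizedExperiment::colData(object)$sppr), 3),
              collapse = " - "), "mg/g/h\n")
})

#' Bipartite metabolic network
#'
#' Genes (enzyme-coding) and metabolites form a bipartite graph: a gene is
#' linked to every metabolite its enzyme consumes or produces.  Gene nodes can
#' carry weights (correlation p-values used by the reporter-metabolite and
#' path searches) and a per-gene homology confidence score in (0,1] derived
#' from the bidirectional best-hit bit scores used to transfer the network.
#'
#' @slot edges data.frame with columns \code{gene}, \code{metabolite} and
#'   optionally \code{reaction}.
#' @slot geneWeights named numeric, p-values in (0,1] per gene (may be empty).
#' @slot confidence named numeric in (0,1] per gene (may be empty).
#' @export
setClass("MetabolicNetwork",
         representation(edges = "data.frame",
                        geneWeights = "numeric",
                        confidence = "numeric"))

setValidity("MetabolicNetwork", function(object) {
    msg <- NULL
    e <- object@edges
    if (!all(c("gene", "metabolite") %in% colnames(e)))
        msg <- c(msg, "edges need 'gene' and 'metabolite' columns")
    else if (any(e$gene %in% e$metabolite))
        msg <- c(msg, "gene and metabolite node id sets must be disjoint")
    w <- object@geneWeights
    if (length(w) && (is.null(names(w)) || any(w <= 0) || any(w > 1)))
        msg <- c(msg, "geneWeights must be named p-values in (0,1]")
    cf <- object@confidence
    if (length(cf) && (is.null(names(cf)) || any(cf <= 0) || any(cf > 1)))
        msg <- c(msg, "confidence must be named scores in (0,1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MetabolicNetwork
#'
#' @param edges data.frame with columns \code{gene} and \code{metabolite}
#'   (optionally \code{reaction}).
#' @param geneWeights named numeric p-values in (0,1] (optional).
#' @param confidence named numeric per-gene homology confidence in (0,1]
#'   (optional).
#' @return A \code{MetabolicNetwork}.
#' @export
MetabolicNetwork <- function(edges, geneWeights = numeric(0),
                             confidence = numeric(0)) {
    edges$gene <- as.character(edges$gene)
    edges$metabolite <- as.character(edges$metabolite)
    edges <- unique(edges)
    new("MetabolicNetwork", edges = as.data.frame(edges),
        geneWeights = geneWeights, confidence = confidence)
}

#' @describeIn MetabolicNetwork gene node ids
#' @param object a \code{MetabolicNetwork}
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))

#' @rdname MetabolicNetwork
#' @export
setMethod("networkGenes", "MetabolicNetwork",
          function(object) unique(object@edges$gene))

#' @describeIn MetabolicNetwork metabolite node ids
#' @export
setGeneric("networkMetabolites",
           function(object) standardGeneric("networkMetabolites"))

#' @rdname MetabolicNetwork
#' @export
setMethod("networkMetabolites", "MetabolicNetwork",
          function(object) unique(object@edges$metabolite))

#' @describeIn MetabolicNetwork edge table
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname MetabolicNetwork
#' @export
setMethod("networkEdges", "MetabolicNetwork", function(object) object@edges)

#' @describeIn MetabolicNetwork gene node weights (p-values)
#' @export
setGeneric("geneWeights", function(object) standardGeneric("geneWeights"))

#' @rdname MetabolicNetwork
#' @export
setMethod("geneWeights", "MetabolicNetwork",
          function(object) object@geneWeights)

#' @describeIn MetabolicNetwork replace gene node weights
#' @param value named numeric p-values in (0,1]
#' @export
setGeneric("geneWeights<-",
           function(object, value) standardGeneric("geneWeights<-"))

#' @rdname MetabolicNetwork
#' @export
setMethod("geneWeights<-", "MetabolicNetwork", function(object, value) {
    object@geneWeights <- value
    validObject(object)
    object
})

setMethod("show", "MetabolicNetwork", function(object) {
    cat("MetabolicNetwork:", length(networkGenes(object)), "genes,",
        length(networkMetabolites(object)), "metabolites,",
        nrow(object@edges), "edges\n")
    if (length(object@geneWeights))
        cat("  gene weights set for", length(object@geneWeights), "genes\n")
})
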