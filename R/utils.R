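# internal helpers shared across modules

# p-values are clamped away from 0/1 before qnorm so probit scores stay finite
.clampP <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

.splitMulti <- function(x) {
    x <- as.character(x)
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
}

.joinMulti <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Convert a flat annotation table to GRanges
#'
#' @param annotation data.frame with columns \code{gene_id},
#'   \code{scaffold_id}, \code{start}, \code{end}, \code{strand} and
#'   optionally \code{gc}, \code{taxonomy}, \code{categories}, \code{domains}
#'   (';'-separated) and \code{scaffold_length}; coordinates 1-based
#'   inclusive.  A \code{GRanges} input is returned unchanged.
#' @return \code{GRanges} named by gene id, with scaffold lengths in
#'   \code{seqlengths} when available.
#' @export
annotationToGRanges <- function(annotation) {
    if (is(annotation, "GRanges")) return(annotation)
    ann <- as.data.frame(annotation)
    req <- c("gene_id", "scaffold_id", "start", "end", "strand")
    miss <- setdiff(req, colnames(ann))
    if (length(miss))
        stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
    if (any(ann$start > ann$end))
        stop("annotation has start > end")
    if (anyDuplicated(ann$gene_id))
        stop("duplicate gene ids in annotation")
    gr <- GenomicRanges::GRanges(
        seqnames = ann$scaffold_id,
        ranges = IRanges::IRanges(ann$start, ann$end),
        strand = ann$strand)
    names(gr) <- ann$gene_id
    extra <- setdiff(colnames(ann),
                     c(req, "scaffold_length", "length", "dist_to_end"))
    md <- ann[, extra, drop = FALSE]
    for (col in intersect(c("categories", "domains"), colnames(md)))
        md[[col]] <- IRanges::CharacterList(.splitMulti(md[[col]]))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(md)
    if ("scaffold_length" %in% colnames(ann)) {
        sl <- tapply(ann$scaffold_length, ann$scaffold_id, max)
        GenomeInfoDb::seqlengths(gr) <-
            as.integer(sl[GenomeInfoDb::seqlevels(gr)])
    }
    gr
}

#' Convert annotation GRanges back to the flat table
#'
#' Inverse of \code{\link{annotationToGRanges}}; derives \code{length} and
#' \code{dist_to_end} (distance from the gene to the nearer scaffold end).
#' @param gr annotation \code{GRanges}
#' @return data.frame, one row per gene, sorted by scaffold and start.
#' @export
grangesToAnnotation <- function(gr) {
    sl <- GenomeInfoDb::seqlengths(gr)
    scaffold <- as.character(GenomeInfoDb::seqnames(gr))
    start <- GenomicRanges::start(gr)
    end <- GenomicRanges::end(gr)
    slen <- unname(sl[scaffold])
    d2e <- ifelse(is.na(slen), NA_real_, pmin(start - 1, slen - end))
    ann <- data.frame(gene_id = names(gr), scaffold_id = scaffold,
                      start = start, end = end,
                      strand = as.character(GenomicRanges::strand(gr)),
                      length = end - start + 1L,
                      dist_to_end = d2e,
                      scaffold_length = slen,
                      stringsAsFactors = FALSE)
    md <- as.data.frame(S4Vectors::mcols(gr))
    for (col in intersect(c("categories", "domains"), colnames(md)))
        md[[col]] <- .joinMulti(S4Vectors::mcols(gr)[[col]])
    ann <- cbind(ann, md)
    rownames(ann) <- NULL
    ann[order(ann$scaffold_id, ann$start), , drop = FALSE]
}

# annotation rows ordered along the chromosome, split per scaffold
.scaffoldOrder <- function(ann) {
    ann <- ann[order(ann$scaffold_id, ann$start), , drop = FALSE]
    split(ann, ann$scaffold_id)
}
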