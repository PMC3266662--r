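# Transcript-protein fold-change integration: quadrant classification,
# translational control efficiency ratio, and fold-change concordance.

#' Classify transcript-protein fold-change pairs
#'
#' Two log2 fold-change cut-offs define the classes: \code{hi} (default 0.6,
#' i.e. 1.5-fold) marks differential expression and \code{lo} (default 0.3,
#' i.e. 1.2-fold) marks "not differentially expressed".  With the sign
#' convention positive = more abundant in the first-named condition:
#' \itemize{
#'   \item Q1: protein and transcript both >= hi
#'   \item Q2: protein >= hi, transcript <= -hi
#'   \item Q3: both <= -hi
#'   \item Q4: protein <= -hi, transcript >= hi
#'   \item T0: protein >= hi, |transcript| <= lo
#'   \item T-0: protein <= -hi, |transcript| <= lo
#' }
#' Anything else (including a transcript between \code{lo} and \code{hi}
#' alongside a changed protein) is \code{unclassified}.
#'
#' @param protein_log2FC,transcript_log2FC finite numeric vectors.
#' @param hi,lo log2 cut-offs.
#' @return character vector of class labels.
#' @examples
#' classifyPairs(c(0.7, 0.7, 0.7), c(0.7, -0.7, 0.1))
#' @export
classifyPairs <- function(protein_log2FC, transcript_log2FC,
                          hi = 0.6, lo = 0.3) {
    if (any(!is.finite(protein_log2FC)) || any(!is.finite(transcript_log2FC)))
        stop("fold changes must be finite")
    p <- protein_log2FC; t <- transcript_log2FC
    cls <- rep("unclassified", length(p))
    cls[p >= hi & t >= hi] <- "Q1"
    cls[p >= hi & t <= -hi] <- "Q2"
    cls[p <= -hi & t <= -hi] <- "Q3"
    cls[p <= -hi & t >= hi] <- "Q4"
    cls[p >= hi & abs(t) <= lo] <- "T0"
    cls[p <= -hi & abs(t) <= lo] <- "T-0"
    cls
}

#' Translational control efficiency ratio
#'
#' \deqn{TCEr = 2^{(protein\ log2FC - transcript\ log2FC)}} — the ratio of
#' the protein fold change to the transcript fold change on the linear
#' scale.  TCEr far from 1 indicates post-transcriptional control; the
#' conventional flags mark proteins translated more than 3 times more
#' (TCEr > 3) or less (TCEr < 1/3) efficiently in the first-named condition.
#' Swapping the comparison direction inverts TCEr exactly.
#'
#' @param protein_log2FC,transcript_log2FC finite numeric vectors.
#' @return data.frame with \code{TCEr}, \code{high} (TCEr > 3) and
#'   \code{low} (TCEr < 1/3).
#' @export
computeTcer <- function(protein_log2FC, transcript_log2FC) {
    if (any(!is.finite(protein_log2FC)) || any(!is.finite(transcript_log2FC)))
        stop("fold changes must be finite")
    tcer <- 2^(protein_log2FC - transcript_log2FC)
    data.frame(TCEr = tcer, high = tcer > 3, low = tcer < 1 / 3)
}

#' Transcript-protein fold-change correlation
#'
#' Pearson and Spearman correlation of paired transcript and protein log2
#' fold changes within one condition comparison.
#'
#' @param pairs data.frame with columns \code{protein_log2FC} and
#'   \code{transcript_log2FC} (one comparison).
#' @return list with \code{pearson} and \code{spearman}.
#' @export
fcCorrelation <- function(pairs) {
    if (nrow(pairs) < 3) stop("need at least 3 pairs")
    list(pearson = stats::cor(pairs$transcript_log2FC,
                              pairs$protein_log2FC, method = "pearson"),
         spearman = stats::cor(pairs$transcript_log2FC,
                               pairs$protein_log2FC, method = "spearman"))
}

#' Full transcript-protein integration of a pairs table
#'
#' Applies \code{\link{classifyPairs}} and \code{\link{computeTcer}} per row
#' and summarises class counts per comparison.
#'
#' @param pairs data.frame with columns \code{protein_id}, \code{gene_id},
#'   \code{comparison}, \code{protein_log2FC}, \code{transcript_log2FC}.
#' @param hi,lo classification cut-offs (see \code{\link{classifyPairs}}).
#' @return the input with \code{class}, \code{TCEr}, \code{tcer_high},
#'   \code{tcer_low} columns appended; attribute \code{"class_counts"} holds
#'   the per-comparison class table.
#' @export
integratePairs <- function(pairs, hi = 0.6, lo = 0.3) {
    pairs$class <- classifyPairs(pairs$protein_log2FC,
                                 pairs$transcript_log2FC, hi = hi, lo = lo)
    tc <- computeTcer(pairs$protein_log2FC, pairs$transcript_log2FC)
    pairs$TCEr <- tc$TCEr
    pairs$tcer_high <- tc$high
    pairs$tcer_low <- tc$low
    attr(pairs, "class_counts") <- table(pairs$comparison, pairs$class)
    pairs
}
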