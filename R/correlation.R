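#' Per-gene correlation of expression with SPPR
#'
#' For every gene the Pearson (default) or Spearman correlation between its
#' log2 expression profile and the per-sample specific extracellular protein
#' production rate is computed, with the exact t-distribution p-value
#' (\eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 df) and Storey q-values for FDR
#' control.  Genes with zero expression variance have no defined correlation;
#' they are excluded and reported with \code{NA}, and do not enter the
#' q-value computation.
#'
#' @param object a \linkS4class{SpprExperiment}, or a numeric matrix of log2
#'   expression (genes x samples).
#' @param sppr per-sample SPPR values (taken from \code{colData} for a
#'   \code{SpprExperiment}); names, if present, must match sample columns.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param alternative sidedness of the p-value: \code{"two.sided"} (default),
#'   \code{"positive"} (H1: r > 0) or \code{"negative"} (H1: r < 0).  The
#'   one-sided variants feed the metabolic-network analyses.
#' @param log_sppr correlate against \code{log(sppr)} instead of the raw rate.
#' @param qvalues compute Storey q-values (skipped for one-sided runs unless
#'   requested).
#' @return data.frame with columns \code{gene_id}, \code{r}, \code{p},
#'   \code{q}, \code{n}; attribute \code{"pi0"} carries the null-proportion
#'   estimate.
#' @examples
#' sim <- simulateExperiment(syntheticSpec(seed = 1))
#' head(correlateToSppr(sim$experiment))
#' @export
setGeneric("correlateToSppr",
           function(object, sppr = NULL, ...) standardGeneric("correlateToSppr"))

#' @rdname correlateToSppr
#' @param ... passed on to the matrix method
#' @export
setMethod("correlateToSppr", "SpprExperiment",
          function(object, sppr = NULL, ...) {
    if (is.null(sppr)) sppr <- sppr(object)
    callGeneric(log2Expr(object), sppr = sppr, ...)
})

#' @rdname correlateToSppr
#' @export
setMethod("correlateToSppr", "matrix", function(object, sppr = NULL,
        method = c("pearson", "spearman"),
        alternative = c("two.sided", "positive", "negative"),
        log_sppr = FALSE, qvalues = TRUE) {
    method <- match.arg(method)
    alternative <- match.arg(alternative)
    expr <- object
    n <- ncol(expr)
    if (n < 3) stop("need at least 3 samples")
    if (length(sppr) != n) stop("sppr length must equal sample count")
    if (!is.null(names(sppr)) && !is.null(colnames(expr))) {
        if (!setequal(names(sppr), colnames(expr)))
            stop("sample ids of sppr do not match expression columns")
        sppr <- sppr[colnames(expr)]
    }
    x <- if (log_sppr) log(sppr) else as.numeric(sppr)
    if (method == "spearman") {
        x <- rank(x)
        expr <- t(apply(expr, 1, rank))
    }
    v <- apply(expr, 1, stats::var)
    ok <- v > 0
    r <- rep(NA_real_, nrow(expr))
    r[ok] <- as.numeric(stats::cor(t(expr[ok, , drop = FALSE]), x))
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tstat), df = n - 2),
                positive = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
                negative = stats::pt(tstat, df = n - 2))
    p <- pmin(p, 1)
    q <- rep(NA_real_, length(p))
    pi0 <- NA_real_
    if (qvalues && any(ok)) {
        qv <- estimateQvalues(p[ok])
        q[ok] <- qv$q
        pi0 <- qv$pi0
    }
    out <- data.frame(gene_id = rownames(expr), r = r, p = p, q = q, n = n,
                      stringsAsFactors = FALSE)
    attr(out, "pi0") <- pi0
    rownames(out) <- NULL
    out
})

#' Storey q-values
#'
#' Estimates the proportion of true nulls \eqn{\pi_0} on a grid of tuning
#' values \eqn{\lambda} via \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m(1-\lambda))}, smooths the estimates with a cubic smoothing spline and
#' takes the value at the largest \eqn{\lambda} (clipped to (0,1]).  The
#' q-value of the i-th ordered p-value is then
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 \, m \, p_{(j)} / j}, capped at 1.
#'
#' @param p p-values in [0,1].
#' @param lambda grid for the \eqn{\pi_0} estimate; a single value skips the
#'   smoother and uses the point estimate at that \eqn{\lambda}.
#' @return list with \code{q} (same order as \code{p}) and \code{pi0}.
#' @examples
#' estimateQvalues(c(0.001, 0.01, 0.5, 0.9), lambda = 0.5)
#' @export
estimateQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0,1]")
    m <- length(p)
    if (length(lambda) == 1) {
        pi0 <- sum(p > lambda) / (m * (1 - lambda))
    } else {
        pl <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                     numeric(1))
        fit <- stats::smooth.spline(lambda, pl, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
    o <- order(p)
    q <- pi0 * m * p[o] / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    list(q = out, pi0 = pi0)
}

#' Select genes significantly correlated with SPPR
#'
#' Partitions genes exceeding an absolute-correlation cut-off by the sign of
#' the correlation and reports the FDR achieved at the cut (the largest
#' q-value among the selected genes).
#'
#' @param records data.frame from \code{\link{correlateToSppr}}.
#' @param r_cut absolute correlation cut-off, in (0,1).
#' @return list with \code{positive} and \code{negative} gene-id vectors and
#'   \code{fdr}, the achieved FDR at the cut (NA if nothing selected).
#' @export
selectSignificant <- function(records, r_cut = 0.8) {
    if (!is.numeric(r_cut) || length(r_cut) != 1 || r_cut <= 0 || r_cut >= 1)
        stop("r_cut must lie strictly between 0 and 1")
    if (!nrow(records)) stop("empty correlation table")
    sel <- !is.na(records$r) & abs(records$r) > r_cut
    fdr <- if (any(sel) && !all(is.na(records$q[sel])))
        max(records$q[sel], na.rm = TRUE) else NA_real_
    list(positive = records$gene_id[sel & records$r > 0],
         negative = records$gene_id[sel & records$r < 0],
         fdr = fdr)
}

#' Sensitivity of the correlation analysis to a single sample
#'
#' Recomputes all gene-SPPR correlations with one sample excluded and
#' reports how the count of genes above an absolute-correlation cut-off
#' changes (the paper-style outlier check: a sample sitting off the
#' regression line attenuates many correlations).
#'
#' @param object \code{SpprExperiment} or expression matrix.
#' @param sppr per-sample SPPR (for the matrix interface).
#' @param sample_id the sample to drop.
#' @param r_cut absolute correlation cut-off.
#' @return list with \code{count_full}, \code{count_excluded},
#'   \code{relative_change} ((excluded - full)/full).
#' @export
exclusionSensitivity <- function(object, sample_id, sppr = NULL,
                                 r_cut = 0.8) {
    if (is(object, "SpprExperiment")) {
        if (is.null(sppr)) sppr <- sppr(object)
        object <- log2Expr(object)
    }
    if (!sample_id %in% colnames(object))
        stop("unknown sample id: ", sample_id)
    if (ncol(object) - 1 < 3)
        stop("exclusion would leave fewer than 3 samples")
    if (is.null(names(sppr))) names(sppr) <- colnames(object)
    countAbove <- function(m, s) {
        cc <- correlateToSppr(m, sppr = s, qvalues = FALSE)
        sum(abs(cc$r) > r_cut, na.rm = TRUE)
    }
    keep <- setdiff(colnames(object), sample_id)
    n_full <- countAbove(object, sppr)
    n_exc <- countAbove(object[, keep, drop = FALSE], sppr[keep])
    list(count_full = n_full, count_excluded = n_exc,
         relative_change = if (n_full > 0) (n_exc - n_full) / n_full
                           else NA_real_)
}

# method-of-moments fit of the scaled-inverse-chi-square variance prior:
# s^2 / s0^2 ~ F(d, d0); matches limma's model with a moment estimator.
.ebPrior <- function(s2, d) {
    m1 <- mean(s2)
    cv2 <- stats::var(s2) / m1^2
    if (!is.finite(cv2) || cv2 * d <= 2) {
        list(d0 = Inf, s0sq = m1)
    } else {
        d0 <- (4 * cv2 * d + 2 * d - 4) / (cv2 * d - 2)
        if (d0 <= 2 || !is.finite(d0)) return(list(d0 = Inf, s0sq = m1))
        list(d0 = d0, s0sq = m1 * (d0 - 2) / d0)
    }
}

#' Moderated differential expression between conditions
#'
#' Per-gene two-group comparison with empirical-Bayes variance moderation:
#' the pooled within-group variance of each gene is shrunk towards a prior
#' variance \eqn{s_0^2} with prior degrees of freedom \eqn{d_0}, both
#' estimated across genes by the method of moments under a scaled inverse
#' chi-square prior, and the moderated t-statistic is referred to a t
#' distribution on \eqn{d + d_0} df.  P-values are Benjamini-Hochberg
#' adjusted per contrast; a gene is called significant when
#' \code{p_adj < p_cut} and \code{|log2FC| > lfc_cut}.
#'
#' @param object \code{SpprExperiment} or log2 expression matrix.
#' @param contrasts list of 2-vectors \code{c(A, B)} of condition labels;
#'   the log2 fold change is mean(A) - mean(B).  Default: all condition
#'   pairs.
#' @param condition per-sample condition labels (matrix interface).
#' @param moderate if \code{FALSE}, plain pooled-variance t-tests.
#' @param p_cut,lfc_cut significance rule applied to the adjusted p-value
#'   and absolute log2 fold change.
#' @return data.frame with columns \code{gene_id}, \code{contrast},
#'   \code{log2FC}, \code{p}, \code{p_adj}, \code{significant}; attributes
#'   \code{d0} and \code{s0sq} per contrast.
#' @export
setGeneric("differentialExpression",
           function(object, ...) standardGeneric("differentialExpression"))

#' @rdname differentialExpression
#' @param ... passed to the matrix method
#' @export
setMethod("differentialExpression", "SpprExperiment",
          function(object, ...) {
    callGeneric(log2Expr(object),
                condition = as.character(conditions(object)), ...)
})

#' @rdname differentialExpression
#' @export
setMethod("differentialExpression", "matrix",
          function(object, condition, contrasts = NULL, moderate = TRUE,
                   p_cut = 0.05, lfc_cut = 0.5) {
    if (length(condition) != ncol(object))
        stop("condition length must equal sample count")
    lev <- unique(condition)
    if (is.null(contrasts)) {
        contrasts <- utils::combn(lev, 2, simplify = FALSE)
    }
    prior <- list()
    res <- lapply(contrasts, function(ct) {
        ia <- condition == ct[1]; ib <- condition == ct[2]
        na <- sum(ia); nb <- sum(ib)
        if (na < 2 || nb < 2)
            stop("contrast ", ct[1], " vs ", ct[2],
                 ": need >=2 replicates per condition")
        a <- object[, ia, drop = FALSE]; b <- object[, ib, drop = FALSE]
        ma <- rowMeans(a); mb <- rowMeans(b)
        lfc <- ma - mb
        d <- na + nb - 2
        ssa <- rowSums((a - ma)^2); ssb <- rowSums((b - mb)^2)
        s2 <- (ssa + ssb) / d
        if (moderate) {
            pr <- .ebPrior(s2, d)
            s2t <- if (is.finite(pr$d0))
                (pr$d0 * pr$s0sq + d * s2) / (pr$d0 + d)
            else rep(pr$s0sq, length(s2))
            dft <- d + pr$d0
        } else {
            pr <- list(d0 = 0, s0sq = NA_real_)
            s2t <- s2
            dft <- d
        }
        se <- sqrt(s2t * (1 / na + 1 / nb))
        tt <- lfc / se
        p <- 2 * stats::pt(-abs(tt), df = dft)
        padj <- stats::p.adjust(p, method = "BH")
        prior[[paste(ct, collapse = "v")]] <<- pr
        data.frame(gene_id = rownames(object),
                   contrast = paste0(ct[1], "v", ct[2]),
                   log2FC = lfc, p = p, p_adj = padj,
                   significant = padj < p_cut & abs(lfc) > lfc_cut,
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, res)
    attr(out, "prior") <- prior
    out
})
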