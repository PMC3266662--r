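# Cross-platform calibration of expression measurements (multiplex
# affinity-capture vs microarray) by AIC model selection, and functional
# category enrichment tests.

#' Fit and select cross-platform calibration models
#'
#' Three nested ordinary-least-squares models relate the microarray signal
#' to the affinity-capture (TRAC) signal of the same genes and samples:
#' \itemize{
#'   \item m0: \eqn{Array_{ij} = \alpha + \beta\,TRAC_{ij} + \epsilon_{ij}}
#'     (single intercept and slope)
#'   \item m1: \eqn{Array_{ij} = \alpha_j + \beta\,TRAC_{ij} +
#'     \epsilon_{ij}} (gene-specific intercepts, shared slope)
#'   \item m2: gene-specific intercepts and slopes
#' }
#' with \eqn{\epsilon \sim N(0, \sigma^2)}.  Models are compared by the
#' Gaussian-likelihood AIC in its least-squares form
#' \eqn{AIC = n \ln(RSS/n) + 2 n_{par}} (same constant convention across
#' models, so differences are comparable); ties select the model with fewer
#' parameters.
#'
#' @param table data.frame with columns \code{gene}, \code{sample},
#'   \code{trac}, \code{array}.
#' @return list with per-model fits (\code{slope}, \code{sigma} —
#'   degrees-of-freedom-corrected residual SD, \code{rss}, \code{aic},
#'   \code{n_params}, and intercepts) and \code{selected}, the winning model
#'   name.
#' @export
fitTracModels <- function(table) {
    df <- data.frame(gene = factor(table$gene), trac = table$trac,
                     array = table$array)
    n <- nrow(df)
    G <- nlevels(df$gene)
    aicOf <- function(fit) {
        rss <- sum(stats::residuals(fit)^2)
        npar <- length(stats::coef(fit)[!is.na(stats::coef(fit))]) + 1  # +sigma
        list(rss = rss, aic = n * log(rss / n) + 2 * npar, n_params = npar,
             sigma = sqrt(rss / stats::df.residual(fit)))
    }
    f0 <- stats::lm(array ~ trac, data = df)
    f1 <- if (G > 1) stats::lm(array ~ 0 + gene + trac, data = df) else f0
    m0 <- c(aicOf(f0), list(slope = unname(stats::coef(f0)["trac"]),
                            intercept = unname(stats::coef(f0)[1])))
    m1 <- c(aicOf(f1),
            list(slope = unname(stats::coef(f1)["trac"]),
                 intercepts = stats::coef(f1)[seq_len(G)]))
    perGene <- table(df$gene)
    if (any(perGene < 2))
        stop("m2 needs at least 2 observations per gene")
    f2 <- if (G > 1) stats::lm(array ~ 0 + gene + gene:trac, data = df)
          else f0
    m2 <- c(aicOf(f2), list(slopes = stats::coef(f2)[-seq_len(G)]))
    fits <- list(m0 = m0, m1 = m1, m2 = m2)
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    npars <- vapply(fits, `[[`, numeric(1), "n_params")
    best <- which(aics <= min(aics) + 1e-9)
    selected <- names(fits)[best[which.min(npars[best])]]
    c(fits, list(selected = selected, n = n, n_genes = G))
}

#' Functional-category over-representation test
#'
#' One-sided over-representation p-value per category, by the
#' hypergeometric tail (for computationally created annotations) or
#' Fisher's exact test (for manual annotations); the two agree for a 2x2
#' table.  Reports the category's share of the query set ("% of expressed")
#' and the query set's share of the category ("% of annotated").  Raw
#' p-values are thresholded without multiple-testing adjustment by default.
#'
#' @param gene_set query gene ids (must be a subset of \code{background}).
#' @param background background gene ids.
#' @param categories data.frame with columns \code{gene} and
#'   \code{category}; must only reference background genes.
#' @param mode \code{"hypergeometric"} or \code{"fisher"}.
#' @param p_cut report categories with p below this cut (default 0.05).
#' @param adjust apply Benjamini-Hochberg adjustment before the cut.
#' @return data.frame with \code{category}, \code{hits}, \code{set_size},
#'   \code{category_size}, \code{background_size}, \code{pct_of_expressed},
#'   \code{pct_of_annotated}, \code{p}, sorted by p; only categories with at
#'   least one hit are tested.
#' @export
enrichmentTest <- function(gene_set, background, categories,
                           mode = c("hypergeometric", "fisher"),
                           p_cut = 0.05, adjust = FALSE) {
    mode <- match.arg(mode)
    if (!length(gene_set)) stop("empty gene set")
    if (!all(gene_set %in% background))
        stop("gene set is not a subset of the background")
    N <- length(unique(background))
    nset <- length(unique(gene_set))
    catMap <- split(categories$gene, categories$category)
    rows <- lapply(names(catMap), function(cat) {
        members <- intersect(unique(catMap[[cat]]), background)
        K <- length(members)
        x <- length(intersect(gene_set, members))
        if (x == 0) return(NULL)
        p <- if (mode == "hypergeometric") {
            stats::phyper(x - 1, K, N - K, nset, lower.tail = FALSE)
        } else {
            m <- matrix(c(x, K - x, nset - x, N - K - nset + x), 2)
            stats::fisher.test(m, alternative = "greater")$p.value
        }
        data.frame(category = cat, hits = x, set_size = nset,
                   category_size = K, background_size = N,
                   pct_of_expressed = 100 * x / nset,
                   pct_of_annotated = 100 * x / K,
                   p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(category = character(0), hits = integer(0),
                          set_size = integer(0), category_size = integer(0),
                          background_size = integer(0),
                          pct_of_expressed = numeric(0),
                          pct_of_annotated = numeric(0), p = numeric(0)))
    if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
    keep <- if (adjust) out$p_adj < p_cut else out$p < p_cut
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}
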