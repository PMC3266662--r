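# Synthetic-data generators: genome annotation, expression with planted
# SPPR correlations and chromosomal clusters, metabolic network with planted
# reporter metabolites and an enriched path, proteome pairs with controlled
# TCEr, paired cross-platform calibration signals, and cultivation tables.
# Every generator is deterministic given the spec seed.

#' Specification of a synthetic study
#'
#' Defines the structure and planted signal of a synthetic chemostat study.
#' The defaults emulate the design of the real experiment at desk scale:
#' 9 samples in 3 conditions (triplicate chemostats at growth rates
#' 0.03/h low density, 0.06/h low density and 0.03/h high density), a
#' genome of \code{n_scaffolds * genes_per_scaffold} genes, a subset of
#' genes with planted expression-SPPR correlations of both signs, planted
#' runs of adjacent co-correlated genes, and log2-normal expression noise.
#'
#' @slot n_scaffolds,genes_per_scaffold,n_samples counts.
#' @slot conditions character, one condition label per sample.
#' @slot sppr_values numeric, per-sample SPPR in mg protein/g biomass/h.
#' @slot planted_corr named numeric: gene id -> target Pearson correlation
#'   in [-1,1].
#' @slot planted_clusters data.frame with columns \code{scaffold},
#'   \code{start} (gene index on the scaffold), \code{length}, \code{sign}.
#' @slot cluster_r absolute planted correlation of cluster genes.
#' @slot noise_sd expression noise SD in log2 units.
#' @slot gc_means,gc_sd GC% distribution per taxonomy class.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticSpec",
         representation(n_scaffolds = "integer",
                        genes_per_scaffold = "integer",
                        n_samples = "integer",
                        conditions = "character",
                        sppr_values = "numeric",
                        planted_corr = "numeric",
                        planted_clusters = "data.frame",
                        cluster_r = "numeric",
                        noise_sd = "numeric",
                        gc_means = "numeric",
                        gc_sd = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- NULL
    if (object@n_scaffolds < 1 || object@genes_per_scaffold < 1)
        msg <- c(msg, "scaffold and gene counts must be positive")
    if (object@n_samples < 3) msg <- c(msg, "need at least 3 samples")
    if (length(object@sppr_values) != object@n_samples)
        msg <- c(msg, "sppr_values length must equal n_samples")
    if (any(object@sppr_values <= 0)) msg <- c(msg, "sppr must be positive")
    if (length(object@conditions) != object@n_samples)
        msg <- c(msg, "conditions length must equal n_samples")
    if (length(object@planted_corr) &&
        (is.null(names(object@planted_corr)) ||
         any(abs(object@planted_corr) > 1)))
        msg <- c(msg, "planted_corr must be named and within [-1,1]")
    if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be positive")
    if (any(object@gc_means < 0) || any(object@gc_means > 100))
        msg <- c(msg, "gc_means must lie in [0,100]")
    pc <- object@planted_clusters
    if (nrow(pc)) {
        if (any(pc$scaffold > object@n_scaffolds) ||
            any(pc$start < 1) ||
            any(pc$start + pc$length - 1 > object@genes_per_scaffold))
            msg <- c(msg, "planted cluster indices exceed scaffold bounds")
        if (!all(pc$sign %in% c("+", "-")))
            msg <- c(msg, "cluster sign must be '+' or '-'")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@n_scaffolds, "scaffolds x",
        object@genes_per_scaffold, "genes,", object@n_samples, "samples,",
        length(object@planted_corr), "planted correlated genes,",
        nrow(object@planted_clusters), "planted clusters, noise_sd",
        object@noise_sd, ", seed", object@seed, "\n")
})

#' Gene identifiers of a synthetic genome
#' @param spec a \code{SyntheticSpec}
#' @return character vector, scaffold-major order
#' @export
syntheticGeneIds <- function(spec) {
    as.vector(vapply(seq_len(spec@n_scaffolds), function(s)
        sprintf("s%02dg%03d", s, seq_len(spec@genes_per_scaffold)),
        character(spec@genes_per_scaffold)))
}

#' Construct a SyntheticSpec
#'
#' @param n_scaffolds,genes_per_scaffold genome size (default 10 x 100).
#' @param conditions per-sample condition labels; default triplicates of
#'   D03, D06, HD.
#' @param sppr_values per-sample SPPR (mg/g/h); default rates typical of
#'   lactose-limited chemostats of a hypersecreting strain, highest at the
#'   low growth rate and lowest at high cell density.
#' @param n_planted_pos,n_planted_neg number of genes planted at
#'   correlation \code{+planted_r}/\code{-planted_r} (placed away from the
#'   planted clusters).
#' @param planted_r target absolute correlation of planted single genes.
#' @param planted_clusters data.frame (\code{scaffold}, \code{start},
#'   \code{length}, \code{sign}); the default plants one positive 5-gene,
#'   one positive 4-gene and one negative 3-gene run.
#' @param cluster_r absolute correlation planted in cluster genes.
#' @param noise_sd log2 expression noise SD (default 0.25).
#' @param gc_means,gc_sd GC%% by taxonomy class; the lineage-specific class
#'   is set lower, as observed for non-syntenic regions.
#' @param seed master seed.
#' @return a validated \code{SyntheticSpec}.
#' @examples
#' syntheticSpec(seed = 7)
#' @export
syntheticSpec <- function(n_scaffolds = 10, genes_per_scaffold = 100,
                          conditions = rep(c("D03", "D06", "HD"), each = 3),
                          sppr_values = c(3.0, 2.6, 3.4, 1.5, 1.4, 1.6,
                                          0.8, 0.7, 0.9),
                          n_planted_pos = 50, n_planted_neg = 50,
                          planted_r = 0.9,
                          planted_clusters = data.frame(
                              scaffold = c(1, 4, 7),
                              start = c(11, 51, 31),
                              length = c(5, 4, 3),
                              sign = c("+", "+", "-")),
                          cluster_r = 0.9,
                          noise_sd = 0.25,
                          gc_means = c(Fungi = 58, Pezizomycotina = 58,
                                       Trichoderma = 55.5),
                          gc_sd = 3,
                          seed = 1) {
    spec <- new("SyntheticSpec",
                n_scaffolds = as.integer(n_scaffolds),
                genes_per_scaffold = as.integer(genes_per_scaffold),
                n_samples = length(conditions),
                conditions = as.character(conditions),
                sppr_values = sppr_values,
                planted_corr = numeric(0),
                planted_clusters = planted_clusters,
                cluster_r = cluster_r,
                noise_sd = noise_sd, gc_means = gc_means, gc_sd = gc_sd,
                seed = as.integer(seed))
    ids <- syntheticGeneIds(spec)
    inCluster <- unlist(lapply(seq_len(nrow(planted_clusters)), function(i)
        sprintf("s%02dg%03d", planted_clusters$scaffold[i],
                planted_clusters$start[i] +
                    seq_len(planted_clusters$length[i]) - 1)))
    free <- setdiff(ids, inCluster)
    npl <- n_planted_pos + n_planted_neg
    if (npl > length(free))
        stop("too many planted genes for the genome size")
    # deterministic, evenly spread placement of planted singles
    pick <- free[round(seq(1, length(free), length.out = npl))]
    if (anyDuplicated(pick)) pick <- utils::head(free, npl)
    pc <- c(rep(planted_r, n_planted_pos), rep(-planted_r, n_planted_neg))
    names(pc) <- pick
    spec@planted_corr <- pc
    validObject(spec)
    spec
}

#' Generate a synthetic genome annotation
#'
#' Gene lengths are log-normal (median about 1.3 kb), intergenic gaps
#' exponential, strands random; GC%% is drawn per gene from its taxonomy
#' class mean (GC is generated as a number, not from sequence).  Taxonomy
#' labels, functional categories and InterPro-style domain sets are sampled
#' from fixed pools.  Deterministic given the spec seed.
#'
#' @param spec a \code{SyntheticSpec}.
#' @return flat annotation data.frame (see
#'   \code{\link{annotationToGRanges}}), sorted by scaffold and start, with
#'   non-overlapping 1-based inclusive coordinates.
#' @export
simulateGenome <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    taxPool <- names(spec@gc_means)
    catPool <- paste0("CAT", sprintf("%02d", 1:20))
    domPool <- sprintf("IPR%06d", 1:150)
    rows <- list()
    for (s in seq_len(spec@n_scaffolds)) {
        n <- spec@genes_per_scaffold
        len <- pmax(200L, as.integer(round(stats::rlnorm(n, log(1300), 0.4))))
        gap <- as.integer(round(stats::rexp(n, 1 / 500))) + 200L
        start <- cumsum(c(1L, len[-n] + gap[-n])) + gap[1]
        end <- start + len - 1L
        tax <- sample(taxPool, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
        gc <- pmin(100, pmax(0, stats::rnorm(n, spec@gc_means[tax],
                                             spec@gc_sd)))
        ndom <- stats::rpois(n, 1.2)
        doms <- vapply(ndom, function(k)
            paste(sample(domPool, min(k, length(domPool))), collapse = ";"),
            character(1))
        cats <- sample(catPool, n, replace = TRUE)
        rows[[s]] <- data.frame(
            gene_id = sprintf("s%02dg%03d", s, seq_len(n)),
            scaffold_id = sprintf("scaffold_%02d", s),
            start = start, end = end,
            strand = sample(c("+", "-"), n, replace = TRUE),
            length = len, gc = gc, taxonomy = tax,
            categories = cats, domains = doms,
            scaffold_length = end[n] + 500L,
            stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    ann$dist_to_end <- pmin(ann$start - 1, ann$scaffold_length - ann$end)
    rownames(ann) <- NULL
    ann
}

# slope that gives expected Pearson correlation rho against fixed x at
# noise level sigma: b = rho*sigma/(sd(x)*sqrt(1-rho^2))
.plantSlope <- function(rho, x, sigma) {
    if (abs(rho) >= 1) return(sign(rho) * 1e6 * sigma / stats::sd(x))
    rho * sigma / (stats::sd(x) * sqrt(1 - rho^2))
}

#' Generate a synthetic expression matrix with planted SPPR correlations
#'
#' Planted genes follow \eqn{y = a + b\,SPPR + \epsilon} with the slope
#' chosen so that the expected Pearson correlation equals the planted
#' target; cluster genes are planted at \eqn{\pm cluster_r}; all other
#' genes are baseline plus independent Gaussian noise on the log2 scale.
#'
#' @param annotation annotation from \code{\link{simulateGenome}}.
#' @param spec the same \code{SyntheticSpec}.
#' @return a \linkS4class{SpprExperiment}; metadata field \code{planted}
#'   records the planted per-gene targets.
#' @export
simulateExpression <- function(annotation, spec) {
    validObject(spec)
    targets <- spec@planted_corr
    pc <- spec@planted_clusters
    if (nrow(pc)) {
        cl <- unlist(lapply(seq_len(nrow(pc)), function(i) {
            g <- sprintf("s%02dg%03d", pc$scaffold[i],
                         pc$start[i] + seq_len(pc$length[i]) - 1)
            stats::setNames(rep(ifelse(pc$sign[i] == "+", 1, -1) *
                                spec@cluster_r, length(g)), g)
        }))
        targets <- c(targets, cl[setdiff(names(cl), names(targets))])
    }
    miss <- setdiff(names(targets), annotation$gene_id)
    if (length(miss))
        stop("planted gene(s) absent from annotation: ",
             paste(utils::head(miss, 5), collapse = ", "))
    set.seed(spec@seed + 1L)
    ids <- annotation$gene_id
    n <- spec@n_samples
    x <- spec@sppr_values
    base <- stats::rnorm(length(ids), 8, 1.2)
    expr <- matrix(stats::rnorm(length(ids) * n, 0, spec@noise_sd),
                   nrow = length(ids))
    expr <- expr + base
    pi <- match(names(targets), ids)
    b <- vapply(targets, .plantSlope, numeric(1), x = x,
                sigma = spec@noise_sd)
    expr[pi, ] <- expr[pi, ] + outer(b, x - mean(x))
    rownames(expr) <- ids
    colnames(expr) <- sprintf("%s_r%d", spec@conditions,
                              stats::ave(seq_len(n), spec@conditions,
                                         FUN = seq_along))
    se <- SpprExperiment(expr, annotation = annotation,
                         condition = spec@conditions, sppr = x)
    S4Vectors::metadata(se)$planted <- targets
    se
}

#' Convenience wrapper: genome plus expression
#' @param spec a \code{SyntheticSpec}
#' @return list with \code{annotation}, \code{experiment} and
#'   \code{planted} (named target correlations)
#' @export
simulateExperiment <- function(spec) {
    ann <- simulateGenome(spec)
    se <- simulateExpression(ann, spec)
    list(annotation = ann, experiment = se,
         planted = S4Vectors::metadata(se)$planted)
}

#' Generate a synthetic bipartite metabolic network
#'
#' Random gene-metabolite edges (Poisson degrees) over a subset of the
#' annotated genes, with a planted chain of metabolites linking the genes
#' of \code{planted_path} consecutively, and planted reporter metabolites
#' wired to genes with planted correlations so that their neighbourhoods
#' carry low p-values downstream.  A cross-species similarity table with
#' bidirectional bit scores is generated for every network gene.
#'
#' @param annotation annotation data.frame.
#' @param n_metabolites number of metabolite nodes.
#' @param planted_reporter metabolite ids (subset of the generated ids) to
#'   wire to correlated genes.
#' @param planted_path gene ids to connect into a chain.
#' @param spec the \code{SyntheticSpec} (seed, planted correlations).
#' @param reporter_sign which correlation tail the planted reporters' genes
#'   are drawn from (\code{"-"}: negatively correlated genes, the default,
#'   or \code{"+"}).
#' @param n_genes number of network genes (default 150, or all if fewer).
#' @param degree_lambda Poisson mean of extra edges per gene (default 1).
#' @return list with \code{network} (\linkS4class{MetabolicNetwork}) and
#'   \code{similarity} (data.frame \code{query}, \code{subject},
#'   \code{bitscore}, both directions).
#' @export
simulateNetwork <- function(annotation, n_metabolites = 60,
                            planted_reporter = character(0),
                            planted_path = character(0), spec,
                            reporter_sign = c("-", "+"),
                            n_genes = 150, degree_lambda = 1) {
    reporter_sign <- match.arg(reporter_sign)
    validObject(spec)
    if (length(planted_path) &&
        length(planted_path) - 1 > n_metabolites)
        stop("planted path cannot be embedded: too few metabolites")
    miss <- setdiff(planted_path, annotation$gene_id)
    if (length(miss)) stop("planted path gene(s) not annotated: ",
                           paste(miss, collapse = ", "))
    set.seed(spec@seed + 2L)
    mets <- sprintf("m%03d", seq_len(n_metabolites))
    if (length(setdiff(planted_reporter, mets)))
        stop("planted_reporter must use generated metabolite ids")
    # reporter neighbourhoods draw from one correlation tail so the planted
    # metabolites stand out in the corresponding one-sided analysis
    tailGenes <- names(spec@planted_corr)[
        if (reporter_sign == "-") spec@planted_corr < 0
        else spec@planted_corr > 0]
    edges <- data.frame(gene = character(0), metabolite = character(0))
    # planted path: consecutive genes share a dedicated chain metabolite
    if (length(planted_path) > 1) {
        chain <- utils::tail(mets, length(planted_path) - 1)
        edges <- rbind(edges,
                       data.frame(gene = planted_path[-length(planted_path)],
                                  metabolite = chain),
                       data.frame(gene = planted_path[-1],
                                  metabolite = chain))
    }
    # planted reporter metabolites: neighbourhoods of correlated genes
    for (m in planted_reporter) {
        k <- min(4, length(tailGenes))
        if (k < 2) stop("planted reporters need planted correlated genes")
        edges <- rbind(edges, data.frame(
            gene = sample(tailGenes, k), metabolite = m))
    }
    pool <- unique(c(planted_path, edges$gene))
    extra <- setdiff(annotation$gene_id, c(pool, names(spec@planted_corr)))
    pool <- c(pool, sample(extra, max(0, min(n_genes, nrow(annotation)) -
                                          length(pool))))
    freeMets <- setdiff(mets, c(planted_reporter,
                                if (length(planted_path) > 1)
                                    utils::tail(mets,
                                                length(planted_path) - 1)))
    if (!length(freeMets)) freeMets <- mets
    ndeg <- 1 + stats::rpois(length(pool), degree_lambda)
    rnd <- data.frame(
        gene = rep(pool, ndeg),
        metabolite = sample(freeMets, sum(ndeg), replace = TRUE))
    edges <- unique(rbind(edges, rnd))
    net <- MetabolicNetwork(edges)
    genes <- networkGenes(net)
    s1 <- stats::runif(length(genes), 60, 400)
    s2 <- s1 * stats::runif(length(genes), 0.8, 1.2)
    src <- paste0("src_", genes)
    sim <- rbind(data.frame(query = genes, subject = src, bitscore = s1,
                            stringsAsFactors = FALSE),
                 data.frame(query = src, subject = genes, bitscore = s2,
                            stringsAsFactors = FALSE))
    conf <- s1 * s2 / max(s1 * s2)
    names(conf) <- genes
    net@confidence <- conf
    validObject(net)
    list(network = net, similarity = sim)
}

#' Generate synthetic transcript-protein pairs with controlled TCEr
#'
#' Protein log2 fold change = transcript log2 fold change +
#' log2(TCEr target) + Gaussian noise; transcript fold changes are the
#' condition mean differences of the supplied experiment.
#'
#' @param experiment a \linkS4class{SpprExperiment}.
#' @param comparisons list of condition pairs \code{c(A, B)}.
#' @param genes genes to report as proteins (default: 60 sampled genes).
#' @param tcer_targets numeric TCEr targets, recycled over genes (or a
#'   named vector by gene id).
#' @param noise_sd protein-level log2 noise SD.
#' @param seed integer seed.
#' @return pairs data.frame (\code{protein_id}, \code{gene_id},
#'   \code{comparison}, \code{protein_log2FC}, \code{transcript_log2FC},
#'   \code{tcer_target}).
#' @export
simulateProteome <- function(experiment, comparisons, genes = NULL,
                             tcer_targets = 1, noise_sd = 0.1, seed = 1) {
    cond <- as.character(conditions(experiment))
    for (ct in comparisons)
        if (!all(ct %in% cond))
            stop("unknown condition in comparison: ",
                 paste(ct, collapse = " vs "))
    expr <- log2Expr(experiment)
    set.seed(seed)
    if (is.null(genes))
        genes <- sample(rownames(expr), min(60, nrow(expr)))
    tc <- if (!is.null(names(tcer_targets))) tcer_targets[genes]
          else rep_len(tcer_targets, length(genes))
    rows <- lapply(comparisons, function(ct) {
        fa <- rowMeans(expr[genes, cond == ct[1], drop = FALSE])
        fb <- rowMeans(expr[genes, cond == ct[2], drop = FALSE])
        tfc <- fa - fb
        pfc <- tfc + log2(tc) + stats::rnorm(length(genes), 0, noise_sd)
        data.frame(protein_id = paste0("spot_", genes),
                   gene_id = genes,
                   comparison = paste0(ct[1], "v", ct[2]),
                   protein_log2FC = pfc, transcript_log2FC = tfc,
                   tcer_target = tc, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Generate paired cross-platform calibration signals
#'
#' Simulates the gene-specific-intercept model
#' \eqn{Array_{ij} = \alpha_j + \beta\,TRAC_{ij} + \epsilon_{ij}},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, with TRAC signals drawn uniformly
#' over a log2-signal-like range.
#'
#' @param gene_ids gene identifiers (one intercept each).
#' @param alphas per-gene intercepts; length must match \code{gene_ids}.
#' @param beta shared slope.
#' @param sigma residual SD (>= 0).
#' @param n_samples samples per gene.
#' @param seed integer seed.
#' @return data.frame (\code{gene}, \code{sample}, \code{trac},
#'   \code{array}).
#' @export
simulateTrac <- function(gene_ids, alphas, beta, sigma, n_samples = 9,
                         seed = 1) {
    if (length(alphas) != length(gene_ids))
        stop("alphas length must equal gene count")
    if (sigma < 0) stop("sigma must be non-negative")
    set.seed(seed)
    G <- length(gene_ids)
    trac <- stats::runif(G * n_samples, 6, 12)
    eps <- stats::rnorm(G * n_samples, 0, sigma)
    gene <- rep(gene_ids, each = n_samples)
    arr <- rep(alphas, each = n_samples) + beta * trac + eps
    data.frame(gene = gene,
               sample = rep(sprintf("s%02d", seq_len(n_samples)), G),
               trac = trac, array = arr, stringsAsFactors = FALSE)
}

#' Generate a steady-state cultivation table
#'
#' Produces per-sample dilution rate, feed substrate, biomass and
#' extracellular protein consistent with the spec's SPPR values under the
#' standard chemostat balances (so \code{\link{computeRates}} recovers the
#' planted SPPR exactly at zero noise).  Residual substrate is below
#' detection (0), as observed in lactose-limited runs.
#'
#' @param spec a \code{SyntheticSpec}.
#' @param yields named biomass yields (g/g) per condition.
#' @param noise_cv relative measurement noise on X and P (default 0).
#' @return cultivation data.frame ready for \code{\link{computeRates}}.
#' @export
simulateCultivations <- function(spec,
                                 yields = c(D03 = 0.45, D06 = 0.52,
                                            HD = 0.45),
                                 noise_cv = 0) {
    validObject(spec)
    set.seed(spec@seed + 3L)
    cond <- spec@conditions
    D <- ifelse(cond == "D06", 0.06, 0.03)
    S_feed <- ifelse(cond == "HD", 40, 10)
    Y <- yields[cond]
    X <- Y * S_feed
    P <- spec@sppr_values * X / (1000 * D)
    if (noise_cv > 0) {
        X <- X * (1 + stats::rnorm(length(X), 0, noise_cv))
        P <- P * (1 + stats::rnorm(length(P), 0, noise_cv))
    }
    data.frame(sample_id = sprintf("%s_r%d", cond,
                                   stats::ave(seq_along(cond), cond,
                                              FUN = seq_along)),
               condition = cond, D = D, X = X, P = P,
               S_feed = S_feed, S_res = 0, stringsAsFactors = FALSE)
}
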