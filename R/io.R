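# Readers and writers for the pipeline's plain-text interchange formats
# (TSV primary, GFF3 accepted for annotation, BED-like output for clusters)
# and the end-to-end pipeline driver.

.readTsv <- function(path, required = NULL) {
    if (!file.exists(path)) stop("input file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1) {
        bad <- which(nf != nf[1])[1]
        stop("malformed row at line ", bad, " of ", path)
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
    df
}

#' Read / write a log2 expression matrix
#'
#' TSV with gene ids in the first column (\code{gene_id}) and one column
#' per sample.
#' @param path file path
#' @return numeric matrix, genes x samples
#' @export
readExpression <- function(path) {
    df <- .readTsv(path, "gene_id")
    if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    storage.mode(m) <- "double"
    m
}

#' @rdname readExpression
#' @param expr matrix to write
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene annotation (flat TSV or GFF3)
#'
#' TSV columns are the flat annotation schema (see
#' \code{\link{annotationToGRanges}}); GFF3 files are parsed with
#' \pkg{rtracklayer}, taking \code{gene}-type features with attributes
#' \code{ID} (or \code{gene_id}), \code{gc}, \code{taxonomy},
#' \code{categories}, \code{domains}.  Coordinates are 1-based inclusive in
#' both formats.
#'
#' @param path file path; format chosen by extension (\code{.gff3}/
#'   \code{.gff} vs anything else = TSV).
#' @return flat annotation data.frame.
#' @export
readAnnotation <- function(path) {
    if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("rtracklayer is required to read GFF3")
        gr <- rtracklayer::import(path, format = "gff3")
        gr <- gr[gr$type == "gene"]
        ids <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
        ann <- data.frame(gene_id = ids,
                          scaffold_id = as.character(
                              GenomeInfoDb::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          stringsAsFactors = FALSE)
        for (col in c("gc", "taxonomy", "categories", "domains")) {
            v <- S4Vectors::mcols(gr)[[col]]
            if (!is.null(v)) ann[[col]] <-
                if (col == "gc") as.numeric(v) else as.character(v)
        }
        sl <- GenomeInfoDb::seqlengths(gr)
        if (!all(is.na(sl))) {
            ann$scaffold_length <- as.integer(sl[ann$scaffold_id])
            ann$dist_to_end <- pmin(ann$start - 1,
                                    ann$scaffold_length - ann$end)
        }
        ann$length <- ann$end - ann$start + 1L
    } else {
        ann <- .readTsv(path, c("gene_id", "scaffold_id", "start", "end",
                                "strand"))
    }
    if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in ", path)
    ann[order(ann$scaffold_id, ann$start), , drop = FALSE]
}

#' @rdname readAnnotation
#' @param annotation flat annotation data.frame
#' @param format \code{"tsv"} or \code{"gff3"}
#' @export
writeAnnotation <- function(annotation, path, format = c("tsv", "gff3")) {
    format <- match.arg(format)
    if (format == "tsv") {
        utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("rtracklayer is required to write GFF3")
        gr <- annotationToGRanges(annotation)
        S4Vectors::mcols(gr)$ID <- names(gr)
        S4Vectors::mcols(gr)$type <- "gene"
        for (col in c("categories", "domains"))
            if (col %in% colnames(S4Vectors::mcols(gr)))
                S4Vectors::mcols(gr)[[col]] <-
                    .joinMulti(S4Vectors::mcols(gr)[[col]])
        rtracklayer::export(gr, path, format = "gff3")
    }
    invisible(path)
}

#' Read / write the cultivation table
#'
#' TSV with the cultivation schema; a precomputed \code{SPPR} column, if
#' present, is kept as is.
#' @param path file path
#' @return data.frame
#' @export
readCultivations <- function(path)
    .readTsv(path, c("sample_id", "condition", "D", "X", "P", "S_feed",
                     "S_res"))

#' Read a bipartite metabolic network edge list
#'
#' TSV with columns \code{gene}, \code{metabolite} and optional
#' \code{reaction}.
#' @param path file path
#' @return a \linkS4class{MetabolicNetwork}
#' @export
readNetwork <- function(path)
    MetabolicNetwork(.readTsv(path, c("gene", "metabolite")))

#' Read transcript-protein pairs
#' @param path TSV with columns \code{protein_id}, \code{gene_id},
#'   \code{comparison}, \code{protein_log2FC}, \code{transcript_log2FC}
#' @return data.frame
#' @export
readPairs <- function(path)
    .readTsv(path, c("protein_id", "gene_id", "comparison",
                     "protein_log2FC", "transcript_log2FC"))

#' Read a blast-tabular similarity score table
#' @param path TSV with columns \code{query}, \code{subject},
#'   \code{bitscore}
#' @return data.frame
#' @export
readSimilarity <- function(path)
    .readTsv(path, c("query", "subject", "bitscore"))

#' Write detected clusters as BED-like TSV
#'
#' Columns: scaffold, 0-based half-open start/end (BED convention on
#' write; \code{readClusters} converts back), sign, gene list.
#' @param clusters data.frame from \code{\link{detectClusters}}
#' @param path file path
#' @export
writeClusters <- function(clusters, path) {
    bed <- data.frame(scaffold = clusters$scaffold_id,
                      start = clusters$start - 1L,
                      end = clusters$end,
                      sign = clusters$sign,
                      genes = clusters$genes)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
    bed <- .readTsv(path, c("scaffold", "start", "end", "sign", "genes"))
    data.frame(scaffold_id = bed$scaffold, sign = bed$sign,
               start = bed$start + 1L, end = bed$end,
               n_genes = lengths(.splitMulti(bed$genes)),
               genes = bed$genes, stringsAsFactors = FALSE)
}

#' Read a YAML pipeline configuration
#'
#' See the packaged example configuration produced by
#' \code{\link{defaultConfig}} for the recognised fields.
#' @param path YAML file
#' @return named list
#' @export
readConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    utils::modifyList(defaultConfig(), cfg)
}

#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults: correlation
#' selection cut 0.8, pair/cluster cut 0.7, DE rule p_adj<0.05 &
#' |log2FC|>0.5, integration cut-offs 0.6/0.3, reporter filter p<0.05,
#' path significance 0.025, and the Monte-Carlo sizes.
#' @return named list
#' @export
defaultConfig <- function() {
    list(seed = 1,
         r_cut_select = 0.8, r_cut_pairs = 0.7,
         de_p = 0.05, de_lfc = 0.5,
         fc_hi = 0.6, fc_lo = 0.3,
         n_perm = 2000, n_shuffle = 1000, n_background = 1000,
         empath_kmin = 3, empath_kmax = 5, empath_pcut = 0.025,
         empath_ncolorings = 300,
         synthetic = list(enabled = TRUE, n_scaffolds = 10,
                          genes_per_scaffold = 100, noise_sd = 0.25),
         inputs = list())
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — inputs (synthetic or from files),
#' physiology, SPPR correlation + selection, adjacent pairs + permutation
#' test + clusters + characteristics, reporter metabolites + enriched
#' paths, transcript-protein integration, calibration fit — writing each
#' stage's table under \code{out_dir} together with a run manifest
#' (package version, seed, parameters, stage warnings).  All randomness is
#' seeded from \code{config$seed}, so outputs are reproducible
#' byte-for-byte.
#'
#' @param config list from \code{\link{readConfig}} /
#'   \code{\link{defaultConfig}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of stage results.
#' @export
runPipeline <- function(config = defaultConfig(), out_dir = tempfile()) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    warnings <- character(0)
    stage <- function(name, fun) {
        tryCatch(withCallingHandlers(fun(), warning = function(w) {
            warnings <<- c(warnings, paste0(name, ": ",
                                            conditionMessage(w)))
            invokeRestart("muffleWarning")
        }), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    res <- list()
    res$inputs <- stage("inputs", function() {
        if (isTRUE(config$synthetic$enabled)) {
            spec <- syntheticSpec(
                n_scaffolds = config$synthetic$n_scaffolds,
                genes_per_scaffold = config$synthetic$genes_per_scaffold,
                noise_sd = config$synthetic$noise_sd,
                seed = config$seed)
            sim <- simulateExperiment(spec)
            cult <- computeRates(simulateCultivations(spec))
            pathGenes <- names(spec@planted_corr)[
                order(spec@planted_corr)][1:4]
            netw <- simulateNetwork(sim$annotation,
                                    planted_reporter = "m001",
                                    planted_path = pathGenes, spec = spec)
            prot <- simulateProteome(sim$experiment,
                                     comparisons = list(c("D03", "D06"),
                                                        c("D03", "HD")),
                                     seed = config$seed)
            trac <- simulateTrac(rownames(sim$experiment)[1:31],
                                 alphas = seq(1, 3, length.out = 31),
                                 beta = 0.52, sigma = 0.25,
                                 seed = config$seed)
            list(spec = spec, annotation = sim$annotation,
                 experiment = sim$experiment, cultivations = cult,
                 network = netw$network, similarity = netw$similarity,
                 pairs = prot, trac = trac)
        } else {
            inp <- config$inputs
            expr <- readExpression(inp$expression)
            ann <- readAnnotation(inp$annotation)
            cult <- readCultivations(inp$cultivations)
            if (!"SPPR" %in% colnames(cult)) cult <- computeRates(cult)
            cond <- cult$condition[match(colnames(expr), cult$sample_id)]
            se <- SpprExperiment(expr, annotation = ann, condition = cond,
                                 sppr = cult$SPPR[
                                     match(colnames(expr),
                                           cult$sample_id)])
            list(annotation = ann, experiment = se, cultivations = cult,
                 network = if (!is.null(inp$network))
                     readNetwork(inp$network),
                 similarity = if (!is.null(inp$similarity))
                     readSimilarity(inp$similarity),
                 pairs = if (!is.null(inp$pairs)) readPairs(inp$pairs),
                 trac = if (!is.null(inp$trac))
                     .readTsv(inp$trac, c("gene", "trac", "array")))
        }
    })
    inp <- res$inputs
    utils::write.table(inp$cultivations, file.path(out_dir,
                                                   "cultivations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$correlation <- stage("correlation", function()
        correlateToSppr(inp$experiment))
    utils::write.table(res$correlation, file.path(out_dir,
                                                  "correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$selection <- stage("selection", function()
        selectSignificant(res$correlation, r_cut = config$r_cut_select))
    res$de <- stage("differential_expression", function()
        differentialExpression(inp$experiment, p_cut = config$de_p,
                               lfc_cut = config$de_lfc))
    utils::write.table(res$de, file.path(out_dir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$pairs <- stage("adjacent_pairs", function()
        adjacentQualifyingPairs(inp$annotation, res$correlation,
                                r_cut = config$r_cut_pairs))
    res$permutation <- stage("pair_permutation", function()
        pairPermutationTest(inp$annotation, res$correlation,
                            r_cut = config$r_cut_pairs,
                            n_perm = config$n_perm, seed = config$seed))
    res$clusters <- stage("clusters", function()
        detectClusters(inp$annotation, res$correlation,
                       r_cut = config$r_cut_pairs))
    writeClusters(res$clusters, file.path(out_dir, "clusters.tsv"))
    res$promoters <- stage("promoter_sharing", function()
        promoterSharing(res$pairs, inp$annotation))
    res$characteristics <- stage("characteristics", function()
        geneCharacteristics(inp$annotation, log2Expr(inp$experiment),
                            as.character(conditions(inp$experiment))))
    if (!is.null(inp$network)) {
        res$reporter <- stage("reporter_metabolites", function() {
            ptail <- correlateToSppr(inp$experiment,
                                     alternative = "negative",
                                     qvalues = FALSE)
            pv <- stats::setNames(.clampP(ptail$p), ptail$gene_id)
            pv <- pv[names(pv) %in% networkGenes(inp$network)]
            reporterMetabolites(inp$network, pv,
                                n_background = config$n_background,
                                seed = config$seed)
        })
        utils::write.table(res$reporter,
                           file.path(out_dir, "reporter.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$empath <- stage("empath", function() {
            ptail <- correlateToSppr(inp$experiment,
                                     alternative = "negative",
                                     qvalues = FALSE)
            pv <- stats::setNames(.clampP(ptail$p), ptail$gene_id)
            proj <- geneProjection(inp$network)
            empath(proj, pv, k_min = config$empath_kmin,
                   k_max = config$empath_kmax,
                   n_shuffle = config$n_shuffle,
                   n_colorings = config$empath_ncolorings,
                   seed = config$seed, p_cut = config$empath_pcut)
        })
        utils::write.table(res$empath$candidates,
                           file.path(out_dir, "empath.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(inp$pairs)) {
        res$integration <- stage("integration", function()
            integratePairs(inp$pairs, hi = config$fc_hi,
                           lo = config$fc_lo))
        utils::write.table(res$integration,
                           file.path(out_dir, "integration.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(inp$trac)) {
        res$trac_fit <- stage("trac_fit", function()
            fitTracModels(inp$trac))
    }
    manifest <- list(package = "spprOmics",
                     version = as.character(utils::packageVersion(
                         "spprOmics")),
                     seed = config$seed,
                     parameters = config[setdiff(names(config),
                                                 c("inputs", "synthetic"))],
                     selected_trac_model = res$trac_fit$selected,
                     warnings = warnings)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    invisible(res)
}
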