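test_that("all generators are byte-identical under a fixed seed", {
    spec <- syntheticSpec(seed = 71)
    expect_identical(simulateGenome(spec), simulateGenome(spec))
    ann <- simulateGenome(spec)
    e1 <- simulateExpression(ann, spec)
    e2 <- simulateExpression(ann, spec)
    expect_identical(log2Expr(e1), log2Expr(e2))
    n1 <- simulateNetwork(ann, spec = spec)
    n2 <- simulateNetwork(ann, spec = spec)
    expect_identical(networkEdges(n1$network), networkEdges(n2$network))
    expect_identical(n1$similarity, n2$similarity)
    t1 <- simulateTrac(c("a", "b"), c(1, 2), 0.5, 0.2, seed = 5)
    expect_identical(t1, simulateTrac(c("a", "b"), c(1, 2), 0.5, 0.2,
                                      seed = 5))
    # a different seed draws different noise
    spec2 <- syntheticSpec(seed = 72)
    expect_false(identical(log2Expr(e1),
                           log2Expr(simulateExpression(ann, spec2))))
})

test_that("generated coordinates are sorted, 1-based and non-overlapping", {
    spec <- syntheticSpec(n_scaffolds = 1, genes_per_scaffold = 10,
                          n_planted_pos = 2, n_planted_neg = 2,
                          planted_clusters = data.frame(
                              scaffold = integer(0), start = integer(0),
                              length = integer(0), sign = character(0)),
                          seed = 2)
    ann <- simulateGenome(spec)
    expect_equal(nrow(ann), 10)
    expect_true(all(ann$start >= 1))
    expect_true(all(ann$start <= ann$end))
    expect_true(all(diff(ann$start) > 0))
    expect_true(all(ann$start[-1] > ann$end[-10]))   # no overlap
    expect_equal(ann$length, ann$end - ann$start + 1)
    expect_true(all(ann$dist_to_end >= 0))
    expect_error(syntheticSpec(n_scaffolds = 0), "positive")
})

test_that("planted GC class means are recovered within 3 standard errors", {
    spec <- syntheticSpec(n_scaffolds = 10, genes_per_scaffold = 150,
                          gc_means = c(Fungi = 55, Pezizomycotina = 58,
                                       Trichoderma = 58),
                          gc_sd = 3, seed = 101)
    ann <- simulateGenome(spec)
    for (cls in names(spec@gc_means)) {
        g <- ann$gc[ann$taxonomy == cls]
        se <- 3 / sqrt(length(g))
        expect_lt(abs(mean(g) - spec@gc_means[[cls]]), 3 * se)
    }
})

test_that("planted correlations are realized at their targets", {
    # in the noise -> 0 limit a planted near-1 correlation is realized
    # almost exactly for every gene
    spec0 <- syntheticSpec(noise_sd = 0.001, planted_r = 0.9999, seed = 52,
                           planted_clusters = data.frame(
                               scaffold = integer(0), start = integer(0),
                               length = integer(0), sign = character(0)))
    sim0 <- simulateExperiment(spec0)
    cc0 <- correlateToSppr(sim0$experiment, qvalues = FALSE)
    r0 <- cc0$r[match(names(sim0$planted), cc0$gene_id)]
    expect_gt(min(abs(r0)), 0.99)
    # at a realistic target the sample correlations scatter around it
    # (Fisher z has SD ~ 1/sqrt(n-3) = 0.41 at n = 9, so individual genes
    # vary widely); the sign is still planted and the bulk sits high
    spec <- syntheticSpec(noise_sd = 0.25, planted_r = 0.9, seed = 51)
    sim <- simulateExperiment(spec)
    cc <- correlateToSppr(sim$experiment, qvalues = FALSE)
    planted <- sim$planted
    rPlanted <- cc$r[match(names(planted), cc$gene_id)]
    expect_equal(sign(rPlanted), unname(sign(planted)))
    expect_gt(median(abs(rPlanted)), 0.8)
    zbar <- mean(atanh(abs(rPlanted)))
    se <- 1 / sqrt(6) / sqrt(length(rPlanted))
    # mean Fisher z recovers the planted value (allowing the small-sample
    # bias of order rho/(2(n-1)))
    expect_lt(abs(zbar - atanh(0.9)), 3 * se + 0.1)
})

test_that("null genes reach nominal false-positive rates", {
    spec <- syntheticSpec(n_scaffolds = 10, genes_per_scaffold = 100,
                          n_planted_pos = 0, n_planted_neg = 0,
                          planted_clusters = data.frame(
                              scaffold = integer(0), start = integer(0),
                              length = integer(0), sign = character(0)),
                          seed = 61)
    sim <- simulateExperiment(spec)
    cc <- correlateToSppr(sim$experiment, qvalues = FALSE)
    frac <- mean(cc$p < 0.05)
    se <- sqrt(0.05 * 0.95 / 1000)
    expect_lt(abs(frac - 0.05), 3 * se + 0.005)
})

test_that("cluster genes share the planted correlation sign", {
    spec <- syntheticSpec(noise_sd = 0.1, seed = 81)
    sim <- simulateExperiment(spec)
    cc <- correlateToSppr(sim$experiment, qvalues = FALSE)
    pc <- spec@planted_clusters
    for (i in seq_len(nrow(pc))) {
        genes <- sprintf("s%02dg%03d", pc$scaffold[i],
                         pc$start[i] + seq_len(pc$length[i]) - 1)
        rs <- cc$r[match(genes, cc$gene_id)]
        expect_true(all(sign(rs) == ifelse(pc$sign[i] == "+", 1, -1)))
    }
})

test_that("the planted path is embedded as a gene-metabolite-gene chain", {
    spec <- syntheticSpec(seed = 91)
    ann <- simulateGenome(spec)
    path <- ann$gene_id[c(5, 50, 120, 300)]
    nw <- simulateNetwork(ann, planted_path = path, spec = spec)
    edges <- networkEdges(nw$network)
    for (i in 1:3) {
        shared <- intersect(edges$metabolite[edges$gene == path[i]],
                            edges$metabolite[edges$gene == path[i + 1]])
        expect_gt(length(shared), 0)
    }
    expect_error(simulateNetwork(ann, planted_path = c("nope", path),
                                 spec = spec), "not annotated")
    expect_error(simulateNetwork(ann, n_metabolites = 2,
                                 planted_path = path, spec = spec),
                 "too few metabolites")
})

test_that("network degree parameters are recovered from the edge counts", {
    spec <- syntheticSpec(seed = 93)
    ann <- simulateGenome(spec)
    nw <- simulateNetwork(ann, n_metabolites = 80, spec = spec,
                          n_genes = 400, degree_lambda = 2)
    edges <- networkEdges(nw$network)
    # per-gene degree is 1 + Poisson(2) before de-duplication, so the mean
    # degree must sit just below 3
    deg <- table(edges$gene)
    expect_lt(abs(mean(deg) - 3), 3 * sqrt(2 / 400) + 0.3)
})

test_that("calibration signals follow the exact affine model at sigma 0", {
    tab <- simulateTrac(c("g1", "g2"), alphas = c(1, 2.5), beta = 0.52,
                        sigma = 0, n_samples = 9, seed = 3)
    a <- rep(c(1, 2.5), each = 9)
    expect_equal(tab$array, a + 0.52 * tab$trac)
    expect_error(simulateTrac("g1", c(1, 2), 0.5, 0.2), "length")
})

test_that("proteome generation validates conditions", {
    spec <- syntheticSpec(seed = 95)
    sim <- simulateExperiment(spec)
    expect_error(simulateProteome(sim$experiment, list(c("D03", "XX"))),
                 "unknown condition")
})
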