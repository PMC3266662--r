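test_that("adjacent qualifying pairs respect sign and scaffold bounds", {
    ann <- toyAnnotation(list(c(0.8, 0.9, -0.8)))
    cc <- toyCorrelations(ann, c(0.8, 0.9, -0.8))
    pr <- adjacentQualifyingPairs(ann, cc)
    expect_equal(nrow(pr), 1)
    expect_equal(c(pr$gene1, pr$gene2), c("t1g1", "t1g2"))

    # same correlations split across a scaffold boundary: no pair
    ann2 <- toyAnnotation(list(0.8, c(0.9, -0.8)))
    cc2 <- toyCorrelations(ann2, c(0.8, 0.9, -0.8))
    expect_equal(nrow(adjacentQualifyingPairs(ann2, cc2)), 0)

    expect_error(adjacentQualifyingPairs(
        ann, rbind(cc, data.frame(gene_id = "ghost", r = 0.9))),
        "absent from annotation")
})

test_that("pair detection matches an exhaustive scan on a random genome", {
    set.seed(12)
    for (i in 1:5) {
        r <- round(runif(30, -1, 1), 2)
        ann <- toyAnnotation(split(r, rep(1:3, each = 10)))
        cc <- toyCorrelations(ann, r)
        pr <- adjacentQualifyingPairs(ann, cc, r_cut = 0.6)
        # oracle: scan every consecutive same-scaffold index pair
        expected <- 0
        for (j in seq_len(nrow(ann) - 1)) {
            if (ann$scaffold_id[j] != ann$scaffold_id[j + 1]) next
            if (abs(r[j]) > 0.6 && abs(r[j + 1]) > 0.6 &&
                sign(r[j]) == sign(r[j + 1])) expected <- expected + 1
        }
        expect_equal(nrow(pr), expected)
    }
})

test_that("permutation p is exact-null calibrated on a 6-gene scaffold", {
    r <- c(0.9, 0.85, 0.2, -0.5, 0.75, -0.9)
    ann <- toyAnnotation(list(r))
    cc <- toyCorrelations(ann, r)
    stat <- function(rv) {
        q <- abs(rv) > 0.7
        ok <- q[-6] & q[-1] & sign(rv[-6]) == sign(rv[-1])
        length(unique(c(which(ok), which(ok) + 1)))
    }
    # exact null: every assignment of the 6 values to the 6 positions
    perms <- allPermutations(6)
    nullStats <- vapply(perms, function(p) stat(r[p]), numeric(1))
    obs <- stat(r)
    pExact <- mean(nullStats >= obs)
    res <- pairPermutationTest(ann, cc, n_perm = 10000, seed = 42)
    pHat <- res$p[res$sign == "+"]
    se <- sqrt(pExact * (1 - pExact) / 10000)
    expect_lt(abs(pHat - pExact), 3 * se + 2 / 10000)
})

test_that("degenerate permutation inputs give p = 1", {
    # every gene qualifies with the same sign: all permutations tie
    r <- rep(0.9, 5)
    ann <- toyAnnotation(list(r))
    res <- pairPermutationTest(ann, toyCorrelations(ann, r), n_perm = 50,
                               seed = 1)
    expect_equal(res$p[res$sign == "+"], 1)
    # no gene qualifies: observed 0, p = 1
    r0 <- rep(0.1, 5)
    res0 <- pairPermutationTest(ann, toyCorrelations(ann, r0), n_perm = 50,
                                seed = 1)
    expect_true(all(res0$p == 1))
    expect_error(pairPermutationTest(ann, toyCorrelations(ann, r),
                                     n_perm = 0), "n_perm")
})

test_that("cluster detection follows seed and extension rules exactly", {
    cases <- list(
        list(r = c(0.9, 0.8, 0.75, -0.2),
             want = list(list(sign = "+", genes = 1:3))),
        list(r = c(0.9, 0.8, -0.9, -0.8, -0.75),
             want = list(list(sign = "-", genes = 3:5))),
        list(r = c(0.9, 0.8, 0.75, 0.3, -0.1),
             want = list(list(sign = "+", genes = 1:4))))
    for (cs in cases) {
        ann <- toyAnnotation(list(cs$r))
        cl <- detectClusters(ann, toyCorrelations(ann, cs$r))
        expect_equal(nrow(cl), length(cs$want))
        for (i in seq_along(cs$want)) {
            expect_equal(cl$sign[i], cs$want[[i]]$sign)
            expect_equal(strsplit(cl$genes[i], ";")[[1]],
                         ann$gene_id[cs$want[[i]]$genes])
        }
    }
    # zero correlation terminates extension and never seeds
    r <- c(0.9, 0.8, 0.75, 0, 0.85)
    ann <- toyAnnotation(list(r))
    cl <- detectClusters(ann, toyCorrelations(ann, r))
    expect_equal(strsplit(cl$genes, ";")[[1]], ann$gene_id[1:3])
})

test_that("clusters map onto reversed coordinates when order is flipped", {
    r <- c(0.2, 0.9, 0.8, 0.75, -0.5, 0.3)
    ann <- toyAnnotation(list(r))
    cl <- detectClusters(ann, toyCorrelations(ann, r))
    # reverse gene order on the scaffold (flip coordinates)
    L <- ann$scaffold_length[1]
    annR <- ann
    annR$start <- L - ann$end + 1
    annR$end <- L - ann$start + 1
    clR <- detectClusters(annR, toyCorrelations(ann, r))
    expect_equal(sort(strsplit(cl$genes, ";")[[1]]),
                 sort(strsplit(clR$genes, ";")[[1]]))
    expect_equal(cl$sign, clR$sign)
})

test_that("planted clusters are recovered at near-zero noise", {
    spec <- syntheticSpec(noise_sd = 0.01, seed = 17)
    sim <- simulateExperiment(spec)
    cc <- correlateToSppr(sim$experiment, qvalues = FALSE)
    cl <- detectClusters(sim$annotation, cc)
    pc <- spec@planted_clusters
    for (i in seq_len(nrow(pc))) {
        planted <- sprintf("s%02dg%03d", pc$scaffold[i],
                           pc$start[i] + seq_len(pc$length[i]) - 1)
        hit <- vapply(strsplit(cl$genes, ";"), function(g)
            all(planted %in% g), logical(1))
        expect_true(any(hit & cl$sign == pc$sign[i]),
                    label = paste("planted cluster", i, "recovered"))
    }
    # every reported cluster passes its own invariants
    for (j in seq_len(nrow(cl))) {
        genes <- strsplit(cl$genes[j], ";")[[1]]
        seed3 <- strsplit(cl$seed_triplet[j], ";")[[1]]
        expect_length(seed3, 3)
        expect_true(all(seed3 %in% genes))
        rs <- cc$r[match(seed3, cc$gene_id)]
        expect_true(all(abs(rs) > 0.7))
        expect_true(all(sign(rs) == ifelse(cl$sign[j] == "+", 1, -1)))
        idx <- match(genes, sim$annotation$gene_id)
        expect_true(all(diff(idx) == 1))  # chromosomally consecutive
    }
})

test_that("promoter sharing requires divergent orientation within the gap", {
    ann <- data.frame(
        gene_id = c("a", "b", "c", "d", "e", "f"),
        scaffold_id = "s", strand = c("-", "+", "+", "+", "-", "+"),
        start = c(1000, 2500, 6000, 7500, 11000, 14000),
        end = c(1700, 3200, 6700, 8200, 12500, 14700),
        stringsAsFactors = FALSE)
    pairs <- data.frame(gene1 = c("a", "c", "e"), gene2 = c("b", "d", "f"))
    res <- promoterSharing(pairs, ann, max_gap = 1000)
    # (a,b): (-,+) starts 1700 vs 2500 -> 800 apart, counted twice
    # (c,d): (+,+) tandem -> excluded; (e,f): (-,+) 1500 apart -> divergent only
    expect_equal(res$divergent, 2)
    expect_equal(res$within_gap, 1)
    expect_equal(res$detail$separation[1], 800)
    annBad <- ann; annBad$strand[1] <- "."
    expect_error(promoterSharing(pairs, annBad), "strand")
})

test_that("gene characteristics equal direct recomputation", {
    spec <- syntheticSpec(n_scaffolds = 2, genes_per_scaffold = 20,
                          n_planted_pos = 3, n_planted_neg = 3,
                          planted_clusters = data.frame(
                              scaffold = integer(0), start = integer(0),
                              length = integer(0), sign = character(0)),
                          seed = 5)
    sim <- simulateExperiment(spec)
    expr <- log2Expr(sim$experiment)
    cond <- as.character(conditions(sim$experiment))
    ch <- geneCharacteristics(sim$annotation, expr, cond)
    g <- ch$gene_id[7]
    expect_equal(ch$max_expr[7], max(expr[g, ]))
    ms <- tapply(expr[g, ], cond, mean)
    expect_equal(ch$max_abs_log2FC[7],
                 max(abs(c(ms[1] - ms[2], ms[1] - ms[3], ms[2] - ms[3]))))
    # constant expression: max = value, fold change 0
    expr2 <- expr; expr2[g, ] <- 8
    ch2 <- geneCharacteristics(sim$annotation, expr2, cond)
    expect_equal(ch2$max_expr[7], 8)
    expect_equal(ch2$max_abs_log2FC[7], 0)
    # gene at the very start of a scaffold has distance 0 to the end
    ann <- sim$annotation
    ann$start[1] <- 1; ann$end[1] <- 100
    ch3 <- geneCharacteristics(ann, expr, cond)
    expect_equal(ch3$dist_to_end[ch3$gene_id == ann$gene_id[1]], 0)
})

test_that("characteristic comparison recovers a planted mean shift", {
    set.seed(23)
    tab <- data.frame(gene_id = sprintf("g%03d", 1:400),
                      gc = c(rnorm(200, 57, 1), rnorm(200, 55, 1)))
    res <- compareCharacteristics(tab, tab$gene_id[1:200],
                                  tab$gene_id[201:400], "gc")
    expect_lt(abs(res$estimate - 2), 3 * sqrt(2 / 200))
    expect_lt(res$p.value, 1e-6)
    # identical values give coefficient 0 (perfect-fit warning expected)
    tab0 <- transform(tab, gc = 5)
    expect_equal(suppressWarnings(
        compareCharacteristics(tab0, tab$gene_id[1:200],
                               tab$gene_id[201:400], "gc")$estimate), 0)
    expect_error(compareCharacteristics(tab, tab$gene_id[1:10],
                                        tab$gene_id[5:20], "gc"), "overlap")
    expect_error(compareCharacteristics(tab, tab$gene_id[1],
                                        tab$gene_id[2], "gc"), "few genes")
})
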