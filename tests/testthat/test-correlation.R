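test_that("per-gene correlation matches the covariance formula", {
    sppr <- c(3.0, 2.6, 3.4, 1.5, 1.4, 1.6, 0.8, 0.7, 0.9)
    set.seed(4)
    expr <- rbind(prop = 2 * sppr + 5,
                  anti = -sppr,
                  rand = rnorm(9))
    cc <- correlateToSppr(expr, sppr = sppr)
    expect_equal(cc$r[cc$gene_id == "prop"], 1)
    expect_equal(cc$r[cc$gene_id == "anti"], -1)
    # brute-force covariance formula on the random gene
    y <- expr["rand", ]
    rOracle <- sum((y - mean(y)) * (sppr - mean(sppr))) /
        sqrt(sum((y - mean(y))^2) * sum((sppr - mean(sppr))^2))
    expect_equal(cc$r[cc$gene_id == "rand"], rOracle)
    tOracle <- rOracle * sqrt(7) / sqrt(1 - rOracle^2)
    expect_equal(cc$p[cc$gene_id == "rand"], 2 * pt(-abs(tOracle), 7))
})

test_that("three-point anti-correlation and input validation", {
    m <- matrix(c(1, 2, 3), 1, dimnames = list("g", c("a", "b", "c")))
    cc <- correlateToSppr(m, sppr = c(3, 2, 1), qvalues = FALSE)
    expect_equal(cc$r, -1)
    expect_error(correlateToSppr(m[, 1:2, drop = FALSE], sppr = c(1, 2)),
                 "3 samples")
    expect_error(correlateToSppr(m, sppr = c(a = 1, b = 2, d = 3)),
                 "sample ids")
})

test_that("correlation is invariant to a common sample permutation", {
    set.seed(9)
    expr <- matrix(rnorm(50 * 9), 50, 9,
                   dimnames = list(sprintf("g%02d", 1:50), letters[1:9]))
    sppr <- runif(9, 0.5, 3.5); names(sppr) <- letters[1:9]
    cc1 <- correlateToSppr(expr, sppr = sppr, qvalues = FALSE)
    perm <- sample(9)
    cc2 <- correlateToSppr(expr[, perm], sppr = sppr[perm], qvalues = FALSE)
    expect_equal(cc1$r, cc2$r)
})

test_that("zero-variance genes are excluded from the q-value input", {
    expr <- rbind(flat = rep(8, 9), ok = rnorm(9))
    colnames(expr) <- letters[1:9]
    cc <- correlateToSppr(expr, sppr = 1:9)
    expect_true(is.na(cc$r[cc$gene_id == "flat"]))
    expect_false(is.na(cc$q[cc$gene_id == "ok"]))
})

test_that("q-values reproduce the single-lambda Storey formula", {
    p <- c(0.001, 0.01, 0.5, 0.9)
    qv <- estimateQvalues(p, lambda = 0.5)
    # hand computation: pi0 = #{p > 0.5}/(m * 0.5) = 1/2
    expect_equal(qv$pi0, 0.5)
    m <- 4
    raw <- qv$pi0 * m * sort(p) / seq_len(m)
    oracle <- rev(cummin(rev(raw)))[match(p, sort(p))]
    expect_equal(qv$q, oracle)

    allOne <- estimateQvalues(rep(1, 10), lambda = 0.5)
    expect_true(all(allOne$q == 1))
    expect_error(estimateQvalues(c(0.5, 1.2)), "0,1")
})

test_that("q-values are monotone in the ordered p-values", {
    set.seed(2)
    for (i in 1:5) {
        p <- runif(200)
        q <- estimateQvalues(p)$q
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-12))
        expect_true(all(q >= 0 & q <= 1))
    }
})

test_that("selection partitions by sign and validates the cut", {
    rec <- data.frame(gene_id = c("g1", "g2", "g3"),
                      r = c(0.85, -0.9, 0.5), p = 0.01, q = 0.02, n = 9)
    sel <- selectSignificant(rec, 0.8)
    expect_equal(sel$positive, "g1")
    expect_equal(sel$negative, "g2")
    expect_equal(sel$fdr, 0.02)
    expect_error(selectSignificant(rec, 1.0), "between 0 and 1")
    expect_error(selectSignificant(rec, 0), "between 0 and 1")
})

test_that("null genes are selected at the exact t-tail rate", {
    # P(|r| > 0.8) for a null gene at n = 9 from the t transform
    pTheory <- 2 * pt(-0.8 * sqrt(7) / sqrt(1 - 0.64), 7)
    hits <- 0; total <- 0
    for (s in 1:20) {
        set.seed(100 + s)
        expr <- matrix(rnorm(100 * 9), 100, 9,
                       dimnames = list(sprintf("g%03d", 1:100), NULL))
        cc <- correlateToSppr(expr, sppr = runif(9, 0.5, 3.5),
                              qvalues = FALSE)
        sel <- selectSignificant(cc, 0.8)
        hits <- hits + length(sel$positive) + length(sel$negative)
        total <- total + 100
    }
    se <- sqrt(pTheory * (1 - pTheory) / total)
    expect_lt(abs(hits / total - pTheory), 3 * se + 1e-3)
})

test_that("excluding a correlation-attenuating sample raises the count", {
    sppr <- c(3.0, 2.6, 3.4, 1.5, 1.4, 1.6, 0.8, 0.7, 0.9)
    names(sppr) <- sprintf("s%d", 1:9)
    set.seed(7)
    expr <- t(replicate(20, 0.8 * sppr + rnorm(9, 0, 0.2)))
    # sample s9 measured badly: signal replaced by noise, attenuating r
    expr[, 9] <- rnorm(20, mean(expr), 2)
    rownames(expr) <- sprintf("g%02d", 1:20)
    colnames(expr) <- names(sppr)
    res <- exclusionSensitivity(expr, "s9", sppr = sppr, r_cut = 0.8)
    expect_gt(res$count_excluded, res$count_full)
    expect_gt(res$relative_change, 0)

    # round trip: excluding then restoring changes nothing
    again <- exclusionSensitivity(expr, "s9", sppr = sppr, r_cut = 0.8)
    expect_identical(res, again)
    expect_error(exclusionSensitivity(expr, "nope", sppr = sppr), "unknown")
    expect_error(exclusionSensitivity(expr[, 1:3], "s1", sppr = sppr[1:3]),
                 "fewer than 3")
})

test_that("unmoderated differential expression equals the pooled t-test", {
    set.seed(5)
    expr <- matrix(rnorm(30 * 6), 30, 6,
                   dimnames = list(sprintf("g%02d", 1:30), NULL))
    cond <- rep(c("A", "B"), each = 3)
    de <- differentialExpression(expr, condition = cond, moderate = FALSE)
    for (i in c(1, 17, 30)) {
        tt <- t.test(expr[i, 1:3], expr[i, 4:6], var.equal = TRUE)
        expect_equal(de$log2FC[i], unname(diff(rev(tt$estimate))))
        expect_equal(de$p[i], tt$p.value)
    }
    same <- matrix(rep(c(1, 2, 3), each = 6), 3, 6, byrow = TRUE)
    rownames(same) <- c("a", "b", "c")
    de0 <- differentialExpression(same, condition = cond, moderate = FALSE)
    expect_equal(de0$log2FC, rep(0, 3))
    expect_error(differentialExpression(expr[, 1:4],
                                        condition = c("A", "A", "A", "B")),
                 "replicates")
})

test_that("moderated fold changes agree with limma and power is adequate", {
    skip_if_not_installed("limma")
    set.seed(21)
    n <- 1000
    expr <- matrix(rnorm(n * 6, 8, 0.3), n, 6,
                   dimnames = list(sprintf("g%04d", 1:n), NULL))
    de_idx <- 1:50
    expr[de_idx, 1:3] <- expr[de_idx, 1:3] + 1.5
    cond <- rep(c("A", "B"), each = 3)
    de <- differentialExpression(expr, condition = cond)
    design <- cbind(1, cond == "A")
    fit <- limma::eBayes(limma::lmFit(expr, design))
    expect_equal(de$log2FC, unname(fit$coefficients[, 2]))
    # same genes lead the ranking under both moderation schemes
    expect_gt(cor(-log10(de$p), -log10(fit$p.value[, 2])), 0.98)
    # planted effect of 1.5 log2 units at sd 0.3: nearly all detected
    expect_gte(mean(de$significant[de_idx]), 0.9)
    expect_lt(mean(de$significant[-de_idx]), 0.01)
})

test_that("q-value FDR is calibrated on all-null data", {
    set.seed(31)
    fp <- 0; called <- 0
    for (i in 1:10) {
        expr <- matrix(rnorm(500 * 9), 500, 9,
                       dimnames = list(sprintf("g%03d", 1:500), NULL))
        cc <- correlateToSppr(expr, sppr = runif(9, 0.5, 3.5))
        called <- called + sum(cc$q < 0.05, na.rm = TRUE)
    }
    # with no signal anywhere, any q < 0.05 call is a false positive;
    # expected count per run is at most 0.05 * (expected discoveries),
    # so across runs calls must stay rare
    expect_lt(called / 10, 2)
})
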