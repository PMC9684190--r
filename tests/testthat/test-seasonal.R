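test_that("the threshold chain derives from the analytic average", {
    th <- deriveThresholds(2625)
    expect_equal(round(averageTPM(th)), 381)
    expect_equal(similarityThreshold(th), 38)
    expect_equal(combinedThreshold(th), 76)
    expect_equal(highThreshold(th), 571)
    expect_equal(minFold(th), 1.5)

    th2 <- deriveThresholds(1000)
    expect_equal(c(averageTPM(th2), similarityThreshold(th2),
                   combinedThreshold(th2), highThreshold(th2)),
                 c(1000, 100, 200, 1500))
    th3 <- deriveThresholds(4000)
    expect_equal(c(averageTPM(th3), similarityThreshold(th3),
                   combinedThreshold(th3), highThreshold(th3)),
                 c(250, 25, 50, 375))
})

test_that("fold change is symmetric, pseudocounted and >= 1", {
    expect_equal(foldChange(100, 200, pseudo = 0), 2)
    expect_equal(foldChange(200, 100, pseudo = 0), 2)
    for (x in c(0, 1, 57.3, 1e4))
        expect_equal(foldChange(x, x), 1)
    expect_equal(foldChange(0, 99), 100)  # (99+1)/(0+1)
    expect_error(foldChange(-1, 5), "non-negative")
})

test_that("gene classification applies the direction and significance rules", {
    th <- deriveThresholds(2625)
    c1 <- classifyGene(100, 200, th)
    expect_equal(c1$direction, "higher_b")
    expect_true(c1$significant)  # combined 300 >= 76, fold ~1.99 >= 1.5

    c2 <- classifyGene(400, 420, th)
    expect_equal(c2$direction, "similar")  # diff 20 < 38
    expect_false(c2$significant)

    c3 <- classifyGene(10, 60, th)
    expect_equal(c3$direction, "higher_b")
    expect_false(c3$significant)  # combined 70 < 76

    # the paper-style boundary: a raw TPM ratio of exactly 1.5 passes
    # with pseudo = 0 but the pseudocount shrinks it below threshold
    expect_true(classifyGene(300, 200, th, pseudo = 0)$significant)
    expect_false(classifyGene(300, 200, th, pseudo = 1)$significant)

    expect_error(classifyGene(-5, 10, th), "negative")
})

test_that("classifyAll tallies partition the gene set", {
    th <- deriveThresholds(2625)
    x <- tpmExperiment(matrix(c(100, 400, 10, 200, 420, 60), 3, 2,
        dimnames = list(c("g1", "g2", "g3"), c("a", "b"))))
    calls <- classifyAll(x, "a", "b", th)
    expect_equal(unname(callTallies(calls)), c(1, 0, 2, 1, 0, 1))

    # all genes identical -> everything similar
    m <- matrix(rep(c(50, 500, 5000), 2), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
    expect_equal(unname(callTallies(classifyAll(tpmExperiment(m), "a", "b",
                                                th))),
                 c(3, 0, 0, 0, 0, 0))
})

test_that("classification is a partition, symmetric and fold-monotone", {
    set.seed(7)
    n <- 150
    m <- matrix(rexp(2 * n, rate = 1 / 400), n, 2,
                dimnames = list(sprintf("g%03d", seq_len(n)), c("a", "b")))
    x <- tpmExperiment(m)
    th <- deriveThresholds(n)
    calls <- classifyAll(x, "a", "b", th)
    tl <- callTallies(calls)
    expect_equal(tl[["n_similar"]] + tl[["n_higher_a"]] +
                 tl[["n_higher_b"]], n)
    expect_equal(tl[["n_sig"]], tl[["n_sig_a"]] + tl[["n_sig_b"]])

    # swapping samples swaps directions, keeps similar/significant/fold
    rev <- classifyAll(x, "b", "a", th)
    expect_equal(callTallies(rev)[["n_higher_a"]], tl[["n_higher_b"]])
    expect_equal(callTallies(rev)[["n_higher_b"]], tl[["n_higher_a"]])
    expect_equal(callTable(rev)$fold, callTable(calls)$fold)
    expect_equal(callTable(rev)$significant, callTable(calls)$significant)

    # significant set shrinks as foldMin grows
    nsig <- vapply(c(1.2, 1.5, 2, 3), function(fm)
        callTallies(classifyAll(x, "a", "b",
            deriveThresholds(n, foldMin = fm)))[["n_sig"]], numeric(1))
    expect_true(all(diff(nsig) <= 0))
    # significant is a subset of non-similar
    cc <- callTable(calls)
    expect_true(all(cc$direction[cc$significant] != "similar"))
})

test_that("classification is invariant under per-sample count rescaling", {
    set.seed(21)
    n <- 60
    cts <- matrix(rpois(2 * n, 80) + 1, n, 2,
                  dimnames = list(sprintf("g%03d", seq_len(n)),
                                  c("a", "b")))
    len <- sample(300:3000, n)
    x1 <- computeTPM(countExperiment(cts, lengths = len))
    cts2 <- cts; cts2[, "a"] <- cts2[, "a"] * 7; cts2[, "b"] <- cts2[, "b"] * 3
    x2 <- computeTPM(countExperiment(cts2, lengths = len))
    th <- deriveThresholds(n)
    expect_equal(callTable(classifyAll(x2, "a", "b", th)),
                 callTable(classifyAll(x1, "a", "b", th)),
                 tolerance = 1e-9)
})

test_that("high-expression sets use an inclusive threshold", {
    th <- deriveThresholds(2625)  # H = 571
    x <- tpmExperiment(matrix(c(571, 570, 600, 100), 2, 2,
        dimnames = list(c("g1", "g2"), c("a", "b"))))
    hi <- highExpressionSets(x, c("a", "b"), th)
    expect_equal(hi$sets$a, "g1")       # 571 is in, 570 is out
    expect_equal(hi$sets$b, "g1")
    expect_equal(hi$intersection, "g1")

    # disjoint constructed sets intersect empty
    x2 <- tpmExperiment(matrix(c(600, 10, 10, 600), 2, 2,
        dimnames = list(c("g1", "g2"), c("a", "b"))))
    expect_length(highExpressionSets(x2, c("a", "b"), th)$intersection, 0L)

    # planted 30-gene shared high set is recovered exactly
    n <- 100
    m <- matrix(50, n, 2, dimnames = list(sprintf("g%03d", seq_len(n)),
                                          c("a", "b")))
    shared <- sprintf("g%03d", 1:30)
    m[shared, ] <- 700
    hi3 <- highExpressionSets(tpmExperiment(m), c("a", "b"), th)
    expect_equal(sort(hi3$intersection), shared)
})

test_that("unexpressed genes are those with zero TPM", {
    x <- tpmExperiment(matrix(c(0, 5, 0, 0, 8, 0), 3, 2,
        dimnames = list(c("g1", "g2", "g3"), c("a", "b"))))
    un <- unexpressedSets(x, c("a", "b"))
    expect_equal(un$sets$a, c("g1", "g3"))
    expect_equal(un$sets$b, c("g1", "g3"))
    expect_equal(un$intersection, c("g1", "g3"))
})

test_that("top-N ranking is deterministic under ties", {
    tp <- c(g2 = 500, g1 = 500, g3 = 900, g4 = 10)
    top <- topExpressed(tp, n = 3)
    expect_equal(top$gene_id, c("g3", "g1", "g2"))  # tie: id ascending
    expect_equal(top$tpm[1], 900)
    expect_error(topExpressed(tp, n = 5), "exceeds")
    # n = n_genes is a permutation of all genes
    expect_setequal(topExpressed(tp, n = 4)$gene_id, names(tp))
})

test_that("top-N overlap counts shared gene ids", {
    a <- data.frame(gene_id = c("g1", "g2", "g3"), tpm = 3:1)
    expect_equal(topOverlap(a, a)$n, 3)
    b <- data.frame(gene_id = c("g9", "g8"), tpm = 2:1)
    expect_equal(topOverlap(a, b)$n, 0)
    expect_equal(topOverlap(a, c("g2", "g3", "g7"))$shared, c("g2", "g3"))
})

test_that("the published top-25 tables overlap in nine genes", {
    t2 <- readExpressionTable(extfile("table2_summer_top25.tsv"))
    t3 <- readExpressionTable(extfile("table3_winter_top25.tsv"))
    expect_equal(nrow(t2), 25L)
    expect_equal(nrow(t3), 25L)
    top <- topExpressed(stats::setNames(t2$tpm, t2$gene_id), n = 25)
    expect_equal(top$gene_id[1], "HQ_RS01075")
    expect_equal(top$tpm[1], 2380)
    expect_equal(topOverlap(t2, t3)$n, 9)
})
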