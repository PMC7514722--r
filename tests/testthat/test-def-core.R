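test_that("defValue reproduces the worked entropy examples", {
    # profile (1,2,3): proportions (1/6, 2/6, 3/6), H = 0.079 to 3 d.p.
    expect_equal(round(defValue(c(1, 2, 3)), 3), 0.079)
    expect_equal(defValue(c(1, 2, 3)), oracleH(c(1, 2, 3)), tolerance = 1e-12)

    # uniform profiles score exactly zero for any n
    for (n in c(2, 3, 4, 10))
        expect_equal(defValue(rep(1, n)), 0)
    expect_equal(defValue(rep(3.7, 5)), 0)

    # two-sample profile (3,1): frozen from the scalar formula with p =
    # (0.75, 0.25): H = 1 - 0.5623351/0.6931472
    expect_equal(defValue(c(3, 1)), 0.1887219, tolerance = 1e-6)
    expect_equal(defValue(c(3, 1)), oracleH(c(3, 1)), tolerance = 1e-12)

    # all expression in one sample: maximal score
    for (c0 in c(1, 5, 1e6))
        expect_equal(defValue(c(c0, 0, 0)), 1)

    # degenerate all-zero profile scores 0 (such genes are filtered anyway)
    expect_equal(defValue(c(0, 0, 0)), 0)
})

test_that("defValue rejects invalid profiles with named errors", {
    expect_error(defValue(5), class = "defSingleSample")
    expect_error(defValue(numeric(0)), class = "defSingleSample")
    expect_error(defValue(c(1, -1)), class = "defNegativeValues")
    expect_error(defValue(c(1, NA)), class = "defNegativeValues")
})

test_that("the statistic is log-base, permutation, and scale invariant", {
    set.seed(42)
    for (i in 1:50) {
        n <- sample(2:12, 1)
        v <- stats::runif(n, 0, 10)
        v[sample(n, sample(0:(n - 1), 1))] <- 0
        hNat <- defValue(v)
        expect_equal(defValue(v, base = 2), hNat, tolerance = 1e-12)
        expect_equal(defValue(v, base = 10), hNat, tolerance = 1e-12)
        expect_equal(defValue(sample(v)), hNat, tolerance = 1e-12)
        expect_equal(defValue(v * stats::runif(1, 0.01, 100)), hNat,
                     tolerance = 1e-12)
        expect_gte(hNat, 0)
        expect_lte(hNat, 1)
    }
})

test_that("two-sample score grows strictly with imbalance", {
    ps <- seq(0.5, 0.99, by = 0.01)
    hs <- vapply(ps, function(p) defValue(c(p, 1 - p) * 10), numeric(1))
    expect_true(all(diff(hs) > 0))
    # and symmetrically below 1/2
    expect_equal(defValue(c(0.2, 0.8)), defValue(c(0.8, 0.2)))
})

test_that("defAll matches a per-gene scalar loop and preserves order", {
    set.seed(7)
    for (i in 1:20) {
        m <- sample(1:30, 1); n <- sample(2:8, 1)
        x <- matrix(stats::runif(m * n, 0, 5), m)
        x[sample(length(x), length(x) %/% 4)] <- 0
        rownames(x) <- paste0("g", seq_len(m))
        h <- defAll(x)
        loop <- vapply(seq_len(m), function(i) defValue(x[i, ]), numeric(1))
        expect_equal(unname(h), loop, tolerance = 1e-12)
        expect_identical(names(h), rownames(x))
    }
    expect_length(defAll(matrix(numeric(0), 0, 4)), 0)
})

test_that("defAll on the two worked profiles gives (0, 0.079)", {
    x <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
    h <- defAll(x)
    expect_equal(unname(round(h, 3)), c(0, 0.079))
})

test_that("ranking is stable under ties and ranks are a permutation", {
    # tied values keep input order, as in reported tables where several
    # genes share the same printed score
    h <- c(gA = 0.0617, gB = 0.0608, gC = 0.0608, gD = 0.0608, gE = 0.0581)
    rt <- rankGenes(h)
    expect_identical(rt$rank, 1:5)
    expect_identical(rt$gene_id, names(h))

    set.seed(11)
    h2 <- stats::setNames(stats::runif(40), paste0("g", 1:40))
    rt2 <- rankGenes(h2)
    expect_setequal(rt2$rank, seq_along(h2))
    # rank order consistent with nonincreasing score
    expect_true(all(diff(rt2$def_value[order(rt2$rank)]) <= 0))
    # distinct values: (gene, rank) pairs do not depend on input order
    rt2r <- rankGenes(rev(h2))
    expect_identical(rt2$rank[match(rt2r$gene_id, rt2$gene_id)], rt2r$rank)

    expect_identical(rankGenes(c(only = 0.3))$rank, 1L)
})

test_that("DE calls use a strict threshold and respond to lowering it", {
    h <- c(top = 0.0617, borderline = 0.0101, at = 0.05)
    r05 <- callDE(h, 0.05)
    expect_identical(unname(r05$de_call), c(TRUE, FALSE, FALSE))
    r01 <- callDE(h, 0.01)
    expect_identical(unname(r01$de_call), c(TRUE, TRUE, TRUE))
    # lowering the cut-off can only add calls
    expect_true(all(r01$de_call >= r05$de_call))
    expect_identical(S4Vectors::metadata(r05)$threshold, 0.05)

    expect_error(callDE(h, 0), class = "defBadThreshold")
    expect_error(callDE(h, 1), class = "defBadThreshold")
    expect_error(callDE(h, 1.5), class = "defBadThreshold")
})

test_that("topK returns gene ids in rank order and caps at m", {
    h <- c(flat = 0, varied = 0.079)
    expect_identical(topK(h, 1), "varied")
    expect_identical(topK(h, 5), c("varied", "flat"))
    h5 <- c(a = 0.0617, b = 0.0608, c = 0.0608, d = 0.0608, e = 0.0581)
    expect_identical(topK(h5, 5), c("a", "b", "c", "d", "e"))
})

test_that("runDEF wires filter, normalization, scoring and calling", {
    # the flat gene sets a realistic library depth near the top of its
    # decade, where a handful of reads in one sample is a strong signal
    cnt <- rbind(allzero = c(0L, 0L, 0L, 0L),
                 onehit  = c(5L, 0L, 0L, 0L),
                 flat    = c(600000L, 600000L, 600000L, 600000L))
    colnames(cnt) <- paste0("s", 1:4)
    res <- runDEF(makeCounts(cnt), threshold = 0.05)
    expect_identical(res$gene_id, c("onehit", "flat"))
    expect_identical(S4Vectors::metadata(res)$removedGenes, "allzero")
    expect_identical(res$rank, 1:2)
    expect_true(res$de_call[res$gene_id == "onehit"])
    expect_false(res$de_call[res$gene_id == "flat"])

    # all genes zero: empty result, everything in removedGenes
    z <- makeCounts(matrix(0L, 3, 4))
    rz <- runDEF(z)
    expect_identical(nrow(rz), 0L)
    expect_length(S4Vectors::metadata(rz)$removedGenes, 3)
})
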