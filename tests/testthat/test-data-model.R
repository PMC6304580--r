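test_that("labeled matrix dialect reads identifiers and binary entries", {
    path <- writeTempTSV(c("drug\tt1\tt2", "d1\t1\t0", "d2\t0\t1"))
    ds <- readInteractions(path, dialect = "matrix")
    expect_identical(drugIds(ds), c("d1", "d2"))
    expect_identical(targetIds(ds), c("t1", "t2"))
    expect_equal(unname(interactions(ds)), diag(2))
    expect_equal(observedPairs(ds), cbind(1:2, 1:2))
})

test_that("matrix dialect rejects malformed files with located errors", {
    bad <- writeTempTSV(c("drug\tt1\tt2", "d1\t1\t2", "d2\t0\t1"))
    expect_error(readInteractions(bad), "d1.*t2")
    conflict <- writeTempTSV(c("drug\tt1", "d1\t1", "d1\t0"))
    expect_error(readInteractions(conflict), "conflicting")
    empty <- tempfile(); file.create(empty)
    expect_error(readInteractions(empty), "empty")
})

test_that("pair list collapses duplicates and preserves first-seen order", {
    path <- writeTempTSV(c("dB,tX", "dA,tY", "dB,tX"))
    ds <- readInteractions(path, dialect = "pairs")
    expect_identical(drugIds(ds), c("dB", "dA"))
    expect_identical(targetIds(ds), c("tX", "tY"))
    expect_equal(sum(interactions(ds)), 2)
})

test_that("read-write-read round-trips a generated table exactly", {
    set.seed(42)
    M <- matrix(0, 54, 26)
    M[sample(length(M), 90)] <- 1
    dimnames(M) <- list(sprintf("D%02d", 1:54), sprintf("T%02d", 1:26))
    ds <- DTIData(M)
    p1 <- tempfile(); p2 <- tempfile()
    writeInteractions(ds, p1)
    ds2 <- readInteractions(p1)
    writeInteractions(ds2, p2)
    ds3 <- readInteractions(p2)
    expect_identical(interactions(ds3), interactions(ds))
    expect_identical(drugIds(ds3), drugIds(ds))
})

test_that("similarity reader symmetrizes, clips and reindexes", {
    path <- writeTempTSV(c("id\ta\tb", "a\t1\t0.4", "b\t0.6\t1"))
    S <- readSimilarity(path, c("a", "b"))
    expect_equal(S["a", "b"], 0.5)
    expect_equal(S["b", "a"], 0.5)

    ## permuted expected order equals per-cell double-indexed lookup
    set.seed(3)
    n <- 5
    ids <- letters[1:n]
    S0 <- randomWeights(n)
    dimnames(S0) <- list(ids, ids)
    path <- tempfile()
    writeSimilarity(S0, path)
    want <- rev(ids)
    S1 <- readSimilarity(path, want)
    for (i in seq_len(n)) for (j in seq_len(n))
        expect_equal(S1[i, j], S0[want[i], want[j]])

    ## idempotent on an already-conformant matrix
    S2 <- readSimilarity(path, ids)
    p2 <- tempfile()
    writeSimilarity(S2, p2)
    expect_equal(readSimilarity(p2, ids), S2)

    expect_error(readSimilarity(path, c(ids, "zz")), "zz")
})

test_that("similarity reader rejects NaN cells", {
    path <- writeTempTSV(c("id\ta\tb", "a\t1\tNaN", "b\t0.5\t1"))
    expect_error(readSimilarity(path, c("a", "b")), "NaN|NA")
})

test_that("dataset statistics reproduce the benchmark-style summaries", {
    set.seed(1)
    M <- matrix(0, 54, 26)
    M[sample(length(M), 90)] <- 1
    st <- datasetStats(DTIData(M))
    expect_equal(st$sparsity, 93.59)
    expect_equal(st$drugsPerTarget, 3.46)
    expect_equal(st$targetsPerDrug, 1.67)

    st0 <- datasetStats(DTIData(matrix(0, 4, 3)))
    expect_equal(st0$sparsity, 100)
    expect_equal(st0$drugsPerTarget, 0)
    expect_equal(st0$pctDrugsOneInteraction, 0)

    expect_error(datasetStats(DTIData(matrix(0, 0, 0))), "no drugs")
})

test_that("DTIData validity enforces the similarity contract", {
    M <- matrix(c(1, 0, 0, 1), 2, 2)
    expect_error(DTIData(M * 2), "0 or 1")
    S <- matrix(c(1, 0.7, 0.2, 1), 2, 2)  # asymmetric
    expect_error(DTIData(M, drugSim = S), "symmetric")
    S2 <- matrix(c(0.9, 0.2, 0.2, 1), 2, 2)  # diagonal != 1
    expect_error(DTIData(M, drugSim = S2), "diagonal")
})
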