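# builds a normalized expression matrix whose log2(x+1) rows have a chosen
# exact correlation structure, for boundary tests of the pair criteria
exprWithLogCor <- function(ids, base, compartment, samples) {
    v <- 2^base - 1
    rownames(v) <- ids
    colnames(v) <- samples
    ExpressionMatrix(pmax(v, 0), compartment, isNormalized = TRUE)
}

test_that("pairs require a shared miRNA and the exact stated criteria", {
    samples <- sprintf("t%02d", 1:40)
    set.seed(8)
    xl <- rnorm(40, 8, 1)
    strong <- 8 + pairWithCorrelation(xl, 0.9, seed = 2)
    border <- 8 + pairWithCorrelation(xl, 0.39, seed = 3)
    exprLnc <- exprWithLogCor("L1", rbind(xl), "lncRNA", samples)
    exprMrna <- exprWithLogCor(c("R1", "R2", "R3"),
                               rbind(strong, border, rnorm(40, 8, 1)),
                               "mRNA", samples)
    # verify the construction: exact r on the log2(x+1) scale
    lv <- log2(exprValues(exprLnc) + 1); mv <- log2(exprValues(exprMrna) + 1)
    expect_equal(cor(lv["L1", ], mv["R2", ]), 0.39, tolerance = 1e-10)

    mirs <- sprintf("mir%02d", 1:30)
    edges <- rbind(
        data.frame(mirna_id = mirs[1:4], target_id = "L1",
                   target_compartment = "lncRNA"),
        data.frame(mirna_id = mirs[1:4], target_id = "R1",
                   target_compartment = "mRNA"),
        data.frame(mirna_id = mirs[1:4], target_id = "R2",
                   target_compartment = "mRNA"),
        data.frame(mirna_id = mirs[5:8], target_id = "R3",
                   target_compartment = "mRNA"))
    pairs <- findCernaPairs("L1", c("R1", "R2", "R3"), mirs, edges,
                            exprLnc, exprMrna, samples)
    # R3 shares no miRNA with L1: no candidate emitted
    expect_false("R3" %in% pairs$mrna_id)
    expect_equal(nrow(pairs), 2L)
    p1 <- pairs[pairs$mrna_id == "R1", ]
    expect_equal(p1$c, 4L)
    # the universe is the differential miRNAs present in the edge table
    expect_equal(p1$N, 8L)
    expect_equal(p1$hyper_p,
                 phyper(3, 4, 8 - 4, 4, lower.tail = FALSE), tolerance = 1e-12)
    expect_true(p1$passed)
    # r = 0.39 fails the >= 0.4 criterion regardless of the enrichment p
    p2 <- pairs[pairs$mrna_id == "R2", ]
    expect_lt(p2$hyper_p, 0.05)
    expect_false(p2$passed)
})

test_that("pair p-value is symmetric in the two target-set sizes", {
    for (seed in 1:10) {
        set.seed(seed)
        N <- sample(10:50, 1)
        K <- sample.int(N, 1)
        n <- sample.int(N, 1)
        c <- sample.int(min(K, n), 1)
        expect_equal(hypergeomSharedMirnaP(N, K, n, c)$p.value,
                     hypergeomSharedMirnaP(N, n, K, c)$p.value,
                     tolerance = 1e-15)
    }
})

test_that("triples expand per shared miRNA and carry DE directions", {
    pairs <- data.frame(
        lncrna_id = "L1", mrna_id = "R1",
        shared_mirnas = "m1;m2;m3", K = 3L, n = 3L, c = 3L, N = 30L,
        hyper_p = 1e-4, corr_r = 0.8, corr_p = 1e-5, passed = TRUE,
        stringsAsFactors = FALSE)
    mirDE <- data.frame(gene_id = c("m1", "m2", "m3"),
                        direction = c("down", "down", "up"),
                        stringsAsFactors = FALSE)
    tr <- assembleTriples(pairs, mirDE)
    expect_equal(nrow(tr), 3L)
    expect_setequal(tr$mirna_id, c("m1", "m2", "m3"))
    expect_equal(tr$mirna_direction[tr$mirna_id == "m3"], "up")

    # optional strictness: keep only miRNAs opposite to a target direction
    tdir <- c(L1 = "up", R1 = "up")
    trStrict <- assembleTriples(pairs, mirDE, requireMirnaOpposite = TRUE,
                                targetDirections = tdir)
    expect_setequal(trStrict$mirna_id, c("m1", "m2"))

    none <- pairs; none$passed <- FALSE
    expect_warning(empty <- assembleTriples(none, mirDE), "no passed")
    expect_equal(nrow(empty), 0L)
})

test_that("network summary: counts, handshake lemma and degree ranking", {
    single <- data.frame(lncrna_id = "L1", mirna_id = "M1", mrna_id = "R1",
                         stringsAsFactors = FALSE)
    s1 <- summarizeNetwork(single)
    expect_equal(s1$nNodes, 3L)
    expect_equal(s1$nEdges, 2L)

    set.seed(23)
    rand <- data.frame(lncrna_id = sample(paste0("L", 1:6), 20, TRUE),
                       mirna_id = sample(paste0("M", 1:8), 20, TRUE),
                       mrna_id = sample(paste0("R", 1:6), 20, TRUE),
                       stringsAsFactors = FALSE)
    s2 <- summarizeNetwork(rand)
    expect_equal(sum(s2$degree$degree), 2L * s2$nEdges)

    star <- data.frame(lncrna_id = "Lhub", mirna_id = paste0("M", 1:5),
                       mrna_id = paste0("R", 1:5), stringsAsFactors = FALSE)
    s3 <- summarizeNetwork(star)
    expect_equal(s3$degree$id[1], "Lhub")
    expect_equal(s3$degree$rank[1], 1L)
    expect_equal(summarizeNetwork(single[0, ])$nNodes, 0L)
})

test_that("criteria act conjunctively: null pass rate below the marginal product", {
    reps <- 20
    joint <- hyperRate <- corRate <- numeric(reps)
    for (s in seq_len(reps)) {
        set.seed(300 + s)
        nL <- 12; nR <- 12; nMir <- 40; samples <- sprintf("t%02d", 1:30)
        lnc <- makeExpr(randomCounts(nL, 30, mu = 200), "lncRNA",
                        genePrefix = "L") |> normalizeCounts()
        mrna <- makeExpr(randomCounts(nR, 30, mu = 200), "mRNA",
                         genePrefix = "R") |> normalizeCounts()
        lncIds <- rownames(exprValues(lnc)); mrnaIds <- rownames(exprValues(mrna))
        mirs <- paste0("m", seq_len(nMir))
        edges <- unique(data.frame(
            mirna_id = sample(mirs, 260, TRUE),
            target_id = sample(c(lncIds, mrnaIds), 260, TRUE),
            stringsAsFactors = FALSE))
        edges$target_compartment <- ifelse(edges$target_id %in% lncIds,
                                           "lncRNA", "mRNA")
        pr <- findCernaPairs(lncIds, mrnaIds, mirs, edges, lnc, mrna,
                             colnames(exprValues(lnc)))
        if (!nrow(pr)) next
        joint[s] <- mean(pr$passed)
        hyperRate[s] <- mean(pr$hyper_p < 0.05)
        corRate[s] <- mean(pr$corr_r >= 0.4 & pr$corr_p < 0.05, na.rm = TRUE)
    }
    expect_lte(mean(joint), mean(hyperRate) * mean(corRate) + 0.01)
})

test_that("inference is deterministic for fixed inputs", {
    rec1 <- runTripleRecovery(simConfig(
        nSamples = c(normal = 8L, A = 12L, AB = 12L, B = 12L, TC = 8L),
        nGenes = c(mRNA = 60L, lncRNA = 40L, miRNA = 40L),
        nTrueTriples = 4L, nDecoyInteractions = 30L, seed = 55))
    rec2 <- runTripleRecovery(simConfig(
        nSamples = c(normal = 8L, A = 12L, AB = 12L, B = 12L, TC = 8L),
        nGenes = c(mRNA = 60L, lncRNA = 40L, miRNA = 40L),
        nTrueTriples = 4L, nDecoyInteractions = 30L, seed = 55))
    expect_identical(rec1$pairs, rec2$pairs)
    expect_identical(rec1$triples, rec2$triples)
    expect_gt(nrow(rec1$pairs), 0L)
})

test_that("triple scoring against planted truth counts TP/FP/FN correctly", {
    truth <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = c("M1", "M2"),
                        mrna_id = c("R1", "R2"), stringsAsFactors = FALSE)
    inferred <- data.frame(lncrna_id = c("L1", "L9"), mirna_id = c("M1", "M9"),
                           mrna_id = c("R1", "R9"), stringsAsFactors = FALSE)
    sc <- scoreTriples(inferred, truth)
    expect_equal(sc$tp, 1L)
    expect_equal(sc$fp, 1L)
    expect_equal(sc$fn, 1L)
    expect_equal(sc$precision, 0.5)
    expect_equal(sc$recall, 0.5)
    expect_true(is.na(scoreTriples(inferred[0, ], truth)$precision))
})
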