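test_that("expression filter keeps the boundary fraction and drops silent genes", {
    v <- rbind(allzero = rep(0, 10),
               boundary = c(5, rep(0, 9)),     # expressed in exactly 10%
               below = rep(0, 10),
               strong = rpois(10, 50))
    m <- makeExpr(v)
    kept <- filterLowExpression(m, minFraction = 0.10)
    expect_setequal(rownames(kept), c("boundary", "strong"))

    set.seed(2)
    v2 <- randomCounts(100, 10, mu = 30)
    v2[1:20, ] <- 0
    expect_equal(nrow(filterLowExpression(makeExpr(v2))), 80L)
    expect_error(filterLowExpression(makeExpr(matrix(0L, 2, 4))), "filter")
})

test_that("size factors recover exact library scaling and hand medians", {
    set.seed(4)
    base <- randomCounts(50, 1, mu = 80)[, 1]
    v <- cbind(s1 = base, s2 = 2 * base)
    rownames(v) <- sprintf("g%02d", 1:50)
    sf <- sizeFactors(makeExpr(v))
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

    expect_equal(unname(sizeFactors(makeExpr(matrix(5:9, 5, 1)))), 1)

    v5 <- matrix(c(10, 20, 30, 40, 50,
                   20, 40, 60, 80, 100,
                   10, 10, 10, 10, 10,
                   5, 50, 15, 20, 25), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    # independent by-hand median-of-ratios
    geo <- exp(rowMeans(log(v5)))
    hand <- apply(v5 / geo, 2, median)
    expect_equal(sizeFactors(makeExpr(v5)), hand, tolerance = 1e-12)
})

test_that("size factors agree with DESeq2 median-of-ratios", {
    skip_if_not_installed("DESeq2")
    v <- randomCounts(200, 8, mu = 60, seed = 9)
    expect_equal(unname(sizeFactors(makeExpr(v))),
                 unname(DESeq2::estimateSizeFactorsForMatrix(v)),
                 tolerance = 1e-10)
})

test_that("NB Wald test is calm under the null and recovers planted effects", {
    set.seed(10)
    v <- randomCounts(300, 50, mu = 200, alpha = 0.05)
    ann <- twoGroupAnnotation(25, 25, samplePrefix = "s")
    ann$sample_id <- colnames(v)
    res <- nbWaldDE(makeExpr(v), ann, "A")
    tab <- deTable(res)
    expect_lt(median(abs(tab$log2fc)), 0.1)
    expect_lte(mean(tab$fdr < 0.05), 0.05)
    expect_true(all(tab$fdr >= tab$p - 1e-12))

    # plant a 2.0 log2FC on 30 genes in the tumor group
    vp <- v
    idx <- 1:30
    vp[idx, 26:50] <- matrix(
        rnbinom(30 * 25, mu = 4 * 200, size = 20), 30, 25)
    resp <- nbWaldDE(makeExpr(vp), ann, "A")
    est <- deTable(resp)$log2fc[idx]
    expect_lt(abs(mean(est) - 2.0), 0.3)
    calls <- callDegs(resp)
    expect_gte(mean(rownames(v)[idx] %in% calls$up), 0.95)
})

test_that("IRLS coefficient matches a brute-force likelihood grid", {
    set.seed(14)
    sf <- exp(rnorm(16, 0, 0.15))
    X <- cbind(1, rep(c(0, 1), each = 8))
    alpha <- 0.15
    mu <- exp(log(90) + 0.9 * X[, 2]) * sf
    y <- rnbinom(16, mu = mu, size = 1 / alpha)
    v <- matrix(y, 1, dimnames = list("g1", sprintf("s%02d", 1:16)))
    fit <- ceRNAnet:::.nb_irls(y, X, log(sf), alpha)
    # profile the exact NB likelihood on a fine beta1 grid, optimizing beta0
    prof <- function(b1) {
        opt <- optimize(function(b0) -ceRNAnet:::nbLogLik(c(b0, b1), y, X,
                                                          log(sf), alpha),
                        interval = c(-5, 15), tol = 1e-12)
        -opt$objective
    }
    grid <- seq(fit$beta[2] - 0.3, fit$beta[2] + 0.3, by = 1e-4)
    ll <- vapply(grid, prof, numeric(1))
    expect_lt(abs(grid[which.max(ll)] - fit$beta[2]), 1e-4 + 1e-9)
})

test_that("few-reference-sample regime pools dispersion with a structured warning", {
    v <- randomCounts(50, 12, mu = 100, seed = 15)
    ann <- twoGroupAnnotation(2, 10)
    ann$sample_id <- colnames(v)
    expect_warning(res <- nbWaldDE(makeExpr(v), ann, "A"),
                   class = "cernanet_pooled_dispersion")
    expect_equal(nrow(deTable(res)), 50L)
    expect_true(all(is.finite(deTable(res)$p)))
})

test_that("fold change is equivariant to library scaling and row order", {
    v <- randomCounts(80, 12, mu = 120, seed = 16)
    ann <- twoGroupAnnotation(6, 6)
    ann$sample_id <- colnames(v)
    base <- deTable(nbWaldDE(makeExpr(v), ann, "A"))
    vScaled <- v
    vScaled[, 3] <- v[, 3] * 10
    # relative to the other samples, the size factor absorbs the scaling
    # exactly (the geometric-mean reference shifts all factors together)
    sfScaled <- sizeFactors(makeExpr(vScaled))
    sf <- sizeFactors(makeExpr(v))
    expect_equal(unname((sfScaled[3] / sfScaled[1]) / (sf[3] / sf[1])), 10,
                 tolerance = 1e-12)
    # ... so fold changes move only through the likelihood's precision
    # weighting of the rescaled sample, a second-order effect
    scaled <- deTable(nbWaldDE(makeExpr(vScaled), ann, "A"))
    expect_lt(max(abs(base$log2fc - scaled$log2fc)), 0.05)

    perm <- sample(nrow(v))
    shuffled <- deTable(nbWaldDE(makeExpr(v[perm, ]), ann, "A"))
    expect_equal(shuffled$log2fc[match(base$gene_id, shuffled$gene_id)],
                 base$log2fc, tolerance = 1e-12)
})

test_that("DEG calling uses strict inequalities at both thresholds", {
    tab <- data.frame(
        gene_id = paste0("g", 1:6),
        base_mean = 10, se = 0.1, wald_z = 0,
        log2fc = c(1.0, 1.2, -1.2, 2.0, 1.5, -0.5),
        p = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.001),
        fdr = c(0.01, 0.25, 0.01, 0.25, 0.1, 0.01),
        direction = "ns", stringsAsFactors = FALSE)
    res <- new("DEResult", contrast = "A_vs_normal", table = tab,
               fdrMax = 0.25, lfcMin = 1)
    calls <- callDegs(res)
    expect_setequal(calls$up, "g5")    # g1 lfc==1, g2/g4 fdr==0.25 excluded
    expect_setequal(calls$down, "g3")
})

test_that("contrast intersection requires all contrasts and flags direction", {
    mk <- function(up, down, genes = paste0("g", 1:6)) {
        tab <- data.frame(gene_id = genes, base_mean = 10,
                          log2fc = ifelse(genes %in% up, 2,
                                          ifelse(genes %in% down, -2, 0)),
                          se = 0.1, wald_z = 0,
                          p = ifelse(genes %in% c(up, down), 1e-4, 0.9),
                          fdr = ifelse(genes %in% c(up, down), 1e-3, 0.9),
                          direction = "ns", stringsAsFactors = FALSE)
        new("DEResult", contrast = "x_vs_normal", table = tab,
            fdrMax = 0.25, lfcMin = 1)
    }
    r1 <- mk(up = c("g1", "g2"), down = "g3")
    r2 <- mk(up = c("g1", "g2"), down = "g3")
    r3 <- mk(up = "g1", down = c("g3", "g2"))   # g2 flips direction
    r4 <- mk(up = c("g1", "g2"), down = c("g3", "g4"))  # g4 only here
    inter <- intersectContrasts(list(r1, r2, r3, r4))
    expect_setequal(inter$gene_id, c("g1", "g2", "g3"))
    expect_true(inter$consistent[inter$gene_id == "g1"])
    expect_false(inter$consistent[inter$gene_id == "g2"])
    expect_false("g4" %in% inter$gene_id)

    same <- intersectContrasts(list(r1, r2))
    expect_setequal(same$gene_id, c("g1", "g2", "g3"))
})

test_that("external validation flags concordance and missing genes", {
    set.seed(18)
    v <- randomCounts(20, 16, mu = 100)
    # plant a clear tumor shift on g001 only
    v["g001", 4:16] <- rnbinom(13, mu = 600, size = 10)
    ann <- data.frame(sample_id = colnames(v),
                      group = rep(c("normal", "tumor"), c(3, 13)),
                      stringsAsFactors = FALSE)
    train <- c(g001 = 2.2, g002 = 1.5, absent = -1)
    out <- externalValidation(makeExpr(v), ann,
                              c("g001", "g002", "absent"), train)
    expect_true(out$concordant[out$gene_id == "g001"])
    expect_true(out$missing[out$gene_id == "absent"])
    expect_false(out$concordant[out$gene_id == "absent"])

    # identical tumor/normal values: p ~ 1, never concordant
    # (constant filler rows pin the size factors at 1)
    flat <- rbind(gF = rep(c(10, 20, 30, 40), 8),
                  matrix(50, 5, 32, dimnames = list(paste0("c", 1:5), NULL)))
    colnames(flat) <- paste0("s", 1:32)
    annF <- data.frame(sample_id = colnames(flat),
                       group = rep(c("normal", "tumor"), each = 16),
                       stringsAsFactors = FALSE)
    outF <- externalValidation(makeExpr(flat), annF, "gF", c(gF = 2))
    expect_gt(outF$wilcoxon_p, 0.9)
    expect_false(outF$concordant)
})
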