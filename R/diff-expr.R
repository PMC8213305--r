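# Differential expression: expression filtering, median-of-ratios size
# factors, a transparent negative-binomial Wald test (method-of-moments
# dispersion + IRLS), threshold calling, cross-subtype intersection and
# external-cohort Wilcoxon validation.

#' Drop genes expressed in too few samples
#'
#' Keeps genes with a count of at least `minCount` in at least `minFraction`
#' of the samples; a fraction exactly equal to the threshold is kept.
#'
#' @param m an [ExpressionMatrix-class] of raw counts.
#' @param minFraction minimum fraction of expressing samples (default 0.10).
#' @param minCount a sample "expresses" a gene when its count is >= this
#'   (default 1, i.e. count > 0).
#' @return the filtered [ExpressionMatrix-class].
#' @export
filterLowExpression <- function(m, minFraction = 0.10, minCount = 1) {
    v <- exprValues(m)
    frac <- rowMeans(v >= minCount)
    keep <- frac >= minFraction
    if (!any(keep))
        stop("no genes pass the expression filter; lower minFraction ",
             "or minCount", call. = FALSE)
    ExpressionMatrix(v[keep, , drop = FALSE], compartment(m), isNormalized(m))
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference genes of the ratio of the sample's
#' count to the gene's geometric mean across samples. Reference genes are
#' those with all-positive counts; if none exist, genes positive in at least
#' 90% of samples are used (with the geometric mean taken over their positive
#' counts), and an error is raised if that set is empty too.
#'
#' @param m an [ExpressionMatrix-class] of (filtered) raw counts.
#' @return named positive numeric vector, one per sample.
#' @export
sizeFactors <- function(m) {
    v <- exprValues(m)
    if (ncol(v) == 1L) return(stats::setNames(1, colnames(v)))
    allpos <- rowSums(v > 0) == ncol(v)
    if (any(allpos)) {
        ref <- v[allpos, , drop = FALSE]
        logGeo <- rowMeans(log(ref))
        sf <- apply(ref, 2, function(col) exp(stats::median(log(col) - logGeo)))
    } else {
        mostpos <- rowMeans(v > 0) >= 0.9
        if (!any(mostpos))
            stop("no gene is positive in >= 90% of samples; cannot compute ",
                 "size factors", call. = FALSE)
        ref <- v[mostpos, , drop = FALSE]
        logGeo <- apply(ref, 1, function(r) mean(log(r[r > 0])))
        sf <- apply(ref, 2, function(col) {
            lr <- log(col) - logGeo
            exp(stats::median(lr[is.finite(lr)]))
        })
    }
    stats::setNames(sf, colnames(v))
}

#' Scale counts by median-of-ratios size factors
#'
#' @param m an [ExpressionMatrix-class] of raw counts.
#' @param sf optional precomputed size factors.
#' @return an [ExpressionMatrix-class] with `isNormalized = TRUE`.
#' @export
normalizeCounts <- function(m, sf = sizeFactors(m)) {
    v <- exprValues(m)
    ExpressionMatrix(t(t(v) / sf[colnames(v)]), compartment(m),
                     isNormalized = TRUE)
}

# NB log-likelihood for one gene, fixed dispersion alpha, log link with
# offset; used by the IRLS fit and by the brute-force oracle in the tests.
nbLogLik <- function(beta, y, X, offset, alpha) {
    mu <- exp(drop(X %*% beta) + offset)
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Fisher-scoring IRLS for the NB GLM with known dispersion.
.nb_irls <- function(y, X, offset, alpha, maxit = 50L, tol = 1e-10) {
    # init from group means of offset-corrected counts
    yAdj <- y / exp(offset)
    grp <- X[, 2]
    m0 <- mean(yAdj[grp == 0]); m1 <- mean(yAdj[grp == 1])
    beta <- c(log(max(m0, 0.125)), log(max(m1, 0.125)) - log(max(m0, 0.125)))
    conv <- FALSE
    for (it in seq_len(maxit)) {
        mu <- exp(drop(X %*% beta) + offset)
        mu <- pmin(pmax(mu, 1e-10), 1e12)
        w <- mu / (1 + alpha * mu)
        score <- drop(crossprod(X, (y - mu) / (1 + alpha * mu)))
        info <- crossprod(X * w, X)
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step)) break
        # dampen huge steps to keep the likelihood climb stable
        if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
        beta <- beta + step
        if (max(abs(step)) < tol) { conv <- TRUE; break }
    }
    mu <- exp(drop(X %*% beta) + offset)
    w <- mu / (1 + alpha * mu)
    info <- crossprod(X * w, X)
    se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, 2))
    list(beta = beta, se = se, converged = conv)
}

# Method-of-moments NB dispersion per gene on normalized counts, with a
# correction for the mean reciprocal size factor; pooled across groups with
# >= minPerGroup samples.
.mom_dispersion <- function(normv, groupsIdx, sf, minPerGroup = 2L) {
    est_one <- function(idx) {
        if (length(idx) < minPerGroup) return(NULL)
        y <- normv[, idx, drop = FALSE]
        xim <- mean(1 / sf[idx])
        mu <- rowMeans(y)
        v <- apply(y, 1, stats::var)
        a <- (v - xim * mu) / mu^2
        a[!is.finite(a)] <- 0
        list(a = a, w = length(idx) - 1L)
    }
    parts <- Filter(Negate(is.null), lapply(groupsIdx, est_one))
    if (!length(parts)) {
        # degenerate: no group large enough; pool everything
        y <- normv
        mu <- rowMeans(y)
        v <- apply(y, 1, stats::var)
        a <- (v - mean(1 / sf) * mu) / mu^2
        a[!is.finite(a)] <- 0
        return(pmax(a, 1e-8))
    }
    wsum <- sum(vapply(parts, `[[`, numeric(1), "w"))
    a <- Reduce(`+`, lapply(parts, function(p) p$a * p$w)) / wsum
    pmax(a, 1e-8)
}

#' Negative-binomial Wald differential expression
#'
#' For each gene, fits the NB log-linear model
#' `log mu = beta0 + beta1 * I(group) + log(sizeFactor)` with a per-gene
#' dispersion obtained by method-of-moments on normalized counts (floored at
#' 1e-8) and then moderated by geometric interpolation (weight 0.5) toward
#' the mean dispersion across genes. The group coefficient is maximized by
#' Fisher-scoring IRLS; `wald_z = beta1/SE`, two-sided normal p, BH FDR
#' within the contrast, `log2fc = beta1/ln(2)`.
#'
#' With fewer than `minPerGroup` samples in either group (the real cohort has
#' only 2 normals), per-group moments are degenerate: the dispersion is
#' pooled and a structured warning of class `cernanet_pooled_dispersion` is
#' emitted rather than failing.
#'
#' @param m filtered raw-count [ExpressionMatrix-class].
#' @param ann sample annotation `data.frame(sample_id, group)`.
#' @param group tumor group label to test.
#' @param reference reference group label (default `"normal"`).
#' @param fdrMax,lfcMin thresholds used for the stored direction calls.
#' @return a [DEResult-class].
#' @export
nbWaldDE <- function(m, ann, group, reference = "normal",
                     fdrMax = 0.25, lfcMin = 1.0) {
    ann <- validateSampleAnnotation(ann)
    v <- exprValues(m)
    keep <- ann$sample_id[ann$group %in% c(group, reference)]
    keep <- intersect(colnames(v), keep)
    v <- v[, keep, drop = FALSE]
    grp <- ann$group[match(keep, ann$sample_id)]
    nRef <- sum(grp == reference); nGrp <- sum(grp == group)
    if (nRef == 0 || nGrp == 0)
        stop("both '", group, "' and '", reference,
             "' must be present in the annotation", call. = FALSE)
    pool <- min(nRef, nGrp) < 3
    if (pool) {
        w <- simpleWarning(sprintf(
            "group '%s' has %d sample(s): pooling dispersion across groups",
            if (nRef < nGrp) reference else group, min(nRef, nGrp)))
        class(w) <- c("cernanet_pooled_dispersion", class(w))
        warning(w)
    }
    em <- ExpressionMatrix(v, compartment(m))
    sf <- sizeFactors(em)
    normv <- t(t(v) / sf)
    groupsIdx <- split(seq_along(grp), grp)
    alphaRaw <- .mom_dispersion(normv, groupsIdx, sf,
                                minPerGroup = if (pool) 3L else 2L)
    alphaTrend <- max(mean(alphaRaw), 1e-8)
    alphaMod <- exp(0.5 * log(alphaRaw) + 0.5 * log(alphaTrend))

    X <- cbind(1, as.numeric(grp == group))
    offset <- log(sf)
    nGenes <- nrow(v)
    log2fc <- se <- z <- p <- rep(NA_real_, nGenes)
    for (g in seq_len(nGenes)) {
        y <- v[g, ]
        if (all(y == 0)) { log2fc[g] <- 0; p[g] <- 1; next }
        fit <- .nb_irls(y, X, offset, alphaMod[g])
        log2fc[g] <- fit$beta[2] / log(2)
        se[g] <- fit$se[2] / log(2)
        if (is.finite(fit$se[2]) && fit$se[2] > 0) {
            z[g] <- fit$beta[2] / fit$se[2]
            p[g] <- 2 * stats::pnorm(-abs(z[g]))
        } else p[g] <- 1
    }
    fdr <- bhFdr(p)
    direction <- ifelse(fdr < fdrMax & log2fc > lfcMin, "up",
                 ifelse(fdr < fdrMax & log2fc < -lfcMin, "down", "ns"))
    tab <- data.frame(gene_id = rownames(v), base_mean = rowMeans(normv),
                      log2fc = log2fc, se = se, wald_z = z, p = p, fdr = fdr,
                      direction = direction, stringsAsFactors = FALSE,
                      row.names = NULL)
    new("DEResult", contrast = paste0(group, "_vs_", reference), table = tab,
        fdrMax = fdrMax, lfcMin = lfcMin)
}

#' Call differential genes at thresholds
#'
#' Strict inequalities on both criteria: `up = {fdr < fdrMax and
#' log2fc > lfcMin}`, `down = {fdr < fdrMax and log2fc < -lfcMin}`.
#'
#' @param res a [DEResult-class].
#' @param fdrMax FDR threshold (default 0.25).
#' @param lfcMin absolute log2 fold-change threshold (default 1.0).
#' @return list with character vectors `up` and `down`.
#' @export
callDegs <- function(res, fdrMax = 0.25, lfcMin = 1.0) {
    tab <- deTable(res)
    ok <- !is.na(tab$fdr) & !is.na(tab$log2fc)
    list(up = tab$gene_id[ok & tab$fdr < fdrMax & tab$log2fc > lfcMin],
         down = tab$gene_id[ok & tab$fdr < fdrMax & tab$log2fc < -lfcMin])
}

#' Intersect differential calls across contrasts
#'
#' Genes differential (up or down) in every supplied contrast, with a
#' per-gene flag for whether the direction is consistent across contrasts.
#'
#' @param results list of [DEResult-class] (one per contrast).
#' @param fdrMax,lfcMin thresholds passed to [callDegs()].
#' @return `data.frame(gene_id, consistent, direction)`; `direction` is the
#'   shared direction or `"mixed"`.
#' @export
intersectContrasts <- function(results, fdrMax = 0.25, lfcMin = 1.0) {
    calls <- lapply(results, callDegs, fdrMax = fdrMax, lfcMin = lfcMin)
    sets <- lapply(calls, function(cl) c(cl$up, cl$down))
    common <- Reduce(intersect, sets)
    if (!length(common))
        return(data.frame(gene_id = character(), consistent = logical(),
                          direction = character(), stringsAsFactors = FALSE))
    dirs <- vapply(common, function(g) {
        d <- vapply(calls, function(cl)
            if (g %in% cl$up) "up" else "down", character(1))
        if (length(unique(d)) == 1L) d[1] else "mixed"
    }, character(1))
    data.frame(gene_id = common, consistent = dirs != "mixed",
               direction = unname(dirs), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' External-cohort validation by Wilcoxon rank-sum
#'
#' For each requested gene, the log2 ratio of mean normalized expression
#' (tumor + 1 over normal + 1) and a two-sided Wilcoxon rank-sum p on the
#' normalized values. A gene is concordant when its fold-change sign agrees
#' with the training estimate and p < `pMax`. Genes absent from the external
#' matrix are reported with `missing = TRUE`, never dropped silently.
#'
#' @param m external-cohort raw-count [ExpressionMatrix-class].
#' @param ann annotation with groups `tumor` (or any non-`normal` label) and
#'   `normal`.
#' @param genes character vector of genes to validate.
#' @param trainingLog2fc named numeric vector of training log2 fold changes.
#' @param pMax significance level for concordance (default 0.05).
#' @return `data.frame(gene_id, log2fc, wilcoxon_p, concordant, missing)`.
#' @export
externalValidation <- function(m, ann, genes, trainingLog2fc, pMax = 0.05) {
    ann <- validateSampleAnnotation(ann)
    normv <- exprValues(normalizeCounts(m))
    keep <- intersect(colnames(normv), ann$sample_id)
    normv <- normv[, keep, drop = FALSE]
    isNormal <- ann$group[match(keep, ann$sample_id)] == "normal"
    out <- lapply(genes, function(g) {
        if (!g %in% rownames(normv))
            return(data.frame(gene_id = g, log2fc = NA_real_,
                              wilcoxon_p = NA_real_, concordant = FALSE,
                              missing = TRUE, stringsAsFactors = FALSE))
        x <- normv[g, !isNormal]; y <- normv[g, isNormal]
        lfc <- log2((mean(x) + 1) / (mean(y) + 1))
        p <- wilcoxonRankSum(x, y)$p.value
        conc <- !is.na(trainingLog2fc[g]) &&
            sign(lfc) == sign(trainingLog2fc[g]) && p < pMax
        data.frame(gene_id = g, log2fc = lfc, wilcoxon_p = p,
                   concordant = conc, missing = FALSE,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
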