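# Shared fixture builders. All data are generated in code; no files ship
# with the tests beyond what the tests themselves write to tempdirs.

makeExpr <- function(values, compartment = "mRNA", isNormalized = FALSE,
                     genePrefix = "g", samplePrefix = "s") {
    v <- as.matrix(values)
    if (is.null(rownames(v)))
        rownames(v) <- paste0(genePrefix, seq_len(nrow(v)))
    if (is.null(colnames(v)))
        colnames(v) <- paste0(samplePrefix, seq_len(ncol(v)))
    ExpressionMatrix(v, compartment, isNormalized)
}

randomCounts <- function(nGenes, nSamples, mu = 100, alpha = 0.1,
                         seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rnbinom(nGenes * nSamples, mu = mu, size = 1 / alpha),
           nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%03d", seq_len(nSamples))))
}

twoGroupAnnotation <- function(nRef, nGrp, group = "A",
                               samplePrefix = "s") {
    n <- nRef + nGrp
    data.frame(sample_id = sprintf("%s%03d", samplePrefix, seq_len(n)),
               group = rep(c("normal", group), c(nRef, nGrp)),
               stringsAsFactors = FALSE)
}

# a marker/expression vector pair with an exact sample correlation r
pairWithCorrelation <- function(x, r, seed = 1) {
    set.seed(seed)
    z <- rnorm(length(x))
    xs <- as.numeric(scale(x))
    zs <- as.numeric(scale(residuals(lm(z ~ x))))
    r * xs + sqrt(1 - r^2) * zs
}

# independent binary-outcome AUC (Mann-Whitney with ties at 1/2)
binaryAuc <- function(marker, positive) {
    pos <- marker[positive]; neg <- marker[!positive]
    gr <- outer(pos, neg, ">")
    eq <- outer(pos, neg, "==")
    mean(gr + 0.5 * eq)
}

# small exponential survival cohort, optionally linked to a marker
survCohort <- function(n, beta = 0, censorFrac = 0.3, lambda0 = log(2) / 1500,
                       seed = 1) {
    set.seed(seed)
    z <- rnorm(n)
    rate <- lambda0 * exp(beta * z)
    tEvent <- rexp(n, rate)
    if (censorFrac > 0) {
        cens <- rexp(n, rate = mean(rate) * censorFrac / (1 - censorFrac))
        time <- pmin(tEvent, cens)
        event <- as.integer(tEvent <= cens)
    } else {
        time <- tEvent; event <- rep(1L, n)
    }
    list(clin = data.frame(sample_id = sprintf("p%04d", seq_len(n)),
                           time = time, event = event,
                           stringsAsFactors = FALSE),
         marker = setNames(z, sprintf("p%04d", seq_len(n))))
}
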