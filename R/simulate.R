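# Synthetic cohort generator with planted ceRNA triples and survival
# effects. Gives every downstream stage a ground truth to score against.

#' Simulation configuration
#'
#' Defaults mirror the thymic-epithelial-tumor training cohort this pipeline
#' targets: subtype sizes 16 (A), 35 (AB), 57 (B) and 11 (TC). The normal
#' group defaults to 10 samples so that per-group dispersion estimation is
#' well defined; the cohort's actual 2 normal samples are available as the
#' `"paper"` preset of [runPipeline()] configs and must not crash the DE fit.
#'
#' @param nSamples named integer vector of group sizes
#'   (`normal`, `A`, `AB`, `B`, `TC`).
#' @param nGenes named integer vector of genes per compartment
#'   (`mRNA`, `lncRNA`, `miRNA`).
#' @param nbDispersion NB dispersion alpha in `var = mu + alpha * mu^2`.
#' @param baselineMean median NB mean of a gene (counts scale).
#' @param nTrueTriples number of planted (lncRNA, miRNA, mRNA) triples.
#' @param tripleLog2fc log2 fold change planted on triple members in every
#'   tumor group (positive for lncRNA/mRNA, negated for the miRNA).
#' @param spongeCorrelation target Pearson correlation of a planted
#'   lncRNA-mRNA pair on the log2 scale, in (0, 1).
#' @param backgroundDeFraction fraction of non-planted genes per compartment
#'   given their own subtype fold changes (random sign, |log2FC| ~ U(1.5, 3)),
#'   emulating the broad differential signal of real tumor-versus-normal
#'   cohorts and populating the differential miRNA universe.
#' @param nDecoyInteractions number of random non-true miRNA-target edges
#'   added to the interaction table.
#' @param survivalBeta log hazard ratio per standard deviation of the first
#'   planted module's expression score.
#' @param censorRate target fraction of censored subjects in (0, 1), or 0 for
#'   fully observed follow-up.
#' @param baselineHazard exponential baseline hazard per day (default gives a
#'   median survival of 1500 days at score zero).
#' @param seed integer seed; all three generators derive their streams from
#'   it, so a fixed seed reproduces the full dataset bit for bit.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nSamples = c(normal = 10L, A = 16L, AB = 35L,
                                   B = 57L, TC = 11L),
                      nGenes = c(mRNA = 300L, lncRNA = 150L, miRNA = 150L),
                      nbDispersion = 0.1,
                      baselineMean = 500,
                      nTrueTriples = 10L,
                      tripleLog2fc = 2.0,
                      spongeCorrelation = 0.7,
                      backgroundDeFraction = 0.4,
                      nDecoyInteractions = 200L,
                      survivalBeta = 1.0,
                      censorRate = 0.3,
                      baselineHazard = log(2) / 1500,
                      seed = 1L) {
    cfg <- list(nSamples = nSamples, nGenes = nGenes,
                nbDispersion = nbDispersion, baselineMean = baselineMean,
                nTrueTriples = as.integer(nTrueTriples),
                tripleLog2fc = tripleLog2fc,
                spongeCorrelation = spongeCorrelation,
                backgroundDeFraction = backgroundDeFraction,
                nDecoyInteractions = as.integer(nDecoyInteractions),
                survivalBeta = survivalBeta, censorRate = censorRate,
                baselineHazard = baselineHazard, seed = as.integer(seed))
    if (!all(c("normal", "A", "AB", "B", "TC") %in% names(cfg$nSamples)) ||
        any(cfg$nSamples < 1))
        stop("nSamples must name all five groups with positive sizes",
             call. = FALSE)
    if (!all(c("mRNA", "lncRNA", "miRNA") %in% names(cfg$nGenes)) ||
        any(cfg$nGenes < 1))
        stop("nGenes must name all three compartments with positive sizes",
             call. = FALSE)
    if (cfg$nbDispersion < 0) stop("nbDispersion must be >= 0", call. = FALSE)
    if (cfg$baselineMean <= 0) stop("baselineMean must be > 0", call. = FALSE)
    if (cfg$spongeCorrelation <= 0 || cfg$spongeCorrelation >= 1)
        stop("spongeCorrelation must lie in (0, 1)", call. = FALSE)
    if (cfg$backgroundDeFraction < 0 || cfg$backgroundDeFraction > 1)
        stop("backgroundDeFraction must lie in [0, 1]", call. = FALSE)
    if (cfg$censorRate < 0 || cfg$censorRate >= 1)
        stop("censorRate must lie in [0, 1)", call. = FALSE)
    if (cfg$nTrueTriples > min(cfg$nGenes))
        stop("nTrueTriples exceeds the smallest compartment", call. = FALSE)
    class(cfg) <- "SimConfig"
    cfg
}

.sim_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

# log2-scale NB noise variance via the delta method: Var(log2 X) ~
# (1/ln2)^2 * (1/mu + alpha). Latent-factor loadings are sized from it so
# that the planted pair correlation on the log2 scale hits the target rho:
# s_g = sqrt(rho/(1-rho) * v_g) makes corr = s_x s_y / sqrt((s_x^2+v_x)
# (s_y^2+v_y)) = rho.
.log2_noise_var <- function(mu, alpha) (1 / log(2))^2 * (1 / mu + alpha)

#' Simulate the three compartment count matrices
#'
#' Negative-binomial counts (`mu`, `var = mu + alpha mu^2`) for mRNA, lncRNA
#' and miRNA compartments over the configured cohort. The first
#' `nTrueTriples` genes of each compartment form planted ceRNA triples: all
#' tumor groups receive a `+tripleLog2fc` shift on the lncRNA and mRNA and
#' `-tripleLog2fc` on the miRNA, and a shared per-triple latent factor (with
#' the miRNA loading negated) induces the sponge-like positive lncRNA-mRNA /
#' negative miRNA co-expression at the configured strength. A further
#' `backgroundDeFraction` of genes get independent subtype fold changes with
#' no cross-compartment structure. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return list with elements `mRNA`, `lncRNA`, `miRNA`
#'   ([ExpressionMatrix-class] of raw counts), `annotation`
#'   (`data.frame(sample_id, group)`) and `truth` (list: `true_triples`
#'   data.frame, `de_genes` per compartment, `survival_beta`).
#' @export
simulateCounts <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    groups <- c("normal", "A", "AB", "B", "TC")
    grp <- rep(groups, times = cfg$nSamples[groups])
    nS <- length(grp)
    samples <- .sim_ids("S", nS)
    ann <- data.frame(sample_id = samples, group = grp,
                      stringsAsFactors = FALSE)
    tumor <- grp != "normal"
    nT <- cfg$nTrueTriples
    alpha <- cfg$nbDispersion

    # one latent factor per planted triple, shared across compartments
    latent <- matrix(stats::rnorm(nT * nS), nT, nS)

    prefixes <- c(mRNA = "MR", lncRNA = "LNC", miRNA = "MIR")
    sign_of <- c(mRNA = 1, lncRNA = 1, miRNA = -1)
    mats <- list()
    de_genes <- list()
    for (comp in c("mRNA", "lncRNA", "miRNA")) {
        nG <- cfg$nGenes[[comp]]
        ids <- .sim_ids(prefixes[[comp]], nG)
        planted <- seq_len(nT)
        base <- log2(cfg$baselineMean) + stats::rnorm(nG, 0, 1.5)
        base[planted] <- log2(cfg$baselineMean) + stats::rnorm(nT, 0, 0.5)

        lfc <- matrix(0, nG, length(groups), dimnames = list(ids, groups))
        lfc[planted, groups != "normal"] <- sign_of[[comp]] * cfg$tripleLog2fc
        nBg <- round(cfg$backgroundDeFraction * (nG - nT))
        bg <- integer(0)
        if (nBg > 0) {
            bg <- sample(setdiff(seq_len(nG), planted), nBg)
            mag <- stats::runif(nBg, 1.5, 3) * sample(c(-1, 1), nBg, TRUE)
            for (g in groups[groups != "normal"])
                lfc[bg, g] <- mag + stats::rnorm(nBg, 0, 0.25)
        }

        logmu <- matrix(base, nG, nS) + lfc[, grp]
        # sponge latent factor on planted genes
        mu_tumor <- 2^(base[planted] + sign_of[[comp]] * cfg$tripleLog2fc)
        v <- .log2_noise_var(mu_tumor, alpha)
        s <- sqrt(cfg$spongeCorrelation / (1 - cfg$spongeCorrelation) * v)
        logmu[planted, ] <- logmu[planted, ] + sign_of[[comp]] * (s * latent)

        sf <- exp(stats::rnorm(nS, 0, 0.2))
        mu <- t(t(2^logmu) * sf)
        counts <- if (alpha > 0) {
            matrix(stats::rnbinom(nG * nS, mu = mu, size = 1 / alpha), nG, nS)
        } else {
            matrix(stats::rpois(nG * nS, lambda = mu), nG, nS)
        }
        dimnames(counts) <- list(ids, samples)
        mats[[comp]] <- ExpressionMatrix(counts, comp)
        de_genes[[comp]] <- ids[sort(c(planted, bg))]
    }

    truth <- list(
        true_triples = data.frame(
            lncrna_id = .sim_ids("LNC", nT),
            mirna_id = .sim_ids("MIR", nT),
            mrna_id = .sim_ids("MR", nT),
            stringsAsFactors = FALSE),
        de_genes = de_genes,
        survival_beta = cfg$survivalBeta)
    list(mRNA = mats$mRNA, lncRNA = mats$lncRNA, miRNA = mats$miRNA,
         annotation = ann, truth = truth)
}

#' Simulate the miRNA-target interaction table
#'
#' Emits both edges of every true triple (miRNA to its lncRNA and its mRNA)
#' plus `nDecoyInteractions` random non-true edges drawn uniformly over all
#' (miRNA, target) pairs, duplicate-free. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @param truth the `truth` element of [simulateCounts()] output.
#' @return validated interaction `data.frame`.
#' @export
simulateInteractions <- function(cfg, truth) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 1L)
    tt <- truth$true_triples
    true_edges <- rbind(
        data.frame(mirna_id = tt$mirna_id, target_id = tt$lncrna_id,
                   target_compartment = "lncRNA", stringsAsFactors = FALSE),
        data.frame(mirna_id = tt$mirna_id, target_id = tt$mrna_id,
                   target_compartment = "mRNA", stringsAsFactors = FALSE))
    mirs <- .sim_ids("MIR", cfg$nGenes[["miRNA"]])
    targets <- c(.sim_ids("LNC", cfg$nGenes[["lncRNA"]]),
                 .sim_ids("MR", cfg$nGenes[["mRNA"]]))
    comp_of <- stats::setNames(
        rep(c("lncRNA", "mRNA"), c(cfg$nGenes[["lncRNA"]],
                                   cfg$nGenes[["mRNA"]])), targets)
    nPossible <- length(mirs) * length(targets) - nrow(true_edges)
    if (cfg$nDecoyInteractions > nPossible)
        stop("nDecoyInteractions exceeds the number of available pairs",
             call. = FALSE)
    seen <- paste(true_edges$mirna_id, true_edges$target_id, sep = "\r")
    decoys <- character(0)
    while (length(decoys) < cfg$nDecoyInteractions) {
        need <- cfg$nDecoyInteractions - length(decoys)
        cand <- paste(sample(mirs, 2L * need + 10L, replace = TRUE),
                      sample(targets, 2L * need + 10L, replace = TRUE),
                      sep = "\r")
        cand <- setdiff(unique(cand), c(seen, decoys))
        decoys <- c(decoys, utils::head(cand, need))
    }
    dec <- do.call(rbind, strsplit(decoys, "\r", fixed = TRUE))
    decoy_edges <- data.frame(mirna_id = dec[, 1], target_id = dec[, 2],
                              target_compartment = unname(comp_of[dec[, 2]]),
                              stringsAsFactors = FALSE)
    validateInteractionTable(rbind(true_edges, decoy_edges))
}

#' Simulate clinical outcomes driven by the first planted module
#'
#' The per-sample module score is the standardized mean of the first planted
#' triple's log2 normalized expression with the miRNA negated,
#' `z = scale((x_mRNA + x_lncRNA - x_miRNA) / 3)`. Event times are
#' exponential with rate `baselineHazard * exp(survivalBeta * z)`;
#' independent uniform censoring on `(0, u)` with `u` solved numerically so
#' the expected censored fraction equals `censorRate`. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @param matrices output list of [simulateCounts()].
#' @return validated clinical `data.frame(sample_id, time, event)`.
#' @export
simulateSurvival <- function(cfg, matrices) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 2L)
    truth <- matrices$truth
    t1 <- truth$true_triples[1, ]
    sc <- function(em, id) {
        v <- exprValues(normalizeCounts(em))
        log2(v[id, ] + 1)
    }
    raw <- (sc(matrices$mRNA, t1$mrna_id) +
            sc(matrices$lncRNA, t1$lncrna_id) -
            sc(matrices$miRNA, t1$mirna_id)) / 3
    z <- as.numeric(scale(raw))
    rate <- cfg$baselineHazard * exp(cfg$survivalBeta * z)
    tEvent <- stats::rexp(length(z), rate = rate)
    if (cfg$censorRate == 0) {
        time <- tEvent; event <- rep(1L, length(z))
    } else {
        censFrac <- function(u) mean((1 - exp(-rate * u)) / (rate * u))
        u <- stats::uniroot(function(u) censFrac(u) - cfg$censorRate,
                            lower = 1e-6, upper = 1e9, tol = 1e-8)$root
        cens <- stats::runif(length(z), 0, u)
        event <- as.integer(tEvent <= cens)
        time <- pmin(tEvent, cens)
    }
    validateClinicalTable(data.frame(
        sample_id = colnames(exprValues(matrices$mRNA)),
        time = time, event = event, stringsAsFactors = FALSE))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulateCounts()], [simulateInteractions()]
#' and [simulateSurvival()] with one configuration.
#'
#' @param cfg a [simConfig()].
#' @return list with `mRNA`, `lncRNA`, `miRNA`, `annotation`, `truth`,
#'   `interactions`, `clinical`.
#' @export
simulateDataset <- function(cfg = simConfig()) {
    d <- simulateCounts(cfg)
    d$interactions <- simulateInteractions(cfg, d$truth)
    d$clinical <- simulateSurvival(cfg, d)
    d
}

#' Write a simulated dataset to TSV files
#'
#' @param d output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return named vector of paths, invisibly.
#' @export
writeSimulatedDataset <- function(d, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(mRNA = file.path(dir, "mrna_counts.tsv"),
               lncRNA = file.path(dir, "lncrna_counts.tsv"),
               miRNA = file.path(dir, "mirna_counts.tsv"),
               annotation = file.path(dir, "samples.tsv"),
               interactions = file.path(dir, "interactions.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               truth = file.path(dir, "true_triples.tsv"))
    writeExpression(d$mRNA, paths["mRNA"])
    writeExpression(d$lncRNA, paths["lncRNA"])
    writeExpression(d$miRNA, paths["miRNA"])
    writeSampleAnnotation(d$annotation, paths["annotation"])
    writeInteractionTable(d$interactions, paths["interactions"])
    writeClinicalTable(d$clinical, paths["clinical"])
    .write_tsv(d$truth$true_triples, paths["truth"])
    invisible(paths)
}
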