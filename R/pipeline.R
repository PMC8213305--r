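# Orchestration: one config drives filter -> per-subtype DE -> intersection
# -> (optional ORA) -> ceRNA pairs/triples -> network export -> (optional
# external validation) -> per-module survival + time-dependent ROC, with a
# JSON-lines run log and a reproducibility manifest.

#' Pipeline configuration
#'
#' All thresholds default to the published analysis settings: expression in
#' at least 10% of samples, FDR < 0.25 with |log2FC| > 1 for the
#' differential screen, hypergeometric p < .05 with correlation >= 0.4
#' (p < .05) for ceRNA pairs, and a 5-year (1825-day) ROC horizon.
#'
#' @param inputs named list of paths (`mRNA`, `lncRNA`, `miRNA`,
#'   `annotation`, `interactions`, `clinical`, optionally `gmt`,
#'   `external`, `externalAnnotation`) or `NULL` when passing in-memory data
#'   to [runPipeline()].
#' @param fdrMax,lfcMin DE thresholds (0.25, 1.0).
#' @param minExpressedFrac expression-filter fraction (0.10).
#' @param hyperPmax,corMin,corPmax ceRNA pair criteria (.05, 0.4, .05).
#' @param corMethod `"pearson"` or `"spearman"`.
#' @param requireMirnaOpposite enforce miRNA-opposite-direction on triples.
#' @param tStar ROC horizon in days (1825).
#' @param maxModules evaluate at most this many top-degree triples as
#'   survival modules (default 10).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(inputs = NULL, fdrMax = 0.25, lfcMin = 1.0,
                           minExpressedFrac = 0.10, hyperPmax = 0.05,
                           corMin = 0.4, corPmax = 0.05,
                           corMethod = "pearson",
                           requireMirnaOpposite = FALSE,
                           tStar = 1825, maxModules = 10L, seed = 1L) {
    cfg <- list(inputs = inputs, fdrMax = fdrMax, lfcMin = lfcMin,
                minExpressedFrac = minExpressedFrac, hyperPmax = hyperPmax,
                corMin = corMin, corPmax = corPmax, corMethod = corMethod,
                requireMirnaOpposite = requireMirnaOpposite, tStar = tStar,
                maxModules = as.integer(maxModules), seed = as.integer(seed))
    stopifnot(cfg$fdrMax > 0, cfg$fdrMax <= 1, cfg$lfcMin >= 0,
              cfg$minExpressedFrac >= 0, cfg$minExpressedFrac <= 1,
              cfg$hyperPmax > 0, cfg$hyperPmax <= 1,
              cfg$corMin >= -1, cfg$corMin <= 1,
              cfg$corPmax > 0, cfg$corPmax <= 1, cfg$tStar > 0)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipelineConfig()] arguments; an `inputs` mapping
#' holds the file paths. Referenced input files must exist.
#'
#' @param path YAML path.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y), names(formals(pipelineConfig)))]
    cfg <- do.call(pipelineConfig, args)
    if (!is.null(cfg$inputs)) {
        paths <- unlist(cfg$inputs)
        miss <- paths[!file.exists(paths)]
        if (length(miss))
            stop("config references missing file(s): ",
                 paste(miss, collapse = ", "), call. = FALSE)
    }
    cfg
}

.log_jsonl <- function(con, stage, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    writeLines(line, con)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
}

.load_inputs <- function(cfg) {
    ip <- cfg$inputs
    list(mRNA = readExpression(ip$mRNA, "mRNA"),
         lncRNA = readExpression(ip$lncRNA, "lncRNA"),
         miRNA = readExpression(ip$miRNA, "miRNA"),
         annotation = readSampleAnnotation(ip$annotation),
         interactions = readInteractionTable(ip$interactions),
         clinical = if (!is.null(ip$clinical)) readClinicalTable(ip$clinical))
}

#' Run the full ceRNA discovery and prognosis pipeline
#'
#' Stages: expression filter; NB Wald DE of each tumor subtype versus
#' normal, per compartment; cross-subtype intersection; optional
#' over-representation analysis of the intersected mRNAs; ceRNA pair and
#' triple inference; network export (SIF/GraphML/TSV); optional external
#' Wilcoxon validation; multivariate Cox risk score, median-split KM/log-rank
#' and time-dependent ROC for the top-degree modules. Any stage failure
#' halts with the stage name; a manifest with the config, seed, package
#' version and per-stage row counts is written at the end.
#'
#' @param cfg a `"PipelineConfig"` (paths in `cfg$inputs`) .
#' @param data optional in-memory dataset as returned by
#'   [simulateDataset()]; overrides `cfg$inputs`.
#' @param outDir output directory.
#' @return invisible list with the main in-memory results (`de`,
#'   `intersection`, `pairs`, `triples`, `network`, `modules`, `manifest`).
#' @export
runPipeline <- function(cfg, data = NULL, outDir) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outDir, "run_log.jsonl")
    con <- file(logPath, open = "wt")
    on.exit(close(con), add = TRUE)
    counts <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
    }

    d <- if (!is.null(data)) data else stage("load", .load_inputs(cfg))
    ann <- validateSampleAnnotation(d$annotation)
    # re-index matrices to the annotation's sample order
    reindex <- function(em) {
        v <- exprValues(em)
        keep <- intersect(ann$sample_id, colnames(v))
        if (!length(keep))
            stop("no overlap between annotation samples and the ",
                 compartment(em), " matrix", call. = FALSE)
        ExpressionMatrix(v[, keep, drop = FALSE], compartment(em),
                         isNormalized(em))
    }
    mats <- stage("align", list(mRNA = reindex(d$mRNA),
                                lncRNA = reindex(d$lncRNA),
                                miRNA = reindex(d$miRNA)))

    filtered <- stage("filter", lapply(mats, filterLowExpression,
                                       minFraction = cfg$minExpressedFrac))
    for (comp in names(filtered))
        .log_jsonl(con, "filter", compartment = comp,
                   genes_in = nrow(mats[[comp]]),
                   genes_out = nrow(filtered[[comp]]))
    counts$filter <- vapply(filtered, nrow, integer(1))

    subtypes <- intersect(c("A", "AB", "B", "TC"), unique(ann$group))
    de <- list()
    for (comp in names(filtered)) {
        de[[comp]] <- lapply(subtypes, function(s)
            suppressWarnings(nbWaldDE(filtered[[comp]], ann, s,
                                      fdrMax = cfg$fdrMax,
                                      lfcMin = cfg$lfcMin)))
        names(de[[comp]]) <- subtypes
        for (s in subtypes) {
            res <- de[[comp]][[s]]
            cl <- callDegs(res, cfg$fdrMax, cfg$lfcMin)
            .write_tsv(deTable(res),
                       file.path(outDir, sprintf("de_%s_%s.tsv", comp, s)))
            .log_jsonl(con, "de", compartment = comp, contrast = s,
                       up = length(cl$up), down = length(cl$down))
        }
    }

    inter <- stage("intersect", lapply(de, intersectContrasts,
                                       fdrMax = cfg$fdrMax,
                                       lfcMin = cfg$lfcMin))
    for (comp in names(inter)) {
        .write_tsv(inter[[comp]],
                   file.path(outDir, sprintf("intersection_%s.tsv", comp)))
        .log_jsonl(con, "intersect", compartment = comp,
                   genes = nrow(inter[[comp]]))
    }
    counts$intersection <- vapply(inter, nrow, integer(1))

    ora <- NULL
    if (!is.null(cfg$inputs$gmt) && nrow(inter$mRNA)) {
        ora <- stage("ora", overrepresentationTest(
            inter$mRNA$gene_id, readGmt(cfg$inputs$gmt),
            rownames(exprValues(filtered$mRNA))))
        .write_tsv(ora, file.path(outDir, "ora_mrna.tsv"))
        .log_jsonl(con, "ora", terms = nrow(ora))
    }

    normed <- lapply(filtered, normalizeCounts)
    tumorSamples <- ann$sample_id[ann$group != "normal"]
    pairs <- stage("pairs", findCernaPairs(
        deLnc = inter$lncRNA$gene_id, deMrna = inter$mRNA$gene_id,
        deMir = inter$miRNA$gene_id, interactions = d$interactions,
        exprLnc = normed$lncRNA, exprMrna = normed$mRNA,
        tumorSamples = intersect(tumorSamples,
                                 colnames(exprValues(normed$lncRNA))),
        hyperPmax = cfg$hyperPmax, corMin = cfg$corMin,
        corPmax = cfg$corPmax, corMethod = cfg$corMethod))
    .write_tsv(pairs, file.path(outDir, "cerna_pairs.tsv"))
    .log_jsonl(con, "pairs", candidates = nrow(pairs),
               passed = sum(pairs$passed))

    mirDirs <- do.call(rbind, lapply(de$miRNA, deTable))
    mirConsensus <- inter$miRNA
    mirDE <- data.frame(gene_id = mirConsensus$gene_id,
                        direction = mirConsensus$direction,
                        stringsAsFactors = FALSE)
    tdir <- stats::setNames(
        c(inter$lncRNA$direction, inter$mRNA$direction),
        c(inter$lncRNA$gene_id, inter$mRNA$gene_id))
    triples <- stage("triples", suppressWarnings(assembleTriples(
        pairs, mirDE, requireMirnaOpposite = cfg$requireMirnaOpposite,
        targetDirections = tdir)))
    .write_tsv(triples, file.path(outDir, "cerna_triples.tsv"))
    .log_jsonl(con, "triples", triples = nrow(triples))
    counts$pairs <- nrow(pairs); counts$triples <- nrow(triples)

    summ <- summarizeNetwork(triples)
    if (nrow(triples)) {
        nodeAttrs <- data.frame(
            id = c(inter$lncRNA$gene_id, inter$mRNA$gene_id,
                   inter$miRNA$gene_id),
            direction = c(inter$lncRNA$direction, inter$mRNA$direction,
                          inter$miRNA$direction), stringsAsFactors = FALSE)
        suppressWarnings(writeNetwork(triples, nodeAttrs,
                                      file.path(outDir, "cerna_network")))
    }
    .log_jsonl(con, "network", nodes = summ$nNodes, edges = summ$nEdges)

    validation <- NULL
    if (!is.null(cfg$inputs$external) &&
        !is.null(cfg$inputs$externalAnnotation) && nrow(triples)) {
        ext <- readExpression(cfg$inputs$external, "mRNA")
        extAnn <- readSampleAnnotation(cfg$inputs$externalAnnotation)
        trainLfc <- stats::setNames(deTable(de$mRNA[[1]])$log2fc,
                                    deTable(de$mRNA[[1]])$gene_id)
        validation <- stage("validation", externalValidation(
            ext, extAnn, unique(triples$mrna_id), trainLfc))
        .write_tsv(validation, file.path(outDir, "external_validation.tsv"))
        .log_jsonl(con, "validation", genes = nrow(validation),
                   concordant = sum(validation$concordant))
    }

    modules <- list()
    if (!is.null(d$clinical) && nrow(triples)) {
        deg <- summ$degree
        nodeDeg <- stats::setNames(deg$degree, deg$id)
        modScore <- nodeDeg[triples$lncrna_id] + nodeDeg[triples$mirna_id] +
            nodeDeg[triples$mrna_id]
        ord <- order(-modScore, triples$lncrna_id, triples$mirna_id,
                     triples$mrna_id)
        top <- triples[utils::head(ord, cfg$maxModules), , drop = FALSE]
        modTab <- list()
        for (i in seq_len(nrow(top))) {
            mod <- c(lncrna = top$lncrna_id[i], mirna = top$mirna_id[i],
                     mrna = top$mrna_id[i])
            fit <- stage("survival", suppressWarnings(
                moduleRiskScore(d$clinical, mod, normed)))
            tS <- min(cfg$tStar, max(d$clinical$time))
            roc <- tryCatch(
                timeDependentRoc(d$clinical, fit$riskScore, tS),
                error = function(e) NULL)
            modules[[i]] <- list(module = mod, fit = fit, roc = roc)
            modTab[[i]] <- data.frame(
                lncrna_id = mod[["lncrna"]], mirna_id = mod[["mirna"]],
                mrna_id = mod[["mrna"]],
                logrank_p = if (!is.null(fit$logrank))
                    fit$logrank$p.value else NA_real_,
                auc = if (!is.null(roc)) roc$auc else NA_real_,
                converged = fit$cox$converged, stringsAsFactors = FALSE)
            .log_jsonl(con, "survival",
                       module = paste(mod, collapse = "|"),
                       logrank_p = signif(modTab[[i]]$logrank_p, 4),
                       auc = signif(modTab[[i]]$auc, 4))
        }
        if (length(modTab))
            .write_tsv(do.call(rbind, modTab),
                       file.path(outDir, "module_survival.tsv"))
    }

    manifest <- list(package = "ceRNAnet",
                     version = as.character(utils::packageVersion("ceRNAnet")),
                     r_version = as.character(getRversion()),
                     seed = cfg$seed,
                     config = cfg[setdiff(names(cfg), "inputs")],
                     stage_counts = counts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(de = de, intersection = inter, ora = ora, pairs = pairs,
                   triples = triples, network = summ,
                   validation = validation, modules = modules,
                   manifest = manifest))
}
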