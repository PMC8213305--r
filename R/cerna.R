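# ceRNA inference: shared-miRNA hypergeometric enrichment plus positive
# co-expression calls lncRNA-mRNA sponge pairs; pairs expand to
# lncRNA-miRNA-mRNA triples; the triple set defines the network.

#' Find candidate ceRNA lncRNA-mRNA pairs
#'
#' For every differential lncRNA and differential mRNA that share at least
#' one targeting differential miRNA, computes (1) the upper-tail
#' hypergeometric probability of the shared count given the two target-set
#' sizes and the differential-miRNA universe, and (2) the co-expression
#' correlation of the pair on `log2(normalized + 1)` values over tumor
#' samples. A pair passes when `hyper_p < hyperPmax`, `corr_r >=
#' corMin` and `corr_p < corPmax` (positive co-expression, as expected of two
#' transcripts competing for the same miRNAs).
#'
#' The universe `N` is the set of differential miRNAs that appear in the
#' interaction table. Correlation defaults to Pearson over tumor samples
#' only; including normals would inflate r through the tumor-normal group
#' shift. Hypergeometric p-values are not multiplicity-adjusted by default
#' (`adjust = "BH"` adjusts them across candidate pairs).
#'
#' @param deLnc,deMrna,deMir character vectors of differential gene ids per
#'   compartment.
#' @param interactions interaction `data.frame` (see
#'   [readInteractionTable()]).
#' @param exprLnc,exprMrna normalized [ExpressionMatrix-class] objects.
#' @param tumorSamples sample ids over which to correlate (tumor only).
#' @param hyperPmax,corMin,corPmax the pair criteria (defaults .05, 0.4, .05).
#' @param corMethod `"pearson"` (default) or `"spearman"`.
#' @param adjust `"none"` (default) or `"BH"` for the hypergeometric p.
#' @return `data.frame` with one row per candidate pair: `lncrna_id`,
#'   `mrna_id`, `shared_mirnas` (`;`-joined), `K`, `n`, `c`, `N`, `hyper_p`,
#'   `corr_r`, `corr_p`, `passed`. Pairs whose members are missing from the
#'   expression matrices are skipped with a message.
#' @export
findCernaPairs <- function(deLnc, deMrna, deMir, interactions,
                           exprLnc, exprMrna, tumorSamples,
                           hyperPmax = 0.05, corMin = 0.4, corPmax = 0.05,
                           corMethod = c("pearson", "spearman"),
                           adjust = c("none", "BH")) {
    corMethod <- match.arg(corMethod)
    adjust <- match.arg(adjust)
    edges <- interactions[interactions$mirna_id %in% deMir, , drop = FALSE]
    universe <- unique(edges$mirna_id)
    N <- length(universe)
    mirsByTarget <- split(edges$mirna_id, edges$target_id)

    lncV <- exprValues(exprLnc)[, tumorSamples, drop = FALSE]
    mrnaV <- exprValues(exprMrna)[, tumorSamples, drop = FALSE]
    lncs <- intersect(deLnc, names(mirsByTarget))
    mrnas <- intersect(deMrna, names(mirsByTarget))
    skipped <- c(setdiff(lncs, rownames(lncV)), setdiff(mrnas, rownames(mrnaV)))
    if (length(skipped))
        message("skipping ", length(skipped),
                " gene(s) absent from the expression matrices: ",
                paste(utils::head(skipped, 5), collapse = ", "))
    lncs <- intersect(lncs, rownames(lncV))
    mrnas <- intersect(mrnas, rownames(mrnaV))

    empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                        shared_mirnas = character(), K = integer(),
                        n = integer(), c = integer(), N = integer(),
                        hyper_p = numeric(), corr_r = numeric(),
                        corr_p = numeric(), passed = logical(),
                        stringsAsFactors = FALSE)
    if (!length(lncs) || !length(mrnas) || N == 0) return(empty)

    lncLog <- log2(lncV[lncs, , drop = FALSE] + 1)
    mrnaLog <- log2(mrnaV[mrnas, , drop = FALSE] + 1)
    rows <- list()
    for (l in lncs) {
        lncMirs <- unique(mirsByTarget[[l]])
        for (mr in mrnas) {
            mrMirs <- unique(mirsByTarget[[mr]])
            shared <- intersect(lncMirs, mrMirs)
            if (!length(shared)) next
            hp <- hypergeomSharedMirnaP(N = N, K = length(mrMirs),
                                        n = length(lncMirs),
                                        c = length(shared))$p.value
            x <- lncLog[l, ]; y <- mrnaLog[mr, ]
            if (stats::sd(x) == 0 || stats::sd(y) == 0) {
                r <- NA_real_; cp <- NA_real_
            } else {
                ct <- corTest(x, y, method = corMethod)
                r <- unname(ct$estimate); cp <- ct$p.value
            }
            rows[[length(rows) + 1L]] <- data.frame(
                lncrna_id = l, mrna_id = mr,
                shared_mirnas = paste(sort(shared), collapse = ";"),
                K = length(mrMirs), n = length(lncMirs), c = length(shared),
                N = N, hyper_p = hp, corr_r = r, corr_p = cp,
                passed = NA, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    hp <- if (adjust == "BH") bhFdr(out$hyper_p) else out$hyper_p
    out$passed <- hp < hyperPmax & !is.na(out$corr_r) &
        out$corr_r >= corMin & out$corr_p < corPmax
    row.names(out) <- NULL
    out
}

#' Expand passed ceRNA pairs into lncRNA-miRNA-mRNA triples
#'
#' One triple per (passed pair, shared miRNA). The miRNA's regulation
#' direction is annotated from its differential-expression result. A sponge
#' triple is biologically expected to have the miRNA moving opposite to its
#' two targets; with `requireMirnaOpposite = TRUE` triples whose miRNA
#' direction matches both targets' are dropped (off by default: the pair
#' criteria as stated are the enrichment and correlation conditions only).
#'
#' @param pairs output of [findCernaPairs()].
#' @param mirDE a [DEResult-class] (or `data.frame` with `gene_id`,
#'   `direction`) for the miRNA compartment.
#' @param requireMirnaOpposite drop triples whose miRNA direction is not
#'   opposite to at least one target's direction (needs `targetDirections`).
#' @param targetDirections optional named direction vector for lncRNA/mRNA
#'   ids, used only when `requireMirnaOpposite = TRUE`.
#' @return `data.frame(lncrna_id, mirna_id, mrna_id, hyper_p, corr_r,
#'   corr_p, mirna_direction)`; zero rows (with a warning) when nothing
#'   passed.
#' @export
assembleTriples <- function(pairs, mirDE, requireMirnaOpposite = FALSE,
                            targetDirections = NULL) {
    mirTab <- if (is(mirDE, "DEResult")) deTable(mirDE) else mirDE
    passed <- pairs[which(pairs$passed), , drop = FALSE]
    empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                        mrna_id = character(), hyper_p = numeric(),
                        corr_r = numeric(), corr_p = numeric(),
                        mirna_direction = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(passed)) {
        warning("no passed ceRNA pairs: empty triple set")
        return(empty)
    }
    rows <- lapply(seq_len(nrow(passed)), function(i) {
        pr <- passed[i, ]
        mirs <- strsplit(pr$shared_mirnas, ";", fixed = TRUE)[[1]]
        dir <- mirTab$direction[match(mirs, mirTab$gene_id)]
        data.frame(lncrna_id = pr$lncrna_id, mirna_id = mirs,
                   mrna_id = pr$mrna_id, hyper_p = pr$hyper_p,
                   corr_r = pr$corr_r, corr_p = pr$corr_p,
                   mirna_direction = ifelse(is.na(dir), "ns", dir),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (requireMirnaOpposite && nrow(out)) {
        tdir <- targetDirections
        opp <- function(a, b) (a == "up" & b == "down") |
            (a == "down" & b == "up")
        keep <- opp(out$mirna_direction, tdir[out$lncrna_id]) |
            opp(out$mirna_direction, tdir[out$mrna_id])
        keep[is.na(keep)] <- FALSE
        out <- out[keep, , drop = FALSE]
    }
    row.names(out) <- NULL
    out
}

# distinct undirected edges induced by a triple table, in SIF order
networkEdges <- function(triples) {
    ed <- rbind(
        data.frame(source = triples$lncrna_id, interaction = "lncRNA-miRNA",
                   target = triples$mirna_id, stringsAsFactors = FALSE),
        data.frame(source = triples$mirna_id, interaction = "miRNA-mRNA",
                   target = triples$mrna_id, stringsAsFactors = FALSE))
    unique(ed)
}

.compartment_of_node <- function(triples, ids) {
    comp <- rep(NA_character_, length(ids))
    comp[ids %in% triples$lncrna_id] <- "lncRNA"
    comp[ids %in% triples$mirna_id] <- "miRNA"
    comp[ids %in% triples$mrna_id] <- "mRNA"
    comp
}

#' Summarize a ceRNA network
#'
#' Node and edge counts (duplicate edges across triples collapsed) and a
#' per-node degree ranking with a deterministic tie-break: degree
#' descending, then lexicographic id. Rank is reported overall and within
#' compartment.
#'
#' @param triples triple `data.frame` from [assembleTriples()].
#' @return list of class `"NetworkSummary"`: `nNodes`, `nEdges`, `degree`
#'   (`data.frame(id, compartment, degree, rank, compartment_rank)`).
#' @export
summarizeNetwork <- function(triples) {
    if (is.null(triples) || !nrow(triples)) {
        return(structure(list(nNodes = 0L, nEdges = 0L,
                              degree = data.frame(id = character(),
                                                  compartment = character(),
                                                  degree = integer(),
                                                  rank = integer(),
                                                  compartment_rank = integer())),
                         class = "NetworkSummary"))
    }
    ed <- networkEdges(triples)
    ids <- sort(unique(c(ed$source, ed$target)))
    deg <- table(factor(c(ed$source, ed$target), levels = ids))
    df <- data.frame(id = ids, compartment = .compartment_of_node(triples, ids),
                     degree = as.integer(deg), stringsAsFactors = FALSE)
    df <- df[order(-df$degree, df$id), , drop = FALSE]
    df$rank <- rank(-df$degree, ties.method = "min")
    df$compartment_rank <- stats::ave(-df$degree, df$compartment,
                                      FUN = function(z) rank(z, ties.method = "min"))
    row.names(df) <- NULL
    structure(list(nNodes = nrow(df), nEdges = nrow(ed), degree = df),
              class = "NetworkSummary")
}

#' @export
print.NetworkSummary <- function(x, ...) {
    cat(sprintf("ceRNA network: %d nodes, %d edges\n", x$nNodes, x$nEdges))
    if (x$nNodes) {
        cat("top nodes by degree:\n")
        print(utils::head(x$degree, 5), row.names = FALSE)
    }
    invisible(x)
}

#' Score inferred triples against a planted ground truth
#'
#' @param triples inferred triple `data.frame`.
#' @param truthTriples `data.frame(lncrna_id, mirna_id, mrna_id)`.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`. Precision of an
#'   empty inference is defined as `NA`.
#' @export
scoreTriples <- function(triples, truthTriples) {
    key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id, sep = "\r")
    inferred <- unique(key(triples))
    truth <- unique(key(truthTriples))
    tp <- length(intersect(inferred, truth))
    list(precision = if (length(inferred)) tp / length(inferred) else NA_real_,
         recall = tp / length(truth),
         tp = tp, fp = length(inferred) - tp, fn = length(truth) - tp)
}
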