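# Tabular IO. Dialect: tab-separated, UTF-8, '.' decimal, no quoting; the
# gene column of expression tables is headed "gene_id". Identifiers are
# case-sensitive opaque strings; no aliasing.

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column `gene_id`; all other
#' cells numeric. Duplicate gene ids, duplicate sample ids, negative or
#' non-numeric values are rejected with an error naming the offender.
#'
#' @param path path to the TSV file.
#' @param compartment `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param isNormalized logical, whether values are normalized (default raw).
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, compartment, isNormalized = FALSE) {
    df <- .read_tsv(path)
    if (names(df)[1] != "gene_id")
        stop("first column must be 'gene_id', got '", names(df)[1], "'",
             call. = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    vals <- df[, -1, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric column(s): ", paste(names(vals)[bad], collapse = ", "),
             call. = FALSE)
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (any(m < 0)) {
        w <- which(m < 0, arr.ind = TRUE)[1, ]
        stop(sprintf("negative value at gene '%s', sample '%s'",
                     rownames(m)[w[1]], colnames(m)[w[2]]), call. = FALSE)
    }
    ExpressionMatrix(m, compartment, isNormalized)
}

#' Write an expression matrix to TSV
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeExpression <- function(x, path) {
    v <- exprValues(x)
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_tsv(df, path)
}

#' Read / write a sample annotation table
#'
#' Columns `sample_id`, `group`; groups must be drawn from
#' normal/A/AB/B/TC/tumor and sample ids must be unique. All matrices are
#' re-indexed to the annotation's sample order on load into the pipeline.
#'
#' @param path TSV path.
#' @return `data.frame(sample_id, group)`.
#' @export
readSampleAnnotation <- function(path) {
    df <- .read_tsv(path)
    validateSampleAnnotation(df)
}

#' @rdname readSampleAnnotation
#' @param ann annotation `data.frame` to validate or write.
#' @export
validateSampleAnnotation <- function(ann) {
    if (!all(c("sample_id", "group") %in% names(ann)))
        stop("annotation needs columns sample_id, group", call. = FALSE)
    ann$sample_id <- as.character(ann$sample_id)
    ann$group <- as.character(ann$group)
    if (anyDuplicated(ann$sample_id))
        stop("duplicate sample id(s): ",
             paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
                   collapse = ", "), call. = FALSE)
    bad <- setdiff(unique(ann$group), .GROUPS)
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    ann[, c("sample_id", "group")]
}

#' @rdname readSampleAnnotation
#' @export
writeSampleAnnotation <- function(ann, path) {
    .write_tsv(validateSampleAnnotation(ann), path)
}

#' Read / write a miRNA-target interaction table
#'
#' Columns `mirna_id`, `target_id`, `target_compartment` (`mRNA` or
#' `lncRNA`). Duplicate edges are rejected, as is a target annotated with two
#' different compartments.
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
readInteractionTable <- function(path) {
    validateInteractionTable(.read_tsv(path))
}

#' @rdname readInteractionTable
#' @param edges interaction `data.frame` to validate or write.
#' @export
validateInteractionTable <- function(edges) {
    need <- c("mirna_id", "target_id", "target_compartment")
    if (!all(need %in% names(edges)))
        stop("interaction table needs columns ", paste(need, collapse = ", "),
             call. = FALSE)
    edges <- edges[, need]
    for (cc in need) edges[[cc]] <- as.character(edges[[cc]])
    if (!all(edges$target_compartment %in% c("mRNA", "lncRNA")))
        stop("target_compartment must be mRNA or lncRNA", call. = FALSE)
    key <- paste(edges$mirna_id, edges$target_id, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate interaction edge(s): ",
             paste(utils::head(unique(gsub("\r", " -> ",
                                           key[duplicated(key)])), 3),
                   collapse = "; "), call. = FALSE)
    comp <- tapply(edges$target_compartment, edges$target_id,
                   function(z) length(unique(z)))
    if (any(comp > 1))
        stop("target(s) with inconsistent compartment: ",
             paste(names(comp)[comp > 1], collapse = ", "), call. = FALSE)
    edges
}

#' @rdname readInteractionTable
#' @export
writeInteractionTable <- function(edges, path) {
    .write_tsv(validateInteractionTable(edges), path)
}

#' Read / write a clinical outcome table
#'
#' Columns `sample_id`, `time` (non-negative, days), `event` (1 = death
#' observed, 0 = censored).
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
readClinicalTable <- function(path) {
    validateClinicalTable(.read_tsv(path))
}

#' @rdname readClinicalTable
#' @param clin clinical `data.frame` to validate or write.
#' @export
validateClinicalTable <- function(clin) {
    need <- c("sample_id", "time", "event")
    if (!all(need %in% names(clin)))
        stop("clinical table needs columns ", paste(need, collapse = ", "),
             call. = FALSE)
    clin <- clin[, need]
    clin$sample_id <- as.character(clin$sample_id)
    if (anyDuplicated(clin$sample_id))
        stop("duplicate sample id(s) in clinical table", call. = FALSE)
    if (any(!is.finite(clin$time)) || any(clin$time < 0))
        stop("time must be finite and >= 0", call. = FALSE)
    if (!all(clin$event %in% c(0, 1)))
        stop("event must be 0 or 1", call. = FALSE)
    clin
}

#' @rdname readClinicalTable
#' @export
writeClinicalTable <- function(clin, path) {
    .write_tsv(validateClinicalTable(clin), path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, `name<TAB>description<TAB>
#' member1<TAB>member2...`.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                    vapply(parts, `[`, character(1), 1L))
}

#' Export a ceRNA network for Cytoscape and igraph
#'
#' Writes (a) a SIF edge file with interaction types `lncRNA-miRNA` and
#' `miRNA-mRNA`, (b) a GraphML file carrying node attributes (compartment,
#' regulation direction, degree), and (c) node/edge attribute TSVs. Each
#' triple contributes its two edges; duplicate edges across triples are
#' collapsed.
#'
#' @param triples triple `data.frame` from [assembleTriples()].
#' @param nodeAttrs optional `data.frame(id, compartment, direction)`; derived
#'   from the triples when omitted.
#' @param pathPrefix output prefix; writes `<prefix>.sif`, `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return named character vector of the four paths, invisibly.
#' @export
writeNetwork <- function(triples, nodeAttrs = NULL, pathPrefix) {
    paths <- c(sif = paste0(pathPrefix, ".sif"),
               graphml = paste0(pathPrefix, ".graphml"),
               nodes = paste0(pathPrefix, "_nodes.tsv"),
               edges = paste0(pathPrefix, "_edges.tsv"))
    if (is.null(triples) || nrow(triples) == 0L) {
        warning("empty triple set: writing empty network files")
        writeLines(character(), paths["sif"])
        g <- igraph::make_empty_graph(directed = FALSE)
        igraph::write_graph(g, paths["graphml"], format = "graphml")
        .write_tsv(data.frame(id = character(), compartment = character(),
                              direction = character(), degree = integer()),
                   paths["nodes"])
        .write_tsv(data.frame(source = character(), interaction = character(),
                              target = character()), paths["edges"])
        return(invisible(paths))
    }
    ed <- networkEdges(triples)
    .write_tsv(ed, paths["edges"])
    writeLines(paste(ed$source, ed$interaction, ed$target, sep = "\t"),
               paths["sif"])

    summ <- summarizeNetwork(triples)
    nodes <- summ$degree
    if (!is.null(nodeAttrs)) {
        dir <- nodeAttrs$direction[match(nodes$id, nodeAttrs$id)]
        nodes$direction <- ifelse(is.na(dir), "ns", dir)
    } else {
        dir <- triples$mirna_direction[match(nodes$id, triples$mirna_id)]
        nodes$direction <- ifelse(is.na(dir), "ns", dir)
    }
    nodes <- nodes[, c("id", "compartment", "direction", "degree")]
    .write_tsv(nodes, paths["nodes"])

    g <- igraph::graph_from_data_frame(
        ed[, c("source", "target", "interaction")],
        directed = FALSE, vertices = nodes)
    igraph::write_graph(g, paths["graphml"], format = "graphml")
    invisible(paths)
}

#' Read back a SIF file written by [writeNetwork()]
#'
#' @param path SIF path.
#' @return `data.frame(source, interaction, target)`.
#' @export
readSif <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(source = character(), interaction = character(),
                          target = character()))
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    data.frame(source = parts[, 1], interaction = parts[, 2],
               target = parts[, 3], stringsAsFactors = FALSE)
}
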