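#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata
NULL

.COMPARTMENTS <- c("mRNA", "lncRNA", "miRNA")
.GROUPS <- c("normal", "A", "AB", "B", "TC", "tumor")

#' ExpressionMatrix: one RNA compartment of a cohort
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single genes-by-samples assay (`"values"`) for one RNA compartment (mRNA,
#' lncRNA or miRNA), together with a flag saying whether the values are raw
#' counts or library-size-normalized values.
#'
#' Invariants enforced by the validity method: unique, non-empty gene and
#' sample identifiers; all values finite and non-negative; raw counts must be
#' integer-valued.
#'
#' @slot compartment one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @slot isNormalized `FALSE` for raw counts, `TRUE` after normalization.
#'
#' @seealso [ExpressionMatrix()] for the constructor, [readExpression()] for
#'   reading from TSV, [normalizeCounts()] for median-of-ratios scaling.
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(compartment = "character", isNormalized = "logical")
)

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@compartment) != 1L ||
        !object@compartment %in% .COMPARTMENTS) {
        msg <- c(msg, sprintf("compartment must be one of %s",
                              paste(.COMPARTMENTS, collapse = ", ")))
    }
    if (length(object@isNormalized) != 1L || is.na(object@isNormalized)) {
        msg <- c(msg, "isNormalized must be TRUE or FALSE")
    }
    if (!"values" %in% names(assays(object))) {
        msg <- c(msg, "assay 'values' is required")
    } else {
        v <- assay(object, "values")
        if (is.null(rownames(v)) || anyDuplicated(rownames(v))) {
            dup <- unique(rownames(v)[duplicated(rownames(v))])
            msg <- c(msg, sprintf("gene ids must be unique (duplicated: %s)",
                                  paste(utils::head(dup, 3), collapse = ", ")))
        }
        if (is.null(colnames(v)) || anyDuplicated(colnames(v))) {
            msg <- c(msg, "sample ids must be present and unique")
        }
        if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
        else if (any(v < 0)) msg <- c(msg, "values must be non-negative")
        else if (isFALSE(object@isNormalized) &&
                 max(abs(v - round(v))) > 1e-8) {
            msg <- c(msg, "raw counts must be integer-valued")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes-by-samples matrix with row and column names.
#' @param compartment `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param isNormalized logical; `FALSE` (default) means raw counts.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, "mRNA")
#' compartment(em)
#' @export
ExpressionMatrix <- function(values, compartment, isNormalized = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(values = values))
    new("ExpressionMatrix", se,
        compartment = as.character(compartment),
        isNormalized = isNormalized)
}

#' @rdname ExpressionMatrix
#' @param object,x an `ExpressionMatrix`.
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname ExpressionMatrix
#' @export
setMethod("compartment", "ExpressionMatrix", function(x) x@compartment)

#' @rdname ExpressionMatrix
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname ExpressionMatrix
#' @export
setMethod("isNormalized", "ExpressionMatrix", function(x) x@isNormalized)

#' @rdname ExpressionMatrix
#' @export
exprValues <- function(x) assay(x, "values")

#' @rdname ExpressionMatrix
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix (%s, %s): %d genes x %d samples\n",
                object@compartment,
                if (object@isNormalized) "normalized" else "raw counts",
                nrow(object), ncol(object)))
})

#' DEResult: one differential-expression contrast
#'
#' Per-gene negative-binomial Wald statistics for one tumor-subtype-versus-
#' reference contrast. The table has one row per tested gene with columns
#' `gene_id`, `base_mean`, `log2fc`, `se`, `wald_z`, `p`, `fdr`, `direction`
#' (`up`/`down`/`ns` at the calling thresholds stored in `fdrMax`/`lfcMin`).
#'
#' @slot contrast label such as `"A_vs_normal"`.
#' @slot table the per-gene `data.frame`.
#' @slot fdrMax,lfcMin thresholds used for the stored `direction` calls.
#' @seealso [nbWaldDE()], [callDegs()], [intersectContrasts()]
#' @export
setClass("DEResult",
    representation(contrast = "character", table = "data.frame",
                   fdrMax = "numeric", lfcMin = "numeric")
)

setValidity("DEResult", function(object) {
    msg <- character()
    need <- c("gene_id", "base_mean", "log2fc", "se", "wald_z", "p", "fdr",
              "direction")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, sprintf("table must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@table$gene_id))
            msg <- c(msg, "one row per gene required")
        p <- object@table$p
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "p values must lie in [0, 1]")
    }
    if (length(object@contrast) != 1L) msg <- c(msg, "single contrast label")
    if (length(msg)) msg else TRUE
})

#' @rdname DEResult-class
#' @param x,object a `DEResult`.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname DEResult-class
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname DEResult-class
#' @export
setGeneric("contrastName", function(x) standardGeneric("contrastName"))

#' @rdname DEResult-class
#' @export
setMethod("contrastName", "DEResult", function(x) x@contrast)

#' @rdname DEResult-class
#' @export
setMethod("show", "DEResult", function(object) {
    tab <- object@table
    cat(sprintf("DEResult %s: %d genes, %d up / %d down (FDR<%g, |log2FC|>%g)\n",
                object@contrast, nrow(tab),
                sum(tab$direction == "up"), sum(tab$direction == "down"),
                object@fdrMax, object@lfcMin))
})
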