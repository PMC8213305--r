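# Reusable statistics: the hypergeometric shared-miRNA tail, BH FDR,
# Wilcoxon rank-sum, correlation tests and a generic over-representation
# test built on the same hypergeometric machinery.

.logsumexp <- function(lx) {
    m <- max(lx)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(lx - m)))
}

#' Hypergeometric shared-miRNA enrichment test
#'
#' Upper-tail probability that an lncRNA and an mRNA share at least the
#' observed number of targeting miRNAs, given the sizes of their target sets
#' and the miRNA universe:
#' \deqn{p = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}
#'   {\binom{N}{n}}}
#' with `N` the universe size, `K` the number of miRNAs targeting the mRNA,
#' `n` the number targeting the lncRNA and `c` the number shared. The sum is
#' accumulated in log space via `lchoose` so that large universes cannot
#' overflow; the result is exact (no continuity approximation).
#'
#' @param N,K,n,c non-negative integers with `K <= N`, `n <= N`,
#'   `c <= min(K, n)`.
#' @return an object of class `"htest"` with `statistic` (the shared count
#'   `c`) and `p.value`.
#' @examples
#' hypergeomSharedMirnaP(N = 40, K = 1, n = 1, c = 1)$p.value  # 1/40
#' @export
hypergeomSharedMirnaP <- function(N, K, n, c) {
    for (v in list(N, K, n, c))
        if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
            stop("N, K, n, c must be single non-negative integers",
                 call. = FALSE)
    if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
    if (c > min(K, n)) stop("c must not exceed min(K, n)", call. = FALSE)
    upper <- min(K, n)
    if (c == 0) {
        p <- 1
    } else {
        i <- c:upper
        lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
        p <- min(1, exp(.logsumexp(lp)))
    }
    structure(list(statistic = c(shared = c), p.value = p,
                   parameter = c(N = N, K = K, n = n),
                   method = "hypergeometric shared-miRNA enrichment test",
                   data.name = sprintf("N=%d, K=%d, n=%d, c=%d", N, K, n, c)),
              class = "htest")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement; output in the input
#' order. Delegates to [stats::p.adjust()] after validating the domain.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return q-values, same length and order as `p`.
#' @export
bhFdr <- function(p) {
    if (!length(p)) return(numeric())
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the pooled size is at most 12 and the data are
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction. Delegates to [stats::wilcox.test()] with the mode
#' chosen by that rule.
#'
#' @param x,y non-empty numeric vectors.
#' @return an `"htest"` with the rank-sum statistic and two-sided p.
#' @export
wilcoxonRankSum <- function(x, y) {
    if (!length(x) || !length(y))
        stop("both samples must be non-empty", call. = FALSE)
    pooled <- c(x, y)
    exact <- (length(pooled) <= 12L) && !anyDuplicated(pooled)
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
}

#' Correlation coefficient with p-value
#'
#' Pearson (default) r with a two-sided p from the t distribution on n - 2
#' degrees of freedom, or Spearman rank correlation. Constant vectors make
#' the coefficient undefined and are rejected.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return an `"htest"` with `estimate` (r) and `p.value`.
#' @export
corTest <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must have equal length",
                                     call. = FALSE)
    if (length(x) < 3) stop("need at least 3 paired observations",
                            call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined for a constant vector", call. = FALSE)
    suppressWarnings(stats::cor.test(x, y, method = method,
                                     alternative = "two.sided"))
}

#' Over-representation test for gene sets
#'
#' Generic functional enrichment over user-supplied annotation sets (e.g.
#' parsed from GMT via [readGmt()]): for each term, the upper-tail
#' hypergeometric probability of the observed query/term overlap given the
#' universe, reusing [hypergeomSharedMirnaP()] with `N = |universe|`,
#' `K = |term ∩ universe|`, `n = |query|`, `c = |term ∩ query|`, followed by
#' BH adjustment across terms.
#'
#' @param query character vector of genes of interest (subset of `universe`).
#' @param termSets named list of character vectors.
#' @param universe character vector, the background gene population.
#' @return `data.frame(term, k, K, n, N, p, q)` sorted by `p` ascending,
#'   ties broken by term label.
#' @export
overrepresentationTest <- function(query, termSets, universe) {
    if (!length(query) || !length(universe))
        stop("query and universe must be non-empty", call. = FALSE)
    universe <- unique(as.character(universe))
    query <- unique(as.character(query))
    extra <- setdiff(query, universe)
    if (length(extra))
        stop("query genes absent from universe: ",
             paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
    if (is.null(names(termSets)) || !length(termSets))
        stop("termSets must be a non-empty named list", call. = FALSE)
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(termSets), function(tn) {
        term <- intersect(unique(termSets[[tn]]), universe)
        K <- length(term)
        k <- length(intersect(term, query))
        p <- if (K == 0) 1 else hypergeomSharedMirnaP(N, K, n, k)$p.value
        data.frame(term = tn, k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhFdr(out$p)
    out[order(out$p, out$term), , drop = FALSE]
}
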