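# End-to-end planted-truth recovery used by several suites: simulate a
# cohort, run DE per subtype, intersect, infer ceRNA pairs and triples,
# score against the planted triples.

runTripleRecovery <- function(cfg) {
    d <- simulateDataset(cfg)
    ann <- d$annotation
    filt <- lapply(d[c("mRNA", "lncRNA", "miRNA")], filterLowExpression)
    subtypes <- intersect(c("A", "AB", "B", "TC"), unique(ann$group))
    inter <- lapply(filt, function(m) intersectContrasts(
        lapply(subtypes, function(s) suppressWarnings(nbWaldDE(m, ann, s)))))
    normed <- lapply(filt, normalizeCounts)
    tumor <- ann$sample_id[ann$group != "normal"]
    pairs <- findCernaPairs(inter$lncRNA$gene_id, inter$mRNA$gene_id,
                            inter$miRNA$gene_id, d$interactions,
                            normed$lncRNA, normed$mRNA, tumor)
    triples <- suppressWarnings(assembleTriples(
        pairs, data.frame(gene_id = inter$miRNA$gene_id,
                          direction = inter$miRNA$direction,
                          stringsAsFactors = FALSE)))
    c(scoreTriples(triples, d$truth$true_triples),
      list(pairs = pairs, triples = triples, data = d, inter = inter))
}
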