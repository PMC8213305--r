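# ceRNAnet

Discovery of lncRNA–miRNA–mRNA **competing endogenous RNA (ceRNA)**
modules from bulk tumor expression cohorts, and scoring of their
prognostic value — built for cohorts with several histological subtypes
(the motivating application is thymic epithelial tumors: subtypes A, AB,
B and TC versus normal thymus), but generic over any multi-subtype
design.

A ceRNA pair is a lncRNA and an mRNA that compete for the same miRNAs.
The package calls a pair when

1. the number *c* of shared targeting miRNAs is hypergeometrically
   enriched given the target-set sizes *K*, *n* and the differential
   miRNA universe *N*:

   $$p = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}} < .05$$

2. the two transcripts are positively co-expressed across tumor samples
   (Pearson r ≥ 0.4, p < .05 on log2 normalized expression).

Around this core: subtype-wise negative-binomial Wald differential
expression (median-of-ratios normalization, moments dispersion, IRLS)
with FDR < 0.25 and |log2FC| > 1 intersected across all subtypes;
expansion of passed pairs into per-miRNA triples; network export
(SIF/GraphML); external-cohort Wilcoxon validation; and per-module
survival scoring — multivariate Cox risk score, median-split
Kaplan–Meier with log-rank, and cumulative/dynamic time-dependent
ROC/AUC at a 5-year horizon. A synthetic-cohort generator with planted
triples and survival effects provides ground truth for every stage.

## Worked example

```r
library(ceRNAnet)
d   <- simulateDataset(simConfig(seed = 7))   # planted ground truth
res <- runPipeline(pipelineConfig(seed = 7), data = d, outDir = "results")

res$network
#> ceRNA network: 27 nodes, 18 edges
#> top nodes by degree:
#>        id compartment degree rank compartment_rank
#>  MIR_0001       miRNA      2    1                1
#>  MIR_0002       miRNA      2    1                1
#>  ...

scoreTriples(res$triples, d$truth$true_triples)
#> $precision  1      $recall  0.9      (9 TP, 0 FP, 1 FN)

res$modules[[1]]$fit
#> ceRNA module LNC_0001 | MIR_0001 | MR_0001
#> Cox PH fit (converged)
#>              beta        se         z            p        HR
#> lncrna  0.3117169 0.1649937  1.889265 0.0588562915 1.3657680
#> mirna  -0.5731101 0.1687420 -3.396370 0.0006828604 0.5637694
#> mrna    0.3222665 0.1811914  1.778597 0.0753059091 1.3802526
#> median-split log-rank: chisq = 30.823, p = 2.83e-08

res$modules[[1]]$roc
#> time-dependent ROC at t* = 1825: AUC = 0.776 (129 cutoffs)
```

Reading: 9 of the 10 planted triples are recovered with no false
positives; the survival-planted module's miRNA carries a protective
coefficient (its expression is negated in the planted hazard), the
median split separates survival decisively, and the risk score
discriminates 5-year outcomes with AUC 0.78.

The same pipeline runs from TSV files on disk (expression matrices,
sample annotation, miRNA-target edges, clinical table) through a YAML
config — see `?runPipeline`, `?readPipelineConfig` and the thin CLI
wrapper in `inst/scripts/cerna.R` (`simulate` and `run` subcommands).
The methods vignette (`vignettes/ceRNA-pipeline.Rmd`) documents the
model, every tunable threshold and the generator's design.

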