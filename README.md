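# homeoDivergence

Expression divergence of retained homeolog triplets under cold stress.

Hexaploid *Camelina sativa* keeps three homeologous copies of most genes,
one per subgenome. Given a gene-level RNA-seq count matrix (control vs
cold, replicated), a syntelog triplet map (one diploid anchor gene → three
camelina copies), and gene lengths, this package answers two questions per
triplet:

* **Dominance under control conditions** — rank the copies by mean FPKM;
  Class 1 if the top copy beats both others (NB exact test *p* < 0.01 and
  FPKM fold change > 2), Class 2 if the top two each beat the third,
  Class 3 if all three pairwise fold changes are < 1.5; otherwise
  unclassified.
* **Cold-response divergence** — a copy is cold-induced when log2FC > 1
  and *p* < 0.01 (up only); triplets with 3/2/1 induced copies are
  Type 1/2/3. Within Type 1, copies are ranked by inducibility
  (FPKM ratio cold/control, 0.1 pseudo-count) and a triplet is flagged
  *divergent* when rank-1/rank-3 ≥ 2.

The differential test is a two-group negative-binomial exact test with a
common dispersion φ (variance μ + φμ²) estimated by conditional maximum
likelihood after quantile-equalizing effective libraries (TMM-normalized):
conditional on a gene's total T, the two-sided p-value sums all splits no
more likely than the observed one. At φ = 0 it reduces to the binomial
test. Around this core the package provides FPKM/TPM computation, TMM
factors, a thresholded Pearson coexpression network (TPM > 1, top 20%
variable genes, r > 0.7, Leiden modules), hypergeometric term enrichment,
a publication-style summary report, and a negative-binomial simulator that
plants presence categories, dominance classes, induction types and
divergent-inducibility spreads as recorded truth.

## Worked example

```r
library(homeoDivergence)

cfg <- SimulationConfig(nTriplets = 500, nSingletons = 200,
                        dispersion = 0.05, seed = 101)
out <- runPipeline(cfg)

out$model
#> DispersionModel: phi = 0.0521 over 4 samples
out$report$de
#> $nGenes 1700  $nUp 111  $nDown 2
str(out$report$presence$counts)
#> $ 3: int 359   $ 2: int 32   $ 1: int 38   $ 0: int 71
str(out$report$classes)
#> $ class1: int 95  $ class2: int 54  $ class3: int 81  $ unclassified: int 270
out$report$coldTypes$counts
#> type1 type2 type3
#>    12    15    35
out$report$upRegulated
#> $nUp 111  $nUpInTriplets 101  $percentUpInTriplets 91
head(as.data.frame(out$classification)[, c("presence", "class", "fc12", "fc13", "fc23")], 4)
#>          presence        class     fc12     fc13     fc23
#> ANC00001        3 unclassified 1.535963 1.631899 1.062460
#> ANC00002        3 unclassified 1.035830 1.616965 1.561033
#> ANC00003        3       class3 1.010572 1.031621 1.020829
#> ANC00004        3       class3 1.078677 1.286017 1.387197
```

Reading: the dispersion estimate (0.052) recovers the planted 0.05; 111
genes are called up under cold, 101 of them inside triplets; 359 of 500
triplets express all three copies, and among classified triplets one-copy
dominance (class1, 95) and balanced expression (class3, 81) both occur.
Per-triplet rows show the pairwise FPKM fold changes behind each call —
ANC00003's copies are all within 1.04×, a clear Class 3.

Real data enters through `readCountsTSV()` (counts + sample sheet),
`readTripletMap()`, and `readGeneLengths()` / `geneLengthsFromGFF()`;
the stage functions (`tmmFactors`, `estimateCommonDispersion`, `deTest`,
`classifyTriplets`, `classifyColdTypes`, `buildCoexpressionNetwork`,
`hypergeomEnrich`, `buildReport`) compose exactly as `runPipeline()` does.

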