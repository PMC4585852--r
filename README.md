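# restoreTE

Detection of translational compensation of copy-number imbalance from
paired transcriptome / translatome profiles.

## The problem

Segmental copy-number alterations (CNAs) change gene dosage wholesale.
Polysome profiling splits each sample's expression into total
cytoplasmic mRNA (the **transcriptome**, TC) and polysome-engaged mRNA
(the **translatome**, TL); their per-gene log2 difference is the
translational efficiency, `TE = TL − TC`. A gene whose TE shift
*opposes* its collinear CNA — deleted but translationally enhanced, or
gained but translationally repressed — has its protein output buffered
back toward the unaltered state. `restoreTE` finds such genes and
quantifies how pervasive the behavior is:

| CNA  | TE shift | class        |
|------|----------|--------------|
| loss | up       | RESTORE_UP   |
| gain | down     | RESTORE_DOWN |
| gain | up       | ENHANCE_UP   |
| loss | down     | ENHANCE_DOWN |

The package is aimed at groups analyzing matched aCGH/CNV and
polysome-profiling (or ribosome-profiling) panels — for example
high-risk neuroblastoma cell-line panels, where recurrent segmental
gains and losses dominate the genomic landscape.

It implements, behind Bioconductor-style S4 interfaces:

* **Copy number** — recursive circular binary segmentation with
  permutation significance (`segmentProfile`), density-mode
  re-centering (`recenterProfile`), threshold calling
  (`callSegments`), gene-level calls and cross-sample consensus
  directions (`geneCalls`, `assignGeneDirection`), recurrent-region
  scoring with a rotation null (`recurrentAberrations`).
* **Expression** — QC-flag probe filtering, quantile normalization,
  first-quartile detectability, TE computation and summaries, joint
  profile clustering (`PairedExpression`, `teMatrix`,
  `clusterProfiles`), delta-CT qPCR normalization.
* **Differential representation** — rank product with permutation PFP
  (`rankProductTest`), paired t with BH (`pairedTTest`), a SAM-style
  moderated statistic with sign-flip FDR (`samTest`), and their
  consensus (`consensusDiffrep`).
* **Compensation statistics** — classification (`restoreCalls`),
  exact binomial prevalence, Fisher enrichments, per-line one-sided
  rank-sum tests, breadth correlation, pan-cancer and protein-complex
  bootstraps, histone-family stoichiometry coordination
  (`familySignals`, `stoichiometryCv`), Kaplan–Meier / log-rank
  prognosis concordance (`restorePrognosisConcordance`).
* **Synthetic data** — `simulateStudy()` plants all of the above
  structure (recurrent CNAs, dosage + compensation, a shared
  translational program, histone stoichiometry, a survival cohort,
  catalogs) under one seed, with ground truth, so the entire chain is
  testable without any external data.

## Worked example

```r
library(restoreTE)

config <- simConfig(seed = 1)      # 2000 genes, 13 lines, defaults
result <- runPipeline(config)      # simulate + analyze (~4 min)

result$summary$class_counts
#> $RESTORE_UP    [1] 60
#> $RESTORE_DOWN  [1] 60
#> $ENHANCE_UP    [1] 28
#> $ENHANCE_DOWN  [1] 36

signif(result$summary$prevalence_p, 3)
#> [1] 4.43e-05
result$summary$wilcoxon_lines_significant_up
#> [1] 13
result$summary$coordination_lines_gt1
#> [1] 13
round(result$summary$prognosis_fraction_concordant, 2)
#> [1] 0.65
result$summary$recovery$recovery_fraction
#> [1] 1
```

Reading: of the planted compensation classes, every RESTORE gene is
recovered; RESTORE calls significantly outnumber ENHANCE calls (exact
binomial p ≈ 4e−5); in all 13 lines, lost genes show higher TE than
neutral genes (one-sided rank-sum p < 0.05); histone translatome family
sums are tighter than their transcriptome counterparts
(CV ratio > 1) in every line except the planted control; and 65% of
RESTORE genes are prognosis-concordant in the synthetic cohort.

A command-line wrapper with per-stage subcommands (`simulate`,
`segment`, `call`, `te`, `diffrep`, `classify`, `stats`,
`stoichiometry`, `prognosis`, `run-all`) is installed at
`system.file("scripts", "pipeline.R", package = "restoreTE")`.

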