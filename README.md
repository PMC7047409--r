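# finregen

Multi-omics analysis of regenerating zebrafish fin tissue, rebuilt as a
tested, reusable R pipeline. The biological setting: after caudal-fin
amputation, lineage-restricted cells (e.g. *sp7*+ osteoblasts) form the
blastema and regrow the fin. The epigenomic signature of this process is
**stable lineage-specific DNA methylation** (cell-type hypoDMRs persist
through regeneration; almost no time-course DMRs are real) combined with
**dynamic chromatin accessibility**: regeneration genes are activated
through distal elements that are hypomethylated *before* injury and gain
Tn5 accessibility during regeneration. The package implements that whole
analysis chain and a seeded synthetic multi-omics generator with a
ground-truth ledger, so every stage is validated by planted-signal
recovery.

## What is implemented

* **Methylome** — per-CpG beta-binomial Wald tests on smoothed
  (window-pooled) counts: for group *i* with pooled counts
  (*m_i*, *t_i*) and methylation level *mu_i = m_i / t_i*,

  ```
  wald = (mu1 - mu2) / sqrt(var1 + var2),
  var_i = mu_i (1 - mu_i) (1 + (t_i - 1) phi_i) / t_i
  ```

  with method-of-moments dispersion *phi*; region assembly with
  `delta = 0, minlen = 200, minCG = 5, dis.merge = 50, pct.sig = 0.5`;
  final filters p < 1e-5, ≥ 5 CpGs covered ≥ 5x per group, mean
  difference > 0.25; and the **empirical replicate-null curve** — DMR
  counts between biological replicates as the false-positive baseline
  for between-condition counts.
* **Accessibility** — Tn5 insertion-site adjustment (+4 bp on +, −5 bp
  on −), sliding-window Poisson peak calling, replicate reproducibility
  (reciprocal overlap + rank concordance), insertion counting, and
  differential accessibility (negative-binomial Wald, |log2FC| > 1,
  FDR < 0.01).
* **Transcriptome** — median-of-ratios size factors, the same NB Wald
  engine at FC > 2 / FDR < 0.05, TPM, distal-enhancer assignment
  (nearest peak > 10 kb from the TSS), accessibility–expression
  concordance.
* **Enhancer integration** — classification of gained DARs as
  regeneration-enhancer candidates (distal > 2 kb, methylation < 0.6 in
  uninjured cells, |Δ meth| < 0.25), plus the packaged reporter-assay
  table and its tally.
* **Regulatory network** — PWM scanning with exact discretized-score
  p-values (dynamic programming), binomial motif enrichment in gained
  DARs, a CENTIPEDE-style two-component EM footprint mixture (bound
  sites called at posterior > 0.95), upstream-TF selection by enrichment
  and early expression, TF → target edges through bound sites in gained
  DARs linked to upregulated nearest-TSS genes, and the CRISPR gRNA
  score
  `60·GC + 10·transcripts − 30·position + 2[pos20 = G] − 3[pos20 = A]`.
* **Synthetic data** — seeded generators for methylome (bimodal CpG
  methylation, ~80% global mCG/CG, planted stable cell-type DMRs), ATAC
  insertions (peaks, DARs, trapezoid footprints), negative-binomial
  expression (DE genes at 4 dpa, TFs rising from 1 dpa), and
  genome/GTF/PWM files with planted consensus instances — all recorded
  in a truth ledger.

## Worked example

```r
library(finregen)
res <- run_pipeline(validate_config(list(seed = 1)))
res$null_curve
res$recovery
```

With the default synthetic world (30,000 CpGs, 200 planted cell-type
DMRs of effect 0.4 at coverage 20, 60 DARs at fold 4, 40 DE genes, a
3-TF / 20-target network) this prints, among others:

```
       comparison           type p_threshold n_dmrs
 1:        pos_t0 replicate_null       1e-05      0
 ...
 8:  pos_t0_vs_t4      condition       1e-05      0
11: pos_vs_neg_t0      condition       1e-05     92
```

i.e. the paper's central qualitative result on synthetic data: the
cross-timepoint DMR count is indistinguishable from the replicate-null
baseline while the cross-cell-type count dwarfs it. The recovery block
reports planted-signal recovery per stage:

```
dmr   recall 0.985  precision 1
dar   recall 1      precision 1
de    recall 0.953  precision 1
edges recall 1      precision 0.952
```

and `res$stability$fraction_stable` is `1.0` (every called cell-type
DMR changes < 0.25 between 0 and 4 dpa), `res$hypo_fraction$fraction`
is `0.9` (gained DARs hypomethylated before injury).

A command-line interface mirrors the stages
(`simulate`, `dmr`, `dmr-null`, `atac-shift`, `peaks`, `dar`, `de`,
`enhancers`, `grna-score`, `run`), e.g.

```r
finregen_cli(c("grna-score", "--seq", strrep("G", 20),
               "--prop", "1", "--relpos", "0"))   # prints 72
```

## Conventions

All internal coordinates are 0-based half-open; conversion (GTF) happens
only at I/O boundaries. The methylC dialect is fixed as tab-separated
`chrom start end context ratio strand coverage` with CpG dyads
strand-collapsed onto the + strand cytosine. See the methods vignette
(`vignettes/finregen-methods.Rmd`) for the statistical models, tunable
parameters and known limitations.
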