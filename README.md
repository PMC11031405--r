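# proteonet

Differential proteomics with network propagation and signed term
enrichment — an R implementation of the analysis chain used to read out
nutrient-signaling (TORC1–S6K) interventions from factorial TMT
proteomics, plus a synthetic benchmark with planted ground truth so
every stage is verifiable without the deposited raw data.

**Who it is for.** Proteomics/systems-biology analysts with a
peptide-level intensity table from a factorial design (age × drug ×
genetic induction, replicated), a high-confidence protein–protein
interaction network, and term→gene annotations, who want
module-resolved functional calls ("which processes does rapamycin
regulate, and are they S6K-dependent?") rather than flat protein lists.

## The method

1. **Normalize** — log2, per-peptide z-score, rescale by the global SD
   and mean of the log2 data, so every peptide row shares the global
   moments. **Filter** proteins detected in ≥ 3 of 4 replicates in
   every design cell; **impute** the rest by kNN (k = 10); aggregate
   peptides to proteins by median.
2. **Test** — per-protein OLS on cell-mean coding; empirical-Bayes
   variance shrinkage through a scaled inverse-χ² prior
   (s²_post = (d₀s₀² + d s²)/(d₀ + d), d₀ by trigamma inversion of the
   log-variance moments); moderated t on d₀ + d df for named contrasts
   such as `EtOHvsRapa` (rapamycin vs vehicle) and `RUvsRURapa`
   (rapamycin under constitutively active S6K).
3. **Propagate** — import log2 fold changes onto the combined-score
   > 899 interaction graph and smooth, x_{t+1} = αWx_t + (1−α)x₀ with
   α = 0.5 for 26 iterations (W = D^(−1/2)AD^(−1/2)); select the top and
   bottom 5% of nodes with more than four interactions.
4. **Enrich & classify** — one-sided Fisher (hypergeometric tail) tests
   of each selection against the degree-filtered measured background,
   minimal term size 5; signed scores = −log10 p (+ up, − down);
   rule-based classes: age-related terms, S6K^CA-dependent vs
   -independent rapamycin terms (100-fold p-ratio rule),
   S6K-inhibition-induced terms, and protein-level TORC1–S6K dependence
   (changed by knockdown and rapamycin, unchanged under activation).
5. **Integrate** — restrict three datasets to their common genes,
   re-propagate and re-enrich each, and keep terms significant
   (p < 0.05) in the same direction in all three.

The synthetic generator plants a known log2 effect on one network
module of a stochastic-block-model graph, with module-aligned true
terms among size-matched decoys, peptide-level offsets, batch effects
and MCAR + intensity-dependent (MNAR) missingness — so recovery of the
planted term is a sharp end-to-end test of the whole chain.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → preprocess → differential → propagation → enrichment →
integration), each a thin script over the package functions, writing
its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential.R
Rscript analysis/04_network_propagation.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_integration.R
```

Output of the default run (seed 1; 2,000 proteins, 10 modules × 20
nodes, δ = +1 planted on module 1 for the rapamycin contrast):

```
simulated 6057 peptides / 2000 proteins x 32 samples
normalized: global mean 18.151, global sd 1.720, 2 constant rows dropped
detection filter (>=3 of 4 per cell): 1877 kept, 123 dropped
EtOHvsRapa            120 proteins with p < 0.05 (of 1877)
TORC1-S6K-dependent proteins: 17
module-1 set shift in EtOHvsRapa: median shift 4.18, p = 2.65e-13
EtOHvsRapa           coverage 94%, 10 up / 10 down of 199 eligible; 10/10 up from module 1
EtOHvsRapa           top term TERM_M01 (up, p = 6.97e-10, signed score +9.16)
classified: 2 age-related, 1 S6K^CA-dependent + 0 -independent rapamycin, 0 inhibition-induced
common genes across the three datasets: 398
  term_id direction score_ds1 score_ds2 score_ds3
 TERM_M01        up    3.9174  4.357464  3.762341
planted shared term TERM_M01 recovered: yes
```

Reading this: of 2,000 simulated proteins, 1,877 pass the every-cell
detection rule. The rapamycin contrast flags 120 proteins at p < 0.05;
after propagation the entire up-selection (10/10 nodes) comes from the
planted module, its true term `TERM_M01` is the top enriched term
(signed score +9.16, i.e. p ≈ 7e-10 in the up direction), the
p-ratio rule classifies it as S6K^CA-dependent (the effect was planted
in the uninduced stratum only), and the three-dataset integration
recovers it as the single concordantly upregulated term with
per-dataset signed scores around +4. The equivalent single call is
`run_pipeline(pipeline_config(seed = 1), out_dir = "results/run1")`,
which also writes a manifest with parameters and file checksums.

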