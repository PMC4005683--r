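# spliceArray

Splicing-index analysis of exon junction microarrays.

Junction arrays (such as the Affymetrix Human Junction Array, HJAY) carry
probes on exon bodies and on exon–exon junctions, so that for every
annotated alternative-splicing event — cassette exons, alternative 5′/3′
splice sites, mutually exclusive exons — there are probesets supporting
the *inclusion* isoform and probesets supporting the *exclusion* isoform.
`spliceArray` implements a complete two-condition analysis of such data,
for analysts who want the classical probe-level statistics as a tested,
reproducible pipeline rather than a black box:

* **Normalization**: per-array trimmed-mean scaling, probe-affinity
  (background) correction against the gene's constitutive median profile,
  correlation-based constitutive probe selection, and a per-sample
  **gene expression index** (mean of selected constitutive probes).
* **Regulated genes**: expressed if the condition-mean index ≥ 500;
  regulated if expressed in ≥ 1 condition, symmetric fold change ≥ 1.5,
  and two-sided pooled t-test p ≤ 0.05 on log2 indices.
* **Splicing caller**: per-probe splicing index
  `si(p,s) = log2(I(p,s) / index(gene(p), s))`, per-probe pooled t-tests
  on the condition contrast Δsi, **Fisher's method** per probeset
  (X = −2 Σ ln pᵢ ~ χ², 2k df, significant at p ≤ 0.01), and an event
  call requiring at least one-third (ceiling) of exclusion probesets
  *and* one-third of inclusion probesets significant, with all
  significant inclusion probesets regulated opposite to the exclusion
  consensus. For a cassette exon this is: the exclusion junction plus at
  least one of the three inclusion probesets, with opposite Δsi signs.
* **Synthetic data**: a seeded generator of HJAY-like designs (realistic
  event-type mix) and intensities from a two-isoform mixture model
  (inclusion ∝ Ψ·E, exclusion ∝ (1−Ψ)·E, constitutive ∝ E, log-normal
  probe affinities and replicate noise) with a ground-truth table, so
  null calibration and recovery are measurable.
* **ChIP-qPCR**: relative enrichment `2^(Ct_reference − Ct_sample)` with
  replicate aggregation.

## A worked example

```r
library(spliceArray)
cfg <- list(simulation = list(seed = 7, n_genes = 300))
res <- run_pipeline(cfg, "results_demo")
report_run("results_demo")
```

```
Junction-array analysis report
==============================
Regulated genes: 19
Called splicing events: 24 (18 cassette, 1 mutually exclusive, 5 alt 5'/3')

Recovery against simulated truth
  TP=24 FP=0 FN=3
  Sensitivity: 0.889
  Direction accuracy among TP: 1.000
```

The simulated 300-gene array carried 313 alternative events, ~10% of which
had a Ψ shift of ±0.3 injected in the treated condition. The caller found
24 of the 27 shifted events (misses concentrate where Ψ clips at 0 or 1
and the majority-isoform junction barely moves), called no false
positives, and got every direction right. `results_demo/` contains
`genes.tsv`, `events.tsv` (per-event calls with probeset evidence),
`summary.tsv` (regulated genes + called events by category), `events.bed`
(0-based half-open), the simulated inputs and truth tables, `run.log`,
and the resolved configuration.

Individual stages are available as plain functions
(`scale_arrays`, `correct_probe_effects`, `select_probes`,
`gene_expression_index`, `call_regulated_genes`, `splicing_index`,
`fisher_combine`, `probeset_stats`, `call_events`, ...), and
`inst/scripts/splicearray.R` offers `simulate` / `run` / `report` / `qpcr`
subcommands for shell use. See the vignette
(`vignettes/junction-array-analysis.Rmd`) for the model, its assumptions,
the calibration results and the design choices.

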