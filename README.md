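# herbdissect

Insect herbivory hits a leaf with several cues at once: mechanical
wounding, the chemistry of the insect's oral secretion, and cues from the
bacteria that secretion carries. `herbdissect` dissects an early leaf
transcriptome response into those components from a five-treatment RNA-seq
design — undamaged control, wounding (`W_W`), wounding + antibiotic-treated
oral secretion (`W_ABOS`), wounding + full oral secretion (`W_OS`,
"simulated herbivory"), and actual insect feeding — and quantifies how
faithfully simulated herbivory reproduces the real thing. It is written
for plant-defense and ecological-transcriptomics researchers who have a
count matrix and want the cue-by-cue decomposition end to end.

## What it computes

* **Cumulative-contrast pattern classification.** Three contrasts each add
  one cue (control→`W_W`, `W_W`→`W_ABOS`, `W_ABOS`→`W_OS`). A gene's
  trichotomous DEG calls (|log₂FC| > 1.5, BH-adjusted p < 0.05; mean count
  < 10 pre-filtered) form a triple over {−1, 0, +1} — one of 3³ = 27
  patterns. Non-null patterns with ≥ 300 genes are **gene modules**.
* **An internal NB Wald test**: median-of-ratios size factors,
  method-of-moments dispersions shrunk toward a fitted `φ(μ) = a₀ + a₁/μ`
  trend, per-gene IRLS, asymptotic Wald p, step-up BH.
* **Inducibility** via the relative distance plasticity index: for every
  control × treatment replicate pair, RDPI = meanₘ |xₜ − x꜀| / (xₜ + x꜀)
  over expressed genes.
* **GO functional networks**: per-module hypergeometric enrichment, top-15
  terms as nodes, edges where gene-set Jaccard J(A,B) = |A∩B|/|A∪B| > 0.2;
  intramodular connectivity C = mean of Cᵢ = 2eᵢ/(kᵢ(kᵢ−1)); extramodular
  connectivity as cross-module degree sums; module clustering by
  topological overlap TOMᵢⱼ = (lᵢⱼ + aᵢⱼ)/(min(kᵢ,kⱼ) + 1 − aᵢⱼ).
* **Actual vs simulated herbivory**: OLS of actual-feeding log₂FC on
  simulated-herbivory log₂FC (y = x means identical responses), and
  per-GO cosine similarity of signed DEG vectors.
* **A negative-binomial simulator** that plants known pattern archetypes
  (with a configurable actual-herbivory attenuation, default 0.74) and
  emits ground truth, so the whole pipeline is testable with no download.

## Worked example

```r
library(herbdissect)
res <- run_pipeline(pipeline_config(seed = 1))
res$summary
#> $total        4919      genes classified in all three contrasts
#> $pattern1     2117      no response to any cue (43.04 %)
#> $responsive   2802
#> $coverage_pct 99.96     % of responsive genes inside the 7 modules
sapply(res$modules, function(m) setNames(m$size, m$code))
#> 0/-1/0  0/1/0 0/0/-1  0/0/1  0/1/1  1/0/0 0/-1/-1
#>    402    401    400    400    400    400     398
res$truth_eval$code_accuracy
#> [1] 0.9991868
res$sim_vs_actual$global_fit[c("slope", "intercept", "r_squared")]
#> $slope 0.7379   $intercept -0.0341   $r_squared 0.9923
```

The seven recovered modules are exactly the seven planted archetypes
(wounding-specific; insect-chemistry up/down; bacteria up/down; both-cue
opposite responders), 99.9 % of genes get their true code, and the
regression of actual-herbivory fold changes on simulated-herbivory fold
changes recovers the planted attenuation (slope ≈ 0.74): simulated
herbivory reproduces the direction of the real response at ~74 % of its
amplitude. `run_pipeline(cfg, outdir = "out/")` additionally writes every
stage table (DE results, patterns, modules, RDPI, network edges/nodes,
per-GO similarity) plus a plain-text summary.

Stages are available individually — `simulate_experiment()`,
`compute_tpm()`, `nb_wald_test()`, `classify_patterns()`,
`extract_modules()`, `hypergeom_enrich()`, `build_go_network()`,
`clustering_stats()`, `topological_overlap()`, `cluster_modules()`,
`rdpi()`, `go_similarity()`, `global_fc_regression()` — and the methods
vignette (`vignettes/dissecting-herbivory-responses.Rmd`) documents the
model, parameter defaults and numerical conventions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package's full pipeline on the default synthetic
world with the given seed (simulation → QC → three cumulative contrasts →
modules → enrichment network → actual-vs-simulated similarity), logs the
headline numbers, and writes the acceptance JSON to `--out`.
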