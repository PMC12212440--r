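# macmem

Analysis of **stimulus-washout memory** in innate immune cells from count
matrices. Macrophages pulsed with interferon-gamma (IFNγ) acquire de novo
enhancer marks (H3K4me1), open chromatin, sustained interferon-stimulated
gene (ISG) expression and a rewired LPS response — and the central
analytical question is whether any of that survives removal of the
cytokine, and under which post-washout treatment (plain media, anti-IFNγ
neutralizing antibody, or the JAK1/2 inhibitor ruxolitinib). `macmem`
implements the downstream half of that study design for epigenomicists
and computational immunologists: it starts from feature-by-sample integer
count tables (CUT&Tag / ATAC peaks, RNA-seq genes) plus a sample sheet,
and produces per-feature memory calls, persistence fractions, shift
statistics and behavioral clusters — with a seeded negative-binomial
simulator carrying ground-truth archetypes so every stage is testable
without external data.

## What it computes

* **Differential induction.** Counts are modeled as negative binomial,
  $y_{is} \sim \mathrm{NB}(\mu_{is}, \phi_i)$ with
  $\mathrm{Var} = \mu + \phi\mu^2$ and $\mu_{is} = c_{ig} L_s / 10^6$
  (plain CPM normalization). Two-group contrasts use a likelihood-ratio
  test with library-size offsets and empirically moderated dispersions
  (method-of-moments estimates shrunk toward a lowess mean–dispersion
  trend, 20 prior df), $p$ from $\chi^2_1$, FDR by Benjamini–Hochberg.
  A peak or gene is *induced* when L2FC > 2 and FDR < 0.01 versus
  unstimulated (both strict), after a top-half abundance filter over the
  acute conditions.
* **Washout persistence.** An induced peak *persists* when the
  washout-vs-baseline contrast keeps L2FC ≥ 0 at FDR < 0.01; per-arm
  persistence fractions and paired Wilcoxon signed-rank shift statistics
  (exact with mid-ranked ties up to 25 pairs) quantify how each treatment
  arm erodes the marks.
* **Behavioral clustering.** Row-z-scored log2 CPM across
  baseline/acute/washout, k-means (k-means++, 50 restarts, seeded,
  deterministic), clusters auto-labeled *augment* / *persist* / *decay*
  by their washout trend.
* **Gene memory classes.** ISG persistence tiers (≥ 90 %, 20–90 %,
  < 20 % of the 8 h level), LPS inducibility (≥ 5-fold; ≥ 4-fold under
  ruxolitinib), *potentiated* (≥ 2-fold above vehicle at two contiguous
  post-LPS timepoints), *tolerized* (≤ 0.5-fold at two contiguous
  timepoints with JAK-independent induction confirmed), and basal
  set-point classes (0 h L2FC < 0.5 → unchanged).

See `vignettes/memory-analysis.Rmd` for the model, the simulator's
archetypes and every numerical choice.

## Worked example

```r
library(macmem)

sim <- simulate_peaks(peak_sim_config(n_features = 800, seed = 42))
pm  <- peak_memory(sim$counts, sim$design)
pm
#> peak_memory analysis
#>   features passing abundance filter: 629 / 800
#>   induced by ifng: 151 peaks
#>   induced by lps: 134 peaks
#>   shared (IFNg & LPS): 59 peaks
#>   persistence after washout (media): 64.9%
#>   persistence after washout (anti_ifng_ab): 41.7%
#>   persistence after washout (ruxolitinib): 9.9%
```

Reading: of 800 simulated peaks, 629 clear the acute abundance filter;
151 are called IFNγ-induced (L2FC > 2, FDR < 0.01), 59 of them shared
with LPS. Two-thirds of the induced peaks remain significantly above
baseline four days after washout in plain media, under half when the
cytokine is neutralized by antibody, and almost none under JAK blockade —
the ordering that identifies continued IFNγ→JAK/STAT signaling as the
persistence mechanism. The shift statistics and clusters from
`summary(pm)`:

```r
#> washout shift (IFNg-induced): mean L2FC = -1.12, Wilcoxon p = 7.73e-06
#> washout shift (LPS-induced):  mean L2FC = -2.33, Wilcoxon p = 3.72e-17
#> augment   decay persist
#>      18      53      80
```

The gene workflow is symmetric:

```r
gsim <- simulate_genes(gene_sim_config(n_features = 800, seed = 42))
gm   <- gene_memory(gsim$counts, gsim$design)
gm
#> gene_memory analysis (media criteria)
#>   IFNg-induced at 8 h (>= 5-fold): 82 genes
#>   persistence tiers (media): >=90%: 30, 20-90%: 13, <20%: 39
#>   LPS-inducible: 263; potentiated: 121 (elevated basal 68 / unchanged 53); tolerized: 55
```

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) ties the
stages together from a YAML config and writes counts/design/truth tables,
per-contrast TSVs, BED files of induced and persistent peaks, a JSON
summary and a manifest recording seeds, thresholds and every configurable
mode.

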