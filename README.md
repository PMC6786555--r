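# bloodconcord

Concordance analysis of blood-collection / RNA-preservation platforms on
two-color expression microarrays.

## The problem

Whole-blood transcriptomics depends heavily on how blood is collected and
the RNA stabilized: commercial stabilization tubes (PAXgene, RNAgard) and
PBMC separation into Trizol each perturb the measured profile *ex vivo*.
For study design the decisive question is whether a platform preserves
**between-individual** expression differences above its own technical
noise. `bloodconcord` answers it with a per-platform signal-to-noise
statistic on technical replicates:

```
S/N = mean Pearson r over within-donor sample pairs
      -----------------------------------------------
      mean Pearson r over across-donor sample pairs
```

computed on normalized M values (`M = log2 R − log2 G` against a
universal reference channel). S/N = 1 means replicates of one person look
no more alike than samples from different people; higher is better.

Around that statistic the package implements the full analysis chain:

* **Normalization** — per-array M-A transform, within-array loess of M on
  A (degree 1, tricube, span 0.3, 4 robustifying iterations),
  across-array quantile normalization of M, duplicate-probe averaging,
  optional variance filter.
* **Concordance** — pairwise sample correlations, S/N per platform,
  sample PCA (probe-centered, unscaled).
* **Probe metrics** — per-probe within-donor variance, donor-effect ANOVA
  p-value, mean absolute replicate fold difference, and per-probe paired
  t-tests between platforms; Pearson correlations of all of these with
  probe properties (GC%, transcript/gene size, distance to transcript
  ends, meanM, meanA) with p < 0.01 flags.
* **Selection + enrichment** — top-variance genes, genes relatively
  higher in one platform (p < 0.05, signed), and a local hypergeometric
  over-representation test with BH FDR (a documented stand-in for
  DAVID-style tools; its FDRs are not numerically comparable to DAVID's).
* **Synthetic data** — a generator emulating the 8-donor × 3-platform
  (3/2/3 replicates, 64 arrays) study design with known probe baselines,
  donor effects, platform offsets, intensity-dependent dye bias, and
  GC-linked replicate noise, so every stage can be validated against
  ground truth.

Annotation coordinates (`Dist3`, `Dist5`) are 0-based nucleotide offsets
with `Dist3 + Dist5 + probe length = TranscriptSize`.

## Worked example

```r
library(bloodconcord)

cfg <- simulation_config(seed = 1L)   # the emulated study design
st  <- simulate_study(cfg)            # simulate + normalize
concordance_table(st$expr)
```

```
     platform mean_within_donor_correlation mean_across_donor_correlation
1     RNAgard                        0.9442                        0.8744
2     PAXgene                        0.9448                        0.8876
3 PBMC_Trizol                        0.9412                        0.9052
  sn_ratio n_within_pairs n_across_pairs
1   1.0798             24            252
2   1.0644              8            112
3   1.0397             24            252
```

Replicates of the same donor correlate at ~0.94 on every platform, but
the platforms differ in how much *individual* signal survives: the
generator attenuates donor effects by `alpha = (1.0, 0.9, 0.7)` across
the three platforms, and the S/N ratios (1.0798 > 1.0644 > 1.0397)
recover exactly that ordering. Pair counts are the combinatorial
expectations from the design (e.g. 8 donors × C(3,2) = 24 within pairs).

The probe-property fingerprint of degradation-like noise:

```r
m  <- within_platform_metrics(st$expr, "RNAgard")
pc <- correlate_with_properties(m, st$annotation)
subset(pc, measure == "Var" &
           property %in% c("Dist3", "TranscriptSize", "GCpercent"))
```

```
  measure       property    n       r     p significant
1     Var          Dist3 2000  0.0039 0.861       FALSE
3     Var TranscriptSize 2000 -0.0146 0.515       FALSE
5     Var      GCpercent 2000  0.7721 0.000        TRUE
```

The generator links replicate noise to GC content (`kappa = 0.3` by
default) and to nothing else; the correlation table flags exactly the
GC column as significant.

`run_pipeline(outdir, sim_config = cfg)` runs every stage and writes the
per-stage TSVs, PCA and variance-vs-GC figures, and a JSON + Markdown
report (schema-validated against `inst/extdata/report-schema.json`);
outputs are byte-identical for a fixed seed. The same pipeline runs on
real data via `sim_config = NULL` with `intensity_dir`, `sample_sheet`
and `annotation` paths — intensity tables are accepted either as the
package's plain TSV or Feature-Extraction-style columns
(`rMedianSignal`/`gMedianSignal`).

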