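# TADomics

TADomics integrates multi-omics measurements of the same samples — DNA
methylation beta values, mutation allele frequencies, expression counts —
into a single event × sample matrix on a common [0,100] scale, maps every
event onto topologically associating domains (TADs), and asks two
questions: *which events differ between two sample groups*, and *which
TADs concentrate more of those differences than chance allows*. It is
aimed at regulatory-genomics analyses where the 3D organisation of the
genome, rather than single genes, is the unit of interpretation: a TAD
that accumulates coordinated methylation and expression changes is a
candidate regulatory neighbourhood.

## The statistics at the core

* **Scaling.** Frequency layers are kept (or clamped) on [0,100]; count
  layers are transformed per sample j as
  `x_ij = ln(1 + c_ij) · 100 / max_i ln(1 + c_ij)`, so the most expressed
  event of every sample sits at 100.
* **Event level.** For a binary contrast, each event gets
  `logFC = mean₁ − mean₀` on the common scale and a moderated t statistic:
  the pooled variance `s²_g` (df `d_g = n₀+n₁−2`) is shrunk toward an
  empirical-Bayes prior `(d₀, s₀²)` estimated from all events by moment
  matching on `log s²` with a Newton inverse-trigamma solve,
  `s̃² = (d₀s₀² + d_g s²_g)/(d₀+d_g)`, `t = logFC / √(s̃²(1/n₀+1/n₁))`
  on `d₀+d_g` df, Benjamini–Hochberg across events. Significant means
  `adj.P.Val < 0.01` and `|logFC| ≥ 2` (both configurable).
* **TAD level.** With `N` TAD-assigned testable events, `K` of them
  significant, a TAD holding `n` events (`k` significant) is scored with
  the upper-tail hypergeometric `P(X ≥ k)`, `X ~ Hyp(N, K, n)`, plus an
  *activation* score — the mean |logFC| of its expression events. A TAD
  is called when `hyper_p < 0.01` and `activation ≥ 2`.
* **Functional analysis.** Local hypergeometric over-representation of
  significant-event genes against GMT gene sets, a per-(term, TAD)
  hypergeometric that localises enriched terms to domains, and PWM motif
  enrichment (log2-odds scanning of both strands, one-sided Fisher test
  of foreground vs background hit counts).

## Worked example

Everything below runs offline: the synthetic generator writes a complete
input bundle (methylation + expression tables, TAD BED, GTF, metadata)
with a known planted truth — here 3 of 50 TADs shifted by 30 scale units
in group 1.

```r
library(TADomics)

bundle <- generateBundle("demo", nTads = 50, eventsPerTad = 20,
                         nPlantedTads = 3, effect = 30, seed = 7)
layers   <- loadOmicsDir(bundle$freqDir, bundle$countsDir)
segments <- readSegments(bundle$tads)
agg <- buildAggregatedTable(layers, segments, bundle$gtf)
agg
#> TADExperiment: 1000 events x 40 samples
#>   sources: methylation.txt (freq), expression.txt (count)
#>   TAD-assigned events: 1000 / 1000 (50 TADs)

meta   <- readSampleMeta(bundle$meta)
events <- eventDiffRun(agg, meta, "group")
sum(events$significant)
#> [1] 59

tads <- tadDiffRun(agg, events, "group")
head(tads[, c("tad_id", "n_events", "n_sig", "hyper_p",
              "activation", "significant")], 5)
#>    tad_id n_events n_sig      hyper_p activation significant
#> 1 TAD0001       20    20 8.231825e-27  28.718847        TRUE
#> 2 TAD0032       20    20 8.231825e-27  28.559686        TRUE
#> 3 TAD0018       20    19 3.881305e-24  29.142603        TRUE
#> 4 TAD0002       20     0 1.000000e+00   1.386749       FALSE
#> 5 TAD0003       20     0 1.000000e+00   1.488147       FALSE

scoreRecovery(bundle$truth, tads)
#> $sensitivity
#> [1] 1
#> $false_calls
#> [1] 0
```

Of the 1,000 events, 59 pass the event-level thresholds — almost exactly
the 60 planted ones — and the three planted TADs are recovered with no
false TAD call: their hypergeometric p-values are vanishingly small and
their activation (~29) sits near the planted 30-unit shift, while null
TADs stay near activation 1–1.5, far below the threshold of 2.

Passing `outDir =` to the same functions writes the standard file suite
(`integrated-table.csv`, `integrated-tad-table.csv`, `summary.txt`,
`<contrast>_evenDiff.txt`, `<contrast>_TADiff.txt` and their summaries).
The same pipeline is scriptable through the CLI launcher installed at
`system.file("scripts", "tadomics", package = "TADomics")`, with
subcommands `simulate`, `integrate`, `evendiff`, `taddiff`, `enrich` and
`plot`.

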