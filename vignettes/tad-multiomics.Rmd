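---
title: "TAD-aware multi-omics integration and differential analysis"
author: "TADomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-aware multi-omics integration and differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Different omics assays measure the same samples on incommensurable scales:
DNA methylation as beta values in [0,1], mutation burden as variant-allele
frequencies, transcription as read counts spanning five orders of
magnitude. Joint analysis of such layers is usually done gene by gene,
which discards the spatial organisation of the genome. Topologically
associating domains (TADs) — megabase-scale self-interacting chromatin
segments — are a natural aggregation unit: regulatory events inside one
TAD tend to act on the same genes. TADomics integrates several per-sample
omics tables into one event-by-sample matrix on a common scale, maps every
event to its TAD, tests events for two-group differences, and then asks
which TADs concentrate more significant events than chance allows.

## Data aggregation

Each input layer is a tab-delimited table: event id, BED-style
chromosome/start/end, then one column per sample. Layers come in two
kinds. `freq` layers are already on a frequency scale — methylation betas
(auto-detected and multiplied by 100 when the layer maximum is at most 1)
and VAFs x100; out-of-range values are clamped to [0,100] with a warning
rather than rejected, since isolated array artefacts should not kill a
run. `count` layers hold expression counts and are rescaled per sample:

$$x_{ij} = \frac{\ln(1 + c_{ij})}{\max_i \ln(1 + c_{ij})} \cdot 100 .$$

The offset inside the logarithm is a deliberate choice: a plain
$\ln(c)$ is undefined at zero counts, which are pervasive in RNA-seq, so
the package uses $\ln(1+c)$ throughout. Division by the per-sample column
maximum pins the most expressed event of each sample at 100; an all-zero
column stays zero. The transform is monotone within a column, so ranks
are preserved. Its known cost is that the column maximum is itself a
random quantity, which injects a small multiplicative sample-to-sample
jitter (well under 2 scale units in the simulated cohorts); because the
jitter is independent across samples it inflates per-event variance
slightly rather than biasing group comparisons.

Sample harmonisation supports two modes. `intersect` (default) keeps only
samples present in every layer. `union` keeps all samples and marks absent
cells `NA`; downstream statistics exclude those cells pairwise per event,
never imputing them.

Coordinates follow two conventions deliberately: everything BED-like on
disk (omics tables, TAD files) is 0-based half-open, GTF is 1-based
closed; both are converted to 1-based closed `GRanges` on load, and
"overlap" always means at least one shared base.

Gene annotation intersects events with GTF features and reports the
highest-precedence feature overlapped: `cds > exon > threeUTR > fiveUTR >
intron > promoter`, with `intergenic` for no overlap. The precedence order
is the package's own tie rule (a CpG in a first exon is better described
as exonic than promoter-proximal); when several genes overlap one event,
all ids are reported, sorted and `;`-joined, so no overlap is silently
dropped. Promoters default to [TSS−1000, TSS+200) on the annotated
strand. TAD assignment is unique per event: when segments overlap (the
segment file is not assumed disjoint), the segment with the largest
overlap wins and exact ties go to the lexicographically smallest segment
id — an arbitrary but deterministic rule for boundary-spanning events.
Events in no segment keep an empty TAD id: they stay in the table and in
the event-level statistics but are excluded from every TAD-level
computation, including the hypergeometric universe (counting untestable
events in the universe would dilute the test with rows that can never be
drawn into a TAD).

Methylation direction can optionally be aligned with activity:
`reverseMethylation()` complements (`100 − x`) freq-layer values in
selected gene features (promoter and intergenic by default, where
methylation is canonically repressive), so that high values mean "active"
across layers. The operation is an involution and is logged in its own
output file rather than applied silently.

## Event-level statistics

For a binary contrast the per-event model is the two-sample comparison on
the common scale: `logFC` is the difference of group means (so a logFC of
2 means 2 points on the 0–100 scale, not a log2 ratio), with the pooled
within-group variance $s_g^2$ on $d_g = n_0 + n_1 - 2$ degrees of
freedom. With tens of thousands of events and modest cohorts, per-event
variances are noisy; the package therefore shrinks them toward a prior
estimated from all events (empirical Bayes). Writing
$e_g = \ln s_g^2 - \psi(d_g/2) + \ln(d_g/2)$ (an unbiased estimator of
$\ln \sigma_g^2$), the prior degrees of freedom $d_0$ solve

$$\psi'(d_0/2) = \overline{(e_g - \bar e)^2}\,\frac{G}{G-1} - \overline{\psi'(d_g/2)}$$

via Newton iteration on the inverse trigamma (tolerance $10^{-8}$, at
most 50 steps; the iteration is started from the small-argument asymptote
and converges in a handful of steps everywhere we have tested). A
non-positive right-hand side means the variances disperse no more than
sampling noise predicts: the prior is infinite and the prior variance is
the plain mean of the $s_g^2$. Otherwise
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \ln(d_0/2))$. The moderated
statistic uses $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and a
t reference with $d_0 + d_g$ degrees of freedom (normal when infinite).
Zero-variance events are excluded from the prior fit but still receive a
finite moderated t, which is precisely the point of the shrinkage. The
test suite verifies this machinery against an independent scalar
re-implementation and against the reference implementation in limma.

Significance defaults to BH-adjusted p below 0.01 **and** |logFC| of at
least 2 scale units; both knobs are exposed because the adjusted-p cut
alone is also a defensible reading, and the effect-size floor only means
anything on the common scale (which is why the statistics run on the
scaled values, not layer-native ones). Events with fewer than two usable
samples in either group after `NA` exclusion are flagged and dropped from
testing and from the BH denominator.

## TAD-level statistics

With $N$ TAD-assigned testable events of which $K$ are significant, a TAD
containing $n$ events, $k$ of them significant, gets the upper-tail
hypergeometric p-value $P(X \ge k)$, $X \sim \mathrm{Hyp}(N, K, n)$. The
second criterion is *activation*: the mean of |logFC| over the TAD's
expression-source events, i.e. the phenotypic corroboration that
something transcriptional moves in that TAD. A TAD is called significant
when the hypergeometric p is below 0.01 and activation is at least 2;
TADs without expression events have activation 0 and can never be called,
a conservative choice preferred over exempting them from the criterion. A
BH-adjusted hypergeometric p is written for information but does not
enter the default call — with ~200 testable TADs the raw cut is already
stringent, and keeping it raw preserves the plain interpretability of the
two-criterion rule. Helper views (`tadSampleMeans()`,
`tadAbsDiffMeans()`) provide the per-TAD matrices used for clustering and
ordination figures.

## Functional analysis

Enrichment is computed locally from user-supplied files so runs are
reproducible offline: GMT gene sets, JASPAR-format PWMs and a genome
FASTA. Gene-set over-representation is the standard hypergeometric ORA
with the universe fixed to genes present in the aggregated table, BH
across terms. Enriched terms are then *localised*: for each (term, TAD)
pair, a hypergeometric test of the term's genes against the TAD's genes,
BH within term — which TADs carry the signal of which term. No numerical
parity with web-service enrichment tools is claimed; the statistical
content of the tests is the same.

Motif analysis extracts event sequences (point events extended ±50 bp by
default, overlapping extensions merged so no base is scanned twice;
expression events contribute their promoter windows), scans both strands
with log2-odds PWM scores — windows containing `N` are skipped — and
counts a sequence as a hit when some window reaches 80% of the motif's
maximum achievable score. Foreground versus background hit counts go into
a one-sided Fisher exact test, BH across motifs. The flank, promoter
window, hit threshold and background composition are all configurable;
the defaults are field-conventional round numbers, not fitted values.

## The synthetic cohort generator

`generateBundle()` writes a complete input set — methylation and
expression tables, TAD BED, toy GTF, metadata, and a `truth.json` with
the planted TADs/events — so every pipeline stage is testable without
downloads. It emulates a joint 450K-methylation + RNA-seq cohort at
reduced scale: 200 non-overlapping TADs of 0.2–1.5 Mb across chr1–chr22,
20 events per TAD of which 20% are transcripts (the approximate
transcript share of such cohorts), one gene per ~3 events, 20 samples per
group, and one binary contrast. Methylation betas come from a
Beta(2,5)/Beta(5,2) mixture (bimodality of real betas), counts from a
negative binomial with dispersion 0.2 (typical RNA-seq overdispersion);
neither distribution is prescribed by the method, they are documented
test scaffolding. Planted TADs shift all their events by a chosen number
of scale units in group 1 — multiplicatively on counts so the shift
survives log scaling, subtractively on betas with saturation at the
boundaries (as real methylation saturates), and with the sign flipped for
methylation to mimic the inverse coupling of methylation and expression.
What the generator does **not** emulate: co-methylation correlation
between neighbouring CpGs, LD, batch effects, or Hi-C-derived TAD
uncertainty — so passing tests demonstrate statistical correctness of the
machinery, not robustness to every pathology of real cohorts.

Test problem sizes were chosen to exercise the asymptotics that matter
while staying desk-scale: exhaustive hypergeometric enumeration to
universe size 60, 10⁴ random vectors for the BH oracle, 5,000 events for
prior recovery, 1,000 events × 100 segments for the interval oracle, and
4,000-event cohorts (200 TADs × 20 events, 20 samples per group) for the
type-I and planted-recovery properties, the latter across ten seeds.

## Degenerate inputs and numerical corners

* All-zero count columns scale to zero rather than dividing by zero.
* An all-zero variance vector is a hard error (advising variance
  filtering); isolated zero variances are handled by shrinkage.
* Hypergeometric inputs are validated (`k ≤ min(K, n)`, `n ≤ N`,
  `K ≤ N`) and inconsistencies are hard errors, not silent clamps.
* Duplicate event ids, within a file or across layers, are hard errors:
  every downstream join keys on the id.
* BH propagates `NA` p-values without counting them as tests.
* PWM columns are validated to sum to 1 (±10⁻⁶); pseudocounts are added
  at parse time so zero-count JASPAR columns stay scannable.

## Known limitations

Contrasts are strictly two-group (multi-level metadata is expanded
one-vs-rest with a warning); there is no covariate adjustment, paired
design, or count-specific mean–variance weighting. TAD calls use a raw
hypergeometric cut by design, so the TAD list's false-positive control is
per-TAD, not family-wise. The gene annotation is strand-blind except in
promoter construction and sequence extraction. Reproducing
published cohort-scale results additionally requires the original data
and the exact TAD segmentation used there; this package ships everything
needed to validate the machinery, not those inputs.
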