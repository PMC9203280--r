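---
title: "Methods: quantifying and analysing 3' UTR splicing"
author: "utr3splice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and analysing 3' UTR splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The quantity being estimated

An intron excised from within a 3' untranslated region leaves a junction
signature in RNA-seq: reads gapped exactly across the intron support
excision ("splicing-out"), while reads crossing a splice-site boundary
contiguously support retention ("splicing-in"). The splicing level of
junction $j$ in sample $s$ is the plug-in ratio

$$\mathrm{SPL}_{js} = \frac{\mathrm{out}_{js}}{\mathrm{out}_{js} + \mathrm{in}_{js}/2},$$

where $\mathrm{in}_{js}$ sums boundary-spanning reads over the donor and
acceptor sites, each requiring at least 6 aligned nt on both sides of the
boundary. Because retention is measured at two sites but excision at one,
the factor $1/2$ averages the two-site evidence: if a fraction $p$ of
transcripts is spliced and each junction yields on average $d$ informative
reads, then $E[\mathrm{out}] = pd$ and $E[\mathrm{in}] = 2(1-p)d$, so the
plug-in ratio recovers $p$ without bias. This is the only reading of the
denominator that makes it commensurate with the per-junction out count, and
it is the convention the simulator inverts exactly.

Two conventions matter downstream:

* **Missingness.** When a junction has no evidence at all in a sample
  (`out = 0`, `in = 0`), its SPL is missing, not zero — absence of coverage
  is not evidence of non-splicing. Missing cells are excluded from medians
  and quantiles and count as "not above threshold" in prevalence rules.
* **Double-spanning reads.** A single read crossing both boundaries
  contributes 2 to `in` by default (`dedupe_spanning_reads` counts it
  once). Whether such reads should count once or twice is genuinely
  ambiguous; counting twice keeps the two sites symmetric.

## Event discovery

Junctions come in as STAR `SJ.out.tab`-dialect tables (1-based inclusive
intron coordinates, converted internally to 0-based half-open;
multimapping reads excluded by default). A junction is a candidate 3' UTR
splicing event when:

1. it is **3' UTR-exclusive**: fully contained in the 3' UTR of at least
   one same-strand transcript and overlapping zero CDS and zero 5' UTR
   bases, and
2. in at least one sample — the same sample for both conditions — it has
   at least `min_reads = 2` junction reads and SPL strictly above
   `min_spl = 0.10`.

Design choices in the classifier that were genuinely open:

* **Strand of the exclusion.** Short-read junction strand is often
  ambiguous, so by default the CDS/5' UTR exclusion considers features on
  either strand (stringent); `stranded_exclusion = TRUE` restricts it to
  the intron's strand. Both are exposed because annotation-driven analyses
  differ on this point.
* **Containment, not overlap.** "Within a 3' UTR" demands full containment
  in a single transcript's 3' UTR region; mere overlap leaves the label
  `MIXED`.
* **Stop codon counts as CDS.** The 3' UTR begins immediately after the
  stop codon; an intron touching the stop codon is `MIXED`.
* **UTRs are derived, not trusted.** 5'/3' UTRs are recomputed as exon
  minus CDS(+stop) on both sides of the CDS span, so annotations without
  explicit UTR features parse identically. A transcript with CDS but no
  stop_codon feature has its stop derived from the CDS 3' end (with a
  warning).
* **Merging across samples** is exact-coordinate union; no boundary-wobble
  clustering.

A **common event (c3USP)** within a cohort has SPL strictly above 10% in a
strict majority of samples. The denominator is all cohort samples by
default (missing counts against commonness — conservative);
`denominator = "observed"` restricts it to measured samples. Per-sample
**burden** is the count of events passing the same per-sample support rule,
optionally normalized by the count of all supported splicing events in that
sample; samples with fewer than 1,000 supported junctions are flagged for
exclusion as low-depth.

## Differential splicing

Per event, tumour and matched-normal SPLs are compared with a two-sided
Mann-Whitney U test (exact enumeration when both groups have at most 8
observations and no ties; normal approximation with tie correction
otherwise — exact where desk-checkable, standard elsewhere).
Benjamini-Hochberg adjustment runs across the testable events of one
cohort; events with fewer than 3 non-missing values in any required group
are reported untestable with `NA` p and excluded from the BH family, so
they do not dilute the correction.

An event is **significant** when

* BH FDR < 0.1, and
* the median shifts against the matched normal and the reference normal
  (e.g. a healthy-tissue cohort) agree in sign (unidirectionality), and
* at least one of the two median differences strictly exceeds 5%.

When the matrix carries no reference-normal cohort the reference criteria
are waived; the rule degrades to FDR < 0.1 and |Δ| > 5%.

For very small matched designs (e.g. 4 tumour/normal pairs) the package
provides a sign-flip permutation FDR: the statistic is the median of paired
SPL differences, the null is built from all $2^n$ sign flips (or a seeded
sample when $2^n$ exceeds `n_perm`), and the per-event FDR is the mean
null count of events at or above the observed statistic divided by the
observed count, capped at 1. Two properties deserve note. First, this
construction is this package's explicit, documented choice of small-sample
procedure — a standard pooled permutation estimator — not a reimplementation
of any particular published variant. Second, at $n = 4$ pairs the median
statistic is conservative by construction: for an event whose four
differences share a sign, flipping the smallest difference leaves the
median unchanged, so at least 4 of the 16 flips tie or exceed the observed
value and the attainable FDR floor is 0.25. The sign-flip FDR at such
depths ranks events; it cannot certify FDR < 0.1 on its own.

Set-overlap enrichment (e.g. oncogene membership among upregulated events)
uses the upper-tail hypergeometric probability $P(X \ge k)$. The RBP
knockdown screen applies the same rank-test machinery per factor against
pooled controls, yielding a volcano-style table of SPL shifts.

## Over- and under-splicing calls

For each significant event, per-tumour status is called against quantile
cutoffs of the normal SPLs. Quantiles use the **nearest-rank** method (the
$\lceil pn \rceil$-th order statistic): deterministic, interpolation-free,
and well defined at small $n$. The over-splicing cutoff is the *larger* of
the matched-normal and reference-normal 90% quantiles (stringent); the
under-splicing cutoff is by default the *smaller* of the two 10% quantiles
— the symmetric, stringent rule — with `under_rule = "max"` as the
alternative, since which of the two the original convention intends is
not determinable from the rule's usual statement. All comparisons are
strict: a tumour exactly at a cutoff is `NEITHER`. Under the null
(tumours drawn from the normal distribution) the expected OVER rate is
$\approx (n - \lceil 0.9n \rceil + 1)/(n+1)$ — about 10.9% at $n = 100$
normals — which the calibration tests check within ±3 points.

## Survival

Overall survival is modelled with univariate Cox proportional hazards
(Efron tie handling) on the raw SPL in $[0,1]$, so the hazard ratio reads
per full 0-to-1 change; no standardization is applied. Events are labelled
`UNFAVOURABLE` (HR > 1, Wald P < 0.05), `FAVOURABLE` (HR < 1, P < 0.05) or
`NS`; the labels deliberately use unadjusted P values, and a BH column is
emitted alongside for transparency. Kaplan-Meier comparisons split samples
at the median SPL with ties (and the odd extra sample) going to the low
group, tested by log-rank. Degenerate covariates and non-converging fits
return `NS` with a diagnostic flag rather than failing a whole cohort.
Fits require at least 20 usable samples and 5 observed deaths.

## Event features

* **Stop-codon distance** is measured in mRNA (exonic) coordinates from the
  first nucleotide after the stop codon to the intron's donor site,
  strand-aware; across multiple containing transcripts the minimum is
  reported (conservative for NMD prediction). For an event in an unspliced
  terminal exon this equals genomic distance on the plus strand.
* **NMD prediction** applies the canonical 50-nt rule: a junction strictly
  more than 50 exonic nt downstream of the stop codon predicts
  nonsense-mediated decay; at or below it, the transcript is predicted to
  escape. The threshold is configurable; a donor 11 nt downstream — the
  geometry of the best-characterized oncogene event — escapes.
* **Repeat overlap** reports the fraction of intron bases covered by the
  union (not the sum) of overlapping repeat intervals, plus a flag for Alu
  elements (repeat name starting `"Alu"`), from RepeatMasker-style BED.
* **Long-read / annotation support** require exact donor and acceptor
  coordinate identity with an isoform model's intron — no wobble window.
  Strand is ignored for long-read identity because single-gap isoform
  models often carry unreliable strand calls; coordinates cannot collide.

## The simulator

`simulate_cohort()` generates the full input surface — annotation GTF,
per-sample SJ tables, splicing-in TSV, sample sheet, clinical table,
repeats BED, isoform models — plus ground truth, from one seed. Its
defaults are the package's reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_events` | 400 | designed junctions, one gene each |
| `frac_3utr` | 0.8 | placed in 3' UTRs (rest: CDS / 5' UTR / non-coding decoys) |
| `n_tumour`, `n_normal`, `n_reference` | 40 / 40 / 40 | cohort sizes |
| `depth_mean` | 80 | Poisson mean informative reads per event per sample |
| `baseline_spl_alpha`, `beta` | 2, 6 | Beta baseline SPLs (mean 0.25) |
| `spl_precision` | 100 | Beta concentration of per-sample variation |
| `frac_dysregulated` | 0.05 | 3' UTR events given a tumour shift |
| `delta` | +0.25 | tumour median SPL shift |
| `surv_beta` | 1.5 | log HR per unit SPL (prognostic = dysregulated events) |
| `frac_alu` | 0.4 | introns overlapped by a designed Alu |

Per event $e$ and sample $s$: the true splicing probability is drawn from a
Beta centred on the event baseline (shifted by `delta` in tumours for
dysregulated events, clipped with a warning if the shift leaves $(0,1)$);
the informative depth is Poisson; `out ~ Binomial(depth, p)` and
`in = 2(depth - out)` — the exact inverse of the SPL formula's two-site
convention, so the plug-in estimate is unbiased. Survival times are
exponential with log-hazard `surv_beta` times the mean true SPL of the
prognostic events, censored uniformly. Donor offsets downstream of the stop
codon cycle through 10/25/40/80/150 nt — most events escape the 50-nt NMD
window, as observed distributions of stop-to-junction distances
concentrate near the stop — and the first locus fixes the 11-nt geometry
exactly. All randomness flows through one seeded generator and outputs are
byte-stable per seed.

What the simulator does *not* emulate: expression covariance between
genes, read-level artefacts (mapping bias, duplicates), multi-isoform
mixtures within a locus, batch effects, and non-proportional hazards.
Passing recovery tests on simulated cohorts therefore demonstrates the
correctness and calibration of the statistical machinery under its own
assumptions, not robustness to real-data artefacts.

## Verification problem sizes

The automated checks run at sizes chosen to make their guarantees sharp
yet quick: the SPL grid is exhaustive on $[0,100]^2$; classifier
equivalence uses 1,000 random introns over a 20-transcript fixture on both
strands; null FDR calibration uses 2,000 events at 30 vs 30 over three
seeds; power/recovery uses the default 400-event, 40/40/40 simulation
(sensitivity ≥ 90% required); over-splicing calibration uses 500 tumours
against 100 normals over three seeds; Cox recovery uses 50 replicates at
$n = 300$ with true HR 4 plus 200 permuted-covariate nulls; the
common-event rule is enumerated exhaustively up to $n = 8$ samples; and
end-to-end determinism compares two complete seeded runs byte for byte
outside provenance headers.

## Known limitations

* GTF only (GENCODE dialect); GFF3 is out of scope.
* Exact-coordinate junction identity throughout; no fuzzy boundary
  matching.
* Survival is overall survival with a single covariate; no
  covariate-adjusted or competing-risk models.
* The sign-flip FDR floor at very small $n$ (above) limits small-cohort
  claims to rankings.
* The 50-nt rule is a prediction heuristic, not a measurement of decay.
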