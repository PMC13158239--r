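---
title: "Models and methods behind spliceflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflow)
```

## Scope and model

spliceflow implements the downstream layer of an event-level
alternative-splicing analysis for a two-genotype (wildtype vs mutant)
bulk RNA-seq design, of the kind used to characterise splicing defects in
*C. elegans* splicing-factor mutants.  It starts from transcript-level
abundance estimates (TPM) and event definitions over seven classes —
skipped exon (SE), retained intron (RI), alternative 5′/3′ splice site
(A5/A3), mutually exclusive exons (MX) and alternative first/last exon
(AF/AL) — and produces:

* per-event percent-spliced-in (PSI) values and condition differences
  (ΔPSI),
* per-event significance calls from a Gaussian GLM with
  Benjamini–Hochberg FDR control,
* reading-frame consequences per event,
* splice-site sequence windows, position matrices, G-test motif
  comparisons, U5/U6 interacting-position contingency classes, and
  strong/weak site-strength calls and shift categories,
* alternative-site geometry (distance, direction, 3-nt periodicity),
* cross-dataset overlap tests (Pearson chi-square) and direction
  concordance.

Upstream read processing (alignment, assembly, quantification) and
count-based differential gene expression are out of scope; the package
consumes their outputs (TPM tables, gene lists).

## PSI and the expression filter

For an event with inclusion transcript set $I$ and total set $T$
($I \subset T$), the PSI in sample $s$ is

$$\mathrm{PSI}_s = \frac{\sum_{t \in I} \mathrm{TPM}_{ts}}
                        {\sum_{t \in T} \mathrm{TPM}_{ts}},$$

set to missing when the denominator is below `min_total_tpm` (default
10): with little supporting expression the ratio is numerically unstable.
Raising the filter can only add missingness (a tested invariant).  ΔPSI is
`mean(PSI mutant) − mean(PSI wildtype)` on the 0–1 scale; positive values
mean more inclusion in the mutant.  The sign convention is stated in every
output header because the literature uses both.

## The per-event genotype model

`fit_event_glm()` fits the Gaussian-family, identity-link GLM
`PSI ~ genotype` and tests the genotype coefficient two-sided against a
t reference with $n - 2$ degrees of freedom.  For a two-level factor this
is exactly the pooled two-sample t-test, and the coefficient equals the
ΔPSI.  With three replicates per condition this is the only GLM
family/link pairing that is well calibrated without further assumptions;
logit or beta-regression variants would need dispersion modelling that
the design cannot support.  Degenerate cases follow fixed conventions:
fewer than two replicates in a condition gives a missing p-value
(excluded from the multiple-testing correction, so untestable events do
not dilute it); zero residual variance gives p = 1 when the coefficient
is zero and p = 0 otherwise.  The table-level `diff_splicing()` uses an
algebraically identical vectorised closed form (verified against the
per-event fit to 1e−12 in the tests).  Benjamini–Hochberg q-values come
from `stats::p.adjust`; significance is `q ≤ alpha` (default 0.05) with
no effect-size floor by default (a configurable floor exists).

## Reading frame

An event preserves frame when the inclusion and exclusion isoforms leave
the downstream reading frame unchanged, i.e. when the affected length —
the skipped-exon length (SE), retained-intron length (RI), or the shift
between the two variant boundaries (A5/A3) — is a multiple of 3.  MX,
AF and AL events differ in more than one local segment and are reported
`not_applicable`.  The tests check every frame call against a brute-force
oracle that sums exon lengths of the two isoforms from the annotation.

## Splice-site windows and motif statistics

All windows are read 5′→3′ in transcript orientation; minus-strand loci
are reverse-complemented.  Donor windows span positions −3..+6 around the
exon|intron boundary and acceptor windows −8..+2 — wide enough to cover
every position the motif statistics use (donor U5 positions −2,−1 and U6
positions +3..+5; acceptor consensus positions −6..+1) with one spare
flank position; widths are configurable.  The genome is held as DNA, so
the canonical *C. elegans* donor consensus GURAGU appears as GTRAG after
the boundary and the acceptor consensus UUUCAG/R as TTTCAG before it.
Windows containing N are kept but flagged and excluded from position
matrices.

Position frequency matrices count N-free windows; information content per
column is $2 + \sum_b p_b \log_2 p_b$ bits without small-sample
correction.  Motif comparison uses the likelihood-ratio G-test
$G = 2\sum O \ln(O/E)$ per position on the 2 × 4 set-by-base table, with
zero observed cells contributing 0 and bases absent from both sets
dropped with a matching df reduction; the whole-motif statistic is the
sum across positions.  U5/U6 classification calls a donor `consensus` at
U5 when positions −2,−1 read AG and at U6 when +3 ∈ {A,G}, +4 = A,
+5 = G.

## Site strength: scoring and threshold

The strong/weak dichotomy for splice sites has no standard formula; the
package operationalises it transparently and configurably.  A site's
score is the log-odds of its window under the position probability
matrix of *all annotated sites of that kind* against a uniform
background, probabilities floored at 1e−3:
$\mathrm{score} = \sum_j \log_2 (p_j(b_j) / 0.25)$ bits.  The strong/weak
threshold is derived from the annotated sites' own score distribution.
The default fits a two-component unequal-variance Gaussian mixture
(`mclust`): consensus-like sites form a narrow high mode, deviant sites a
wide low mode, and the threshold sits midway between the two classified
groups where they meet.  A plain median threshold is available
(`threshold_method = "median"`), but it labels exactly half of the
annotated sites strong by construction, and when the two modes are
unbalanced it lands *inside* a mode and mislabels sites that match the
consensus at every key position; the mixture rule does not.  The fitted
threshold is logged on every run.

Strong→weak shift categories for A5/A3 events are oriented by the
direction of usage gain in the mutant: the category reads losing-site
label → gaining-site label.  A shift is "complete" when the losing site
retains at most 5% usage in the mutant (configurable).

## Alternative-site geometry

For A5/A3 events the "original" site is the variant with the higher mean
PSI in the control condition (ties fall back to the annotation-first
variant and are logged); distances are signed in transcript orientation
(positive = downstream), measured boundary to boundary.  The 3-nt
periodicity statistic is a chi-square goodness-of-fit test of the
distance residues mod 3 against uniformity (df = 2).

## Cross-dataset overlap

Events are matched across datasets by coordinates (contig, strand, class,
coordinate tuple), never by identifier.  The default comparison universe
is events *tested* in both datasets — untested events carry no evidence —
with `universe = "all"` available.  Concurrent sensitivity is tested per
event class with Pearson's chi-square on the 2 × 2 significance table
(df = 1, no continuity correction by default; Yates correction behind a
flag).  Degenerate margins are reported as undefined rather than forced,
and any expected cell below 5 sets a `low_count` flag, since the Pearson
approximation is unreliable there.  Direction concordance compares ΔPSI
signs among events significant in both datasets; exact zeros are excluded
and counted separately.

## The simulator: what it emulates and what it does not

`simulate_splicing_dataset()` builds a toy genome in which each gene
hosts exactly one event realised by two isoforms.  Gene structures are
laid out in transcript coordinates with exons of 90–150 nt (45–120 nt
for internal variants) and introns of 47–80 nt — short introns typical
of the *C. elegans* genome — then placed on the forward or reverse
strand, so strand handling is exercised end to end.  Donor and acceptor
motifs are stamped at every junction: strong sites match the full
consensus; weak sites deviate at 1–3 key positions while always keeping
the invariant GT..AG intron ends.  Each site is strong with probability
`strong_site_fraction` (default 0.5).  A5/A3 boundary shifts are
multiples of 3 with probability `periodic_fraction` (default 0.7),
emulating the in-frame periodicity of 3′SS shifts; shifts start at 10 nt
because the two variant motif stamps would physically overlap at smaller
distances in the constructed loci.

The default study conditions are two genotypes × 3 replicates, 200 genes,
25% of events affected with |ΔPSI| = 0.3 (random sign), replicate noise
SD 0.05 on the PSI scale, and a per-event total TPM drawn lognormal
around 50 (sdlog 0.3).  PSI noise is truncated-Gaussian on the PSI scale
rather than logit-scale: it keeps the truth table directly interpretable,
and the downstream GLM is evaluated against exactly this generative
model.  No empirical estimate of replicate PSI noise is available for
this design; 0.05 is a package choice, flagged in the configuration
documentation.  Intergenic spacers and exon/intron interiors are i.i.d.
uniform ACGT.

The simulator does **not** model read-level sampling error, coverage-
dependent PSI uncertainty, correlated noise between events of one gene,
isoform complexity beyond two isoforms per gene, or background sequence
composition.  Passing recovery tests therefore demonstrates that the
statistical and sequence machinery is correct under its stated model —
not that real data meet that model.

## Numerical choices and problem sizes

Tolerances: statistical engines are compared with closed forms at 1e−9
to 1e−12; PPM column sums at 1e−9.  The test suite and the acceptance
script use 200-gene datasets for recovery and sequence properties,
1000 events for null calibration, and 100 replicate pairs of 500-event
null datasets for overlap calibration.  In the overlap calibration the
sensitivity dichotomy is taken at raw p ≤ 0.25: at a 0.05 rate the
expected co-sensitive count at 500 events is ≈ 1.25, far below the
expected-count ≥ 5 rule the Pearson approximation requires, while at
0.25 all expected cells exceed 30.  The user-facing default for real
comparisons remains q ≤ 0.05.

## Known limitations

* The strength dichotomy is an operationalisation; different scoring
  schemes (e.g. maximum-entropy models) would draw the line elsewhere.
* Frame classification ignores whether the event lies inside an
  annotated CDS.
* The GLM models genotype only; batch or covariate structure is not
  supported.
* PSI is event-level (ioe); transcript-level (ioi) quantification is not
  implemented.
* Branch-point and polypyrimidine-tract features beyond the acceptor
  window are not scanned.
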