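# spliceflow

Event-level alternative-splicing analysis for two-condition bulk RNA-seq
designs, with a synthetic-data module that makes the whole pipeline
testable against a known truth table.

## The problem

Splicing-factor mutants (the motivating system is a *C. elegans*
two-genotype design: wildtype vs mutant, three biological replicates
each) change how often individual splice sites are used.  Given
transcript abundance estimates (TPM) and definitions of
alternative-splicing events — skipped exon (SE), retained intron (RI),
alternative 5′/3′ splice site (A5/A3), mutually exclusive exons (MX),
alternative first/last exon (AF/AL) — the questions are:

* which events change, and by how much (ΔPSI)?
* do the changes preserve reading frame?
* what do the affected splice-site sequences look like (motifs, U5/U6
  interacting positions, strong vs weak sites, shift direction and 3-nt
  periodicity)?
* do two mutants affect the same splice sites, in the same direction?

## The statistics

For an event with inclusion transcripts *I* and total transcripts *T*,
per sample:

    PSI = sum(TPM[I]) / sum(TPM[T])        (missing when sum(TPM[T]) < 10)

Per event, a Gaussian GLM `PSI ~ genotype` is tested two-sided on the
genotype coefficient (t reference, n − 2 df; equivalent to the pooled
two-sample t-test, coefficient = ΔPSI = mutant − wildtype), with
Benjamini–Hochberg FDR control at 0.05.  Motif comparisons use the
likelihood-ratio G-test `G = 2 Σ O ln(O/E)`; cross-dataset overlap uses
Pearson's chi-square on the 2×2 significance table; site strength is a
log-odds score against the annotated-site motif model with a
mixture-based strong/weak threshold.  See the methods vignette
(`vignettes/spliceflow-methods.Rmd`) for every convention and its
rationale.

## Worked example

```r
library(spliceflow)

cfg <- sim_config(n_genes = 200, seed = 1)     # 25% affected, |dPSI| = 0.3
sim <- simulate_splicing_dataset(cfg)

psi <- compute_psi(sim$events, sim$tpm, min_total_tpm = 10)
ds  <- diff_splicing(psi, sim$design, events = sim$events, alpha = 0.05)
sig <- ds[ds$significant, ]
summarise_event_types(sig)
#>   event_class  n percent mean_abs_delta_psi mean_delta_psi
#> 1          A3  6    14.0              0.263         0.1250
#> 2          A5  5    11.6              0.281        -0.1724
#> 3          AF  4     9.3              0.268        -0.2682
#> 4          AL  5    11.6              0.292         0.0641
#> 5          RI 14    32.6              0.276         0.0449
#> 6          SE  9    20.9              0.297         0.0440
```

43 of 200 events are called at FDR 0.05 (the truth table planted ~50
affected events with |ΔPSI| = 0.3; the recovered mean |ΔPSI| per class is
close to 0.3 throughout).  Frame consequences and alternative-site
geometry:

```r
frames <- classify_frame(sim$events)
table(frames$frame[match(sig$event_id, frames$event_id)])
#>       in_frame not_applicable   out_of_frame
#>             11              9             23

geom <- site_distance(sim$events, psi, sim$design)
per  <- periodicity_summary(geom)
per$fraction_in_frame        # 0.606 of A5/A3 shifts are multiples of 3 nt
per$chisq                    # chi-square 23.69, df 2, p = 7.2e-06
```

The end-to-end driver writes every table (PSI, differential splicing,
frames, site windows, geometry, U5/U6 contingency, strength shifts) plus
a manifest with parameter values and file checksums:

```r
run_pipeline(sim_config(seed = 1), out_dir = "results_run")
```

A thin command-line wrapper is included at
`inst/scripts/run_pipeline.R`.

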