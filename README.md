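# decaykit

RNA degradation-rate inference from short dual-fraction 4sU
metabolic-labelling pulses, and the downstream analysis that asks whether
miRNA-dependent transcript destabilization requires translation.

## The problem

miRNAs loaded into the RNA-induced silencing complex (miRISC, marked by
AGO2 binding) can repress targets by blocking translation and by
accelerating transcript decay, and the two are thought to be coupled:
decay follows translational engagement. Cytosolic long noncoding RNAs
that are AGO2-bound but not ribosome-associated are the natural control —
if translation is required for destabilization, depleting miRNAs (e.g. by
DICER knockout, which removes ~80% of mature miRNAs) should stabilize
translated AGO2-bound mRNAs but leave untranslated lncRNAs unchanged.
Answering this needs per-gene degradation *rates* in both conditions, not
steady-state abundances.

## The model

Each gene follows first-order kinetics for premature (P, intronic signal)
and mature (M, exonic signal ∝ P + M) RNA:

    dP/dt = k1 − k2·P        dM/dt = k2·P − k3·M

with synthesis rate k1, processing rate k2 and degradation rate k3
(half-life ln2/k3). During a 4sU pulse of length t the newly synthesized
(labeled) and pre-existing RNA fractions partition the steady state
exactly; their closed forms, evaluated at the pulse times, let a nonlinear
least-squares fit recover (k1, k2, k3) per gene and condition. Library
scales are estimated from the conservation constraint
labeled + pre-existing = steady state (per gene, per pool), with a
model-based calibration of the labeled-vs-pre-existing direction that
short pulses leave weakly determined. Conditions are compared per gene by
a z-test on log rates with Benjamini–Hochberg FDR.

Around the kinetics, the package implements the rest of the analysis:
subcellular localization calls (cytosolic/nuclear expression ratio against
the expressed-mRNA median), translation efficiency
(TE = log2 RP cpm / RNA cpm, for genes with RNA cpm > 1 and > 0 footprint
reads), conserved-ORF micropeptide flagging (same-strand positive-score
overlap), AGO2 peak density per kb (3'UTRs for mRNAs, transcript spans for
lncRNAs), WT-specific CLIP cluster filtering, canonical miRNA seed-match
scanning (8mer/7mer-m8/7mer-A1/6mer), and class-level statistics
(Mann–Whitney, Fisher, chi-square, ECDFs, PCA QC).

A synthetic-data generator (`sim_config()`, `simulate_bundle()`) emulates
the full study design — four transcript classes, miRNA-dependent decay
restricted to translated AND AGO2-bound transcripts, a KO with residual
miRNA activity plus global synthesis–decay compensation,
negative-binomial count noise — so the whole pipeline is testable without
any download. See `vignettes/decaykit-methods.Rmd` for the methods.

## Worked example

The default configuration simulates the full design (2,000 genes, 10- and
15-min pulses, two replicates per condition) and takes about two minutes
on one core:

```r
library(decaykit)

rep <- run_pipeline(sim_config(seed = 1))
print(rep)
#> pipeline_report: 2000 genes, seed 1
#>   81.3% of tested genes have lower k3 in KO; 13.4% at q < 0.05
#>   pulse-concordance R2 (log10 k3): WT 0.865, KO 0.837
#>                  class    n median_log2_fc_k3 frac_q_lt_cut median_log2_fc_ss
#> 1 lncRNA_cyt_bona_fide  291        -0.1700289    0.02749141      -0.000735935
#> 2           lncRNA_nuc  459        -0.1964289    0.01525054       0.002768465
#> 3         micropeptide   50        -0.5490355    0.28000000       0.350061205
#> 4                 mRNA 1200        -0.4420644    0.19849875       0.222829872
```

Reading the output: most genes' degradation rate drops in the
miRNA-depleted condition (the global synthesis–decay compensation), but
the drop is much larger for mRNAs and micropeptide-encoding transcripts
(median log2 KO/WT about −0.44 to −0.55, i.e. stabilized) than for bona
fide cytosolic or nuclear lncRNAs (about −0.17 to −0.20) — the signature
of translation-dependent miRNA destabilization. Steady-state abundance
moves the opposite way: protein-coding classes go up when miRNAs are
lost, lncRNAs do not. Degradation rates fitted from the 10-min and
15-min pulses alone agree at R² ≈ 0.84–0.87 on the log10 scale.
`rep$tests` holds the Mann–Whitney contrasts, `rep$rates` the per-gene
rate tables, `rep$comparisons` the per-rate condition tests.

Individual stages are exported: `labeled_abundance()`,
`preexisting_abundance()`, `normalize_by_conservation()`, `fit_rates()`,
`compare_rates()`, `pulse_agreement()`, `classify_localization()`,
`translation_efficiency()`, `flag_micropeptide()`, `peak_density()`,
`wt_specific_clusters()`, `find_seed_matches()`, and the statistics layer
(`mann_whitney_u()`, `fisher_exact_2x2()`, `bh_fdr()`, `pca_qc()`, ...).

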