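# cachesense

Bacteria eavesdrop on each other through autoinducer-2 (AI-2), a
quorum-sensing signal whose known receptors (LuxP, LsrB) are missing from
most species that nevertheless respond to it. A third receptor type is the
extracytoplasmic **dCache_1** sensor domain: in *Pseudomonas aeruginosa*
the chemoreceptors PctA and TlpQ bind AI-2 through this domain, and the
AI-2-binding subfamily is marked by five jointly conserved pocket residues
— **R126, W128, Y144, D146, D173** in PctA numbering.

`cachesense` is an R package for the computational side of that analysis.
It is written for sequence-analysis and biophysics people who want to

- anchor a family multiple sequence alignment (or a single sequence, by
  pairwise alignment) to PctA reference numbering,
- screen every family member for the five-residue pocket signature
  (`k`-of-5 matching; strict residue identity, gaps and `X` count as
  mismatches),
- profile per-position conservation over the pocket region (position
  frequency matrices; information content `IC = log2(20) − H` in bits, the
  heights of a sequence logo),
- classify proteins into signal-transduction families (MCP, HK, CSP, SP,
  STK, AC/GC, CNB-only, uncharacterized) from Pfam-style domain
  architectures and roll counts up by class and phylum,
- simulate and fit **one-site ITC binding isotherms**. The forward model
  tracks the displacement dilution of a perfusion cell
  (`M_i = M_{i−1}(1 − v_i/V0)`, `L_i = L_{i−1}(1 − v_i/V0) + Ls·v_i/V0`),
  solves the binding quadratic for the complex concentration, and emits
  per-injection heats `q_i = ΔH·V0·(PL_i − PL_{i−1}(1 − v_i/V0)) +
  q_offset`. Fitting is multi-start Levenberg–Marquardt least squares over
  (log10 Kd, n, ΔH, q_offset), with `n` optionally fixed; the Wiseman
  parameter `c = n·M0/Kd` is reported as a design diagnostic,
- compute the phenotype-assay metrics: chemotaxis response index
  `RI = D1/(D1 + D2)` (chemoattraction when RI > 0.52), buffer-corrected
  capillary counts, fold induction, optimal dose.

Synthetic-data generators (aligned families with a planted signature at
exact prevalence, replicated noisy titrations, assay tables) carry
ground-truth labels so every stage is testable without downloads. The
packaged reference sequence is a **synthetic PctA surrogate** carrying the
experimentally established pocket residues; substitute the real PctA via
`reference_pocket_model()` for production screens.

## Worked example

```r
library(cachesense)
library(dplyr)

ref <- pcta_reference()
fam <- generate_family(family_gen_config(n_seqs = 2000,
                                         full_match_fraction = 0.1,
                                         seed = 42))
cmap <- build_column_map(fam$family, ref)
screen <- screen_family(fam$family, cmap, ref, k = 5)
sum(screen$passes)
#> [1] 201
```

201 of 2001 rows carry all five pocket residues: the 200 planted
sequences (10% of 2000) plus the reference row itself. Joining the
protein metadata and rolling up the passing set by functional class:

```r
smry <- summarize_screen(screen, fam$metadata)
rollup(filter(smry, passes), "class")
#> # A tibble: 7 × 2
#>   class               n
#>   <chr>           <int>
#> 1 MCP               103
#> 2 HK                 45
#> 3 CSP                22
#> 4 UNCHARACTERIZED    18
#> 5 SP                  6
#> 6 STK                 6
#> 7 AC/GC               1
```

Conservation over the pocket region ranks the five signature positions on
top:

```r
top_conserved(compute_pfm(fam$family, cmap), 5)
#> [1] 128 144 126 146 173
```

Simulating a standard titration (25 × 10 µl of 700 µM ligand into 1 ml of
70 µM protein at 20 °C) at the high-affinity operating point, correcting
with its dilution control, and fitting:

```r
prot <- titration_protocol()                  # the standard protocol above
truth <- one_site_params(Kd = 0.14e-6, n = 1, dH = -40e3)
reps <- generate_itc_dataset(prot, truth,
                             noise_sd = noise_sd_for(prot, truth, 0.02),
                             n_replicates = 3, seed = 7)
fit <- fit_one_site(subtract_dilution(reps[[1]]$sample, reps[[1]]$control),
                    prot, seed = 7)
fit
#> <one_site_fit> Kd = 1.229e-07 M, n = 1, dH = -3.919e+04 J/mol, c = 569
tidy(fit)
#> # A tibble: 4 × 3
#>   term     estimate std.error
#>   <chr>       <dbl>     <dbl>
#> 1 Kd        1.23e-7   3.42e-8
#> 2 n         1.00e+0   5.83e-3
#> 3 dH       -3.92e+4   5.72e+2
#> 4 q_offset  2.69e-2   2.24e+0
```

A single noisy replicate recovers Kd ≈ 0.12 µM against a generating value
of 0.14 µM, with the stoichiometry and enthalpy essentially exact;
`autoplot(fit)` draws the observed heats and fitted isotherm. Assay
metrics are one-liners: `response_index(6.5, 3.5)` is `0.65`, above the
0.52 chemotaxis threshold.

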