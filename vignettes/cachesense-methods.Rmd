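---
title: "Methods: pocket-signature screening and one-site ITC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket-signature screening and one-site ITC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachesense)
```

`cachesense` implements the computational analyses used to delineate the
AI-2-binding subfamily of dCache_1 sensor domains: reference-anchored
screening for a five-residue binding-pocket signature, conservation
profiling, domain-architecture classification with taxonomy rollups, a
one-site isothermal titration calorimetry (ITC) model with simulation and
fitting, and the quantitative chemotaxis/assay metrics. This vignette is
the package's account of those methods: the models, their assumptions,
the tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Reference anchoring

All pocket coordinates are expressed in PctA residue numbering, 1-based
inclusive. The reference model (`reference_pocket_model()`) bundles the
reference sequence, its dCache_1 domain span (residues 36–261), the
five-position signature R126/W128/Y144/D146/D173, the wider set of
pocket-contact positions (Y101, M111, Y121, R126, W128, Y144, D146, A147,
D173) and the logo window 100–175.

`build_column_map()` anchors a family alignment by walking the reference
row left to right: each non-gap column receives the next reference residue
number, residue identity is verified against the reference sequence at
every assigned position (a hard error cites the first disagreement), and
columns that fall outside the domain span are dropped. This mirrors the
standard practice of removing alignment columns not represented in the
reference domain before logo construction. Reference rows may carry a
Stockholm-style `id/start-end` suffix declaring their first residue
number; without one, the domain start is assumed. The resulting
`column_map` is a strict bijection between retained columns and reference
positions, monotone in both directions.

Two anchoring paths exist: the family MSA path above, and a pairwise
convenience path (`align_to_reference()`) that globally aligns a single
sequence to the reference with BLOSUM62 scores and affine gaps (open 11,
extend 1 — the familiar protein-search defaults). The pairwise path is for
sequences outside the family alignment; reports based on it should be
labeled as such, since a family MSA is the better-informed anchoring. The
test suite checks that both paths extract identical signatures when the
alignment is the one induced by the pairwise aligner.

## Signature screening

`screen_family()` reads the residues at the five signature columns for
every row and counts strict identity matches to the reference signature.
Matching is deliberately literal: no similarity classes, and a gap or an
`X` at a signature column is a mismatch. The threshold `k` (default 5)
is exposed because the four-of-five case is biologically meaningful — the
PctA paralogs PctB and PctC carry four of the five residues and bind AI-2
with much lower affinity. Screening is invariant to row order and to
columns outside the retained set, and pass sets are nested in `k`; all
three properties are tested against generated families.

## Conservation profiling

`compute_pfm()` tallies per-position residue counts over a reference
window (default 100–175, the active-pocket region). Gaps are excluded
from frequencies and reported as a gap fraction alongside; `X` is tallied
separately and excluded as well — the usual logo convention, where column
heights reflect residue composition only. Information content is
`IC = log2(20) − H` bits with `H` the Shannon entropy of the residue
frequencies, so an invariant column scores `log2(20) ≈ 4.32` bits and a
uniform 20-residue column 0 bits (both asserted exactly in the tests).
The small-sample correction `e(n) = 19/(2 ln 2 · n)` is available but off
by default: at family sizes in the thousands it is far below any
meaningful difference. `top_conserved()` ranks positions by maximum
single-residue frequency, ties broken toward the lower position, which is
the quantity that makes the five signature positions stand out in a
planted family.

## Domain-architecture classification

Functional classes are assigned from Pfam-style output domains with an
editable, ordered rule table (`default_class_rules()`, YAML
serializable): MCP ← {MCPsignal, MA}; CSP ← {GGDEF, EAL, HD-GYP, HDc};
HK ← {HisKA, HisKA_2, HisKA_3, HATPase_c}; SP ← {SpoIIE, PP2C};
STK ← {Pkinase}; AC/GC ← {Guanylate_cyc}; CNB-only ← {cNMP_binding, and
nothing else}. Classification is total: the first class in precedence
order with qualifying evidence wins; proteins with only non-qualifying
domains are `OTHER-annotated`; proteins with no output domains at all are
`UNCHARACTERIZED`. The literature names these families but prints neither
the exact Pfam-name mapping nor a tie rule for multi-domain proteins, so
both are package decisions: the domain sets are the canonical Pfam names
for each family, and the precedence MCP > CSP > HK > SP > STK > AC/GC >
CNB-only puts the dedicated signaling outputs ahead of the broadly shared
kinase domains. Reordering precedence only ever moves proteins with
evidence for more than one class (a tested invariant), so single-evidence
cohorts are insensitive to this choice.

## The one-site ITC model

For a perfusion cell of volume `V0` receiving injection `i` of volume
`v_i` from a syringe at ligand concentration `Ls`, the displacement
recursion is

    M_i = M_{i−1} (1 − v_i/V0)
    L_i = L_{i−1} (1 − v_i/V0) + Ls v_i/V0

(the injected volume displaces an equal volume of well-mixed cell
contents). We use this exact recursion rather than the linearized
`i·v/V0` approximation — it is no more complex and removes a systematic
error that grows with injection number. The complex concentration after
each injection solves the one-site quadratic; `bound_complex()` uses the
numerically stable root form `PL = 2ab/(S + sqrt(S² − 4ab))` with
`a = n·M`, `b = L`, `S = a + b + Kd`, which avoids catastrophic
cancellation at low occupancy. The tests require agreement with an
independent 1-D root-finder to 1e-12 relative error, and the simulated
cumulative heat must match an independent mole-balance account that
tracks complex displaced out of the cell.

The measured heat of injection `i` is

    q_i = ΔH · V0 · (PL_i − PL_{i−1}(1 − v_i/V0)) + q_offset + ε_i

in microjoules, with `ε_i` i.i.d. Gaussian. `q_offset` is a constant
per-injection background; heats of dilution are handled the way
instruments do it, by subtracting a buffer-control titration
(`subtract_dilution()`).

Defaults mirror the standard experiment: 25 injections of 10 µl of
700 µM ligand into 1 ml of 70 µM macromolecule at 293.15 K. ΔH defaults
to −40 kJ/mol, a typical exothermic binding enthalpy at this scale; the
recovery analyses assert only Kd and n, so the exact ΔH choice is
immaterial to them. The first injection is kept by default
(`discard_first` is available; vendor conventions differ).

### Fitting

`fit_one_site()` minimizes (optionally weighted) squared residuals of the
forward model over `(log10 Kd, n, ΔH, q_offset)` by Levenberg–Marquardt,
with `Kd` log-parameterized (it is positive and ranges over decades) and
box bounds `log10 Kd ∈ [−12, 0]`. Eight starts spread over the plausible
`Kd` window — with `ΔH` seeded from the total heat per mole of injected
ligand — are run and the best residual sum of squares wins; total failure
is flagged in the result rather than raised. `n` can be fixed (the
standard move in weak-binding regimes where stoichiometry is not
identifiable). Standard errors come from the local curvature at the
optimum; the error on `Kd` is propagated from the log10 scale. The
Wiseman parameter `c = n·M0/Kd` is attached to every fit, with a regime
flag outside `[1, 1000]`.

### What recovery simulations show

The package's recovery studies (tests and `scripts/acceptance.R`)
simulate replicate titrations at the reported operating points — Kd
0.14 µM under the 700→70 µM protocol (`c ≈ 500`), 26 nM under the
13→1.3 µM protocol (`c = 50`), and the weak-binding points 3.1 µM
(13→1.3 µM) and 181 µM (700→70 µM), both fitted with `n = 1` fixed
(`c ≈ 0.4`) — at Gaussian noise with sd equal to 2% of the largest
noise-free heat, then fit each replicate and take the median recovered
Kd. The acceptance script uses 40 replicates per regime (the design floor
is 20; 40 halves the Monte Carlo error of the reported median at a
runtime of about three minutes). A companion simulation study in the test
suite checks that the median recovery error stays under 5% across
`c ∈ [5, 500]` at 1% noise.

Two numerical facts are worth knowing. First, at high `c` the isotherm is
nearly rectangular and `Kd` is informed only by the rounding of the
transition, so single-replicate estimates scatter broadly (±25% at 2%
noise) even though the median is nearly unbiased. Second, in the low-`c`
regimes the per-fit `Kd` distribution is right-skewed along the strongly
correlated `Kd`–`ΔH`–`q_offset` ridge; the median recovered Kd sits
roughly 10% above the generating value. That residual skew is an
identifiability limit of the regime — visible in any one-site fitter —
not an implementation artifact, and it is well inside the 30% band the
recovery analyses use for these regimes.

## Assay metrics

The plate-gradient response index is `RI = D1/(D1 + D2)`; values strictly
greater than 0.52 score as chemoattraction (the strict inequality
matters: 0.52 itself is a non-response). `RI(a, b) + RI(b, a) = 1`
exactly. Capillary counts are corrected by subtracting buffer-capillary
counts, floored at zero with a flag (a negative net count is noise, not
repulsion, in this assay). Fold induction is a plain ratio with a guarded
positive background, and `optimal_dose()` is an argmax with ties broken
toward the lower dose. Crystal-violet and biovolume summaries are
ordinary means ± s.e.m. and use no bespoke math; significance testing is
delegated to standard two-sample tests, not re-derived here.

## Synthetic data: what it does and does not emulate

`generate_family()` emits an alignment directly — one column per
reference domain position, the reference domain as first row — so
screening tests are independent of any aligner. Exactly
`round(f·n_seqs)` generated rows carry all five signature residues (at
the default signature fidelity of 1), a configurable fraction carries
exactly four, and background rows draw residues i.i.d. from a uniform
emission, re-drawn in the astronomically rare case of a chance full
match. Gaps are sprinkled per cell at the indel rate (never at signature
columns of planted rows). Classes and phyla are drawn from configurable
distributions whose defaults reflect the screened cohort's structure —
MCP-dominated classes, Proteobacteria-dominated phyla — and
architectures are realized from the classifier's own rule table, which
guarantees `classify ∘ generate = identity` on the planted labels.
Everything is deterministic given the config, and the ground-truth table
is the oracle used throughout the tests.

What the generator does **not** emulate: phylogenetic correlation between
rows (real families are trees, not i.i.d. draws), position-specific
background composition, alignment uncertainty, and the long-tailed
architecture diversity of real Pfam scans. Passing the planted-truth
tests therefore demonstrates that the screening, classification and
rollup machinery is exact on inputs with known answers — it does not by
itself validate biological conclusions on real alignments, where
alignment quality and the class-rule table dominate. Re-screening the
real 18,970-domain family requires the published supplementary alignment
and metadata; the pipeline is exercised at that scale on synthetic data
instead (`tests/testthat/test-acceptance.R`), and an import shim for the
real tables may be needed since their exact column layout is not
standardized.

The packaged reference is likewise a clearly labeled synthetic PctA
surrogate: a deterministic pseudo-random 300-residue sequence carrying
the experimentally established pocket identities within the 36–261 span.
Every anchoring, screening and conservation computation treats it exactly
as it would the real PctA; substitute the real sequence via
`reference_pocket_model()` for production use.

ITC replicates (`generate_itc_dataset()`) pair each sample titration
with a buffer control (background offset plus noise), with replicate
seeds derived deterministically from a master seed. The noise model is
i.i.d. Gaussian per integrated injection heat; correlated baseline drift
and integration error of raw power traces are out of scope (inputs are
integrated heats).

## Degenerate inputs and edge behavior

Parsers fail hard and specifically: ragged alignments name the offending
row, illegal residues name sequence and position, missing protocol fields
and non-numeric heats name the field or row. Signature extraction never
fails — unmapped or gapped positions yield `-`, which downstream counts
as a mismatch. An all-gap column has undefined information content,
reported as `NA` rather than 0 (zero is a meaningful value: a uniform
column). Classification is total by construction. `fit_one_site()`
refuses fewer than six usable injections, and flags rather than raises
when no start converges.

## Problem sizes

The default test run screens families up to 20,000 rows (about three
seconds to generate, well under a second to screen), runs the four-regime
recovery study at 20 replicates per regime, and the acceptance script
uses 40 replicates; these sizes were chosen to exercise the family-scale
code paths while keeping a full check of the package comfortably
interactive.
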