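# ringsel

Interface selectivity and binding affinity analysis of RING-type E3–E2
ubiquitination complexes.

## The problem

RING-type E3 ubiquitin ligases work by docking an E2 ubiquitin-conjugating
enzyme against their RING domain. The docking surface — the E2's helix α1
and loops L4/L7 against the RING's shallow groove and zinc-chelating loops —
is structurally conserved, yet in cells a given E3 pairs with only a few of
the ~38 human E2s. The muscle-atrophy ligase MuRF1 (TRIM63) is a prime
example: it works with UBE2E1, UBE2J1, UBE2J2 and UBE2L3, with affinities
spanning three orders of magnitude. Which residues make each pairing
selective, when the canonical docking chemistry is shared by all of them?

`ringsel` implements the comparative-interface workflow that answers this
question from predicted or experimental complex structures, plus the
quantitative binding analysis that validates it:

1. **Contact mapping** — parse multi-chain PDB/mmCIF models (per-residue
   confidence read from the B-factor column, low-confidence residues
   maskable), and extract every inter-chain residue pair whose minimum
   heavy-atom distance is ≤ 4 Å (inclusive), with backbone/side-chain
   annotation and zinc-coordination detection.
2. **Position equivalence** — align homologous E2 sequences globally
   (Needleman–Wunsch/Gotoh, BLOSUM62, EMBOSS `needle` defaults: gap open
   10, gap extend 0.5, free end gaps) and express every E2 residue in the
   numbering of a reference E2, so that, e.g., Phe108 of UBE2E1, Met70 of
   UBE2J1, Phe73 of UBE2J2 and Phe63 of UBE2L3 become one equivalence
   class.
3. **Selectivity classification** — across a panel of complexes sharing
   one E3, each projected contact key `(E3 position, E2 reference
   position)` is classified: **canonical** (both sides on catalogued
   generic RING–E2 docking positions), **common** (present in every
   complex of the panel), **selective** (present in exactly one), or
   **other** (a strict subset).
4. **Superposition** — SVD-based Kabsch alignment with reflection
   correction for RMSD comparison of alternative predictions of the same
   complex.
5. **Binding affinity** — for fluorescence titrations with the labeled E3
   held at 10 nM, the exact ligand-depletion-corrected 1:1 isotherm

   f_bound = [(K_d + L + R) − √((K_d + L + R)² − 4·L·R)] / (2R)

   is fitted by profiled least squares (baseline and amplitude linear,
   K_d on a log scale over a grid spanning `[c_min/100, c_max·100]`),
   with residual-resampling bootstrap confidence intervals, a
   signal-to-noise reliability flag (S/N ≥ 10), and mutant-vs-wild-type
   fold changes.

Because no structure or titration data of the original study are
deposited, the package ships first-class synthetic generators: two-chain
complexes with engineered contact geometry, zinc sites and confidence
profiles; panels with planted canonical/common/selective contacts; and
simulated 16-point serial-dilution titrations. Every generator emits a
ground-truth ledger that the downstream tests compare against.

## Worked example

Plant a known interface architecture in a synthetic four-complex panel
(shared E3, the four real E2 sequences), then recover it:

```r
library(ringsel)

plan <- data.frame(
  e3_pos        = c(79, 50, 46, 18, 38),
  e2_ref_pos    = c(140, 108, 55, 47, 120),
  class         = c("canonical", "common", "common", "selective", "selective"),
  selective_for = c(NA, NA, NA, "UBE2J2", "UBE2J1"))

panel <- make_panel(plan, seed = 42)
cmaps <- lapply(names(panel$models), function(id)
  interface_contacts(panel$models[[id]], "A", "B", cutoff = 4, complex_id = id))
names(cmaps) <- names(panel$models)

cls <- classify_panel(cmaps, panel$pmap, canonical_reference())
cls
#> contact_classification over 4 complexes: 5 equivalence keys
#> canonical    common selective
#>         1         2         2

subset(selectivity_report(cls), complex_id == "UBE2J2")
#>    complex_id     class e3_pos e3_resname e2_ref_pos e2_pos e2_resname min_dist
#> 8      UBE2J2 canonical     79        ARG        140    106        ASN      3.5
#> 9      UBE2J2    common     46        LYS         55     20        ASP      3.5
#> 10     UBE2J2    common     50        ASP        108     73        PHE      3.5
#> 11     UBE2J2 selective     18        GLU         47     12        THR      3.5
```

The report resolves every equivalence key back to real residues: the
canonical key is the linchpin Arg79 against the SPA motif (reference
position 140 maps to residue 106 of UBE2J2), the common key at reference
position 108 lands on Phe73 of UBE2J2, and the planted UBE2J2-selective
contact (E3 Glu18 × reference 47) appears only in that complex.

Fit a simulated titration (truth: K_d = 4.2 µM, receptor 10 nM, 2% noise)
and a wild-type/mutant fold change (truths 80 nM and 6.9 µM):

```r
fit <- fit_isotherm(simulate_titration(kd = 4.2e-6, seed = 1),
                    n_boot = 500, seed = 1)
fit
#> isotherm_fit: Kd = 4e-06 M (95% CI 3.6e-06 - 4.53e-06)
#>   amplitude 299, baseline 1e+03, S/N 52.3 (reliable), 16 points

fit_wt  <- fit_isotherm(simulate_titration(8e-8,   seed = 2), n_boot = 0)
fit_mut <- fit_isotherm(simulate_titration(6.9e-6, seed = 2), n_boot = 0)
fold_change(fit_wt, fit_mut)$ratio
#> [1] 85.98611
```

## Documentation

The methods vignette (`vignettes/ring-e2-interface-analysis.Rmd`) describes
the models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the package's numerical choices and
limitations.
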