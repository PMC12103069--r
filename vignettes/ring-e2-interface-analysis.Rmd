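---
title: "Methods: interface selectivity and binding analysis of RING E3-E2 complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface selectivity and binding analysis of RING E3-E2 complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringsel)
```

# Scope and model

`ringsel` compares the protein-protein interfaces of a panel of complexes
that share one RING-type E3 ligase but carry different, homologous E2
conjugating enzymes, and determines binding affinities from fluorescence
titrations. The package's working system is MuRF1 (TRIM63) with its four
muscle E2 partners (UBE2E1, UBE2J1, UBE2J2, UBE2L3); every stage is,
however, parameterised so other RING systems can be analysed by supplying
their own sequences and canonical-position table.

The central abstraction is the **equivalence key**: a contact between E3
residue $i$ and E2 residue $j$ in one complex is comparable to a contact in
another complex only after $j$ is translated into the numbering of a fixed
reference E2 through a sequence alignment. A key $(i, j_\mathrm{ref})$ is
then *present* in a complex if that complex has an interface contact
projecting to it, and the panel-level classes follow from presence
patterns:

1. **canonical** — both sides of the key lie on positions catalogued for
   the generic RING-E3/E2 interface (see the packaged reference table);
2. **common** — not canonical, present in every complex of the panel;
3. **selective** — not canonical, present in exactly one complex;
4. **other** — not canonical, present in a strict subset of size > 1.

Rule order matters: canonical keys are recognised by position, not by
presence count, because the generic docking chemistry is expected in every
RING-E2 pair and would otherwise be indistinguishable from panel-specific
common contacts. Presence itself is binary and sharp by design: a residue
pair at 3.9 Å in one complex and 4.2 Å in another counts as absent in the
second. We do not smooth over the cutoff because the downstream claim —
"this contact exists only in that pair" — is itself binary.

The *other* class deserves a note: a key shared by two complexes out of
four belongs to neither the common nor the selective narrative. We report
it explicitly rather than dropping it, so that class counts always
partition the key universe.

# Contacts and structures

Structures are read from PDB or mmCIF (`bio3d` parsers behind the
`read_structure()` surface). Hydrogens are removed globally — predicted
models are heavy-atom, so all distances in the pipeline are heavy-atom
distances — and alternate locations are resolved to the highest-occupancy
copy, ties broken by file order. Author residue numbering is kept
untouched: for the packaged constructs it equals the 1-based position in
the working sequences, and no renumbering to full-length database
coordinates is attempted.

An interface contact is a cross-chain residue pair whose **minimum
heavy-atom distance** is `<= cutoff`, inclusive, with a default of 4.0 Å.
The distance definition is the one that supports atom-level statements
such as "the backbone carbonyl of this alanine receives the contact":
the realising atom pair is kept and annotated backbone/side-chain.
Distance ties are broken lexicographically by atom-name pair so output is
deterministic. The spatially pruned scan (centroid + radius prefilter) is
required by the test suite to agree *exactly* with a naive all-pairs scan;
the naive path stays in the package as the oracle.

Per-residue confidence (pLDDT in predicted models) is the mean B-factor of
the residue's atoms. `mask_low_confidence()` recomputes the masked set
from scratch at each call (hence idempotent and monotone in the
threshold); masked residues are excluded from contact detection and
superposition but keep their numbering. The default threshold of **70** is
the conventional confident/low boundary for predicted models; the
visual convention of hiding disordered regions does not pin a numeric
value, so the threshold is exposed as a parameter rather than hard-coded.

Metal sites are detected with a default Zn-ligand coordination cutoff of
**2.8 Å**, the standard upper bound for Zn-S/N/O coordination distances;
sites without ligands inside the cutoff are reported and flagged
unligated rather than dropped. Hetero ions never participate in the
interface contact map — the interface is defined between polymer chains.

# Sequence alignment and position maps

The aligner is an affine-gap global Needleman-Wunsch (Gotoh) with the
EMBOSS `needle` conventions, since those are the de facto reference for
pairwise percentages: BLOSUM62 (taken from `Biostrings`, with unknown
residue X scored 0), gap open 10, gap extend 0.5, a gap of length $L$
costing $10 + 0.5(L-1)$, and **free end gaps** by default. Free end gaps
matter here: UBE2E1 carries a ~50-residue N-terminal extension absent from
UBE2L3, and penalised ends would distort the UBC-fold alignment that the
position map depends on. Identity and similarity percentages use all
alignment columns (including gap columns) as the denominator, and
similarity counts columns with a strictly positive substitution score —
both EMBOSS conventions. Traceback prefers diagonal, then vertical (gap in
the second sequence), then horizontal moves, making the emitted alignment
deterministic.

Position maps are **star-shaped**: each E2 is aligned pairwise to the
reference (UBE2E1 in the packaged workflow) and match/mismatch columns
create 1:1 position entries; gap columns never do, so maps are strictly
monotone and invertible on their domain. A full progressive multiple
alignment is deliberately out of scope — all cross-E2 statements the
pipeline makes are phrased relative to the reference numbering, and a star
topology answers exactly that question with far less machinery. Residues
with no reference equivalent (insertions) are carried in an explicit
`unprojected` list, never silently dropped.

Two numbering caveats are handled by computing, not assuming: the SPA
motif of the packaged UBE2E1 construct sits at positions 140-142 (the
pipeline reports sequence-derived positions and does not renumber to match
any externally quoted 141-143), and the L4 bulky-hydrophobic equivalence
class maps reference position 108 to UBE2J1 position 70 (methionine), a
value the test suite checks explicitly.

# Superposition

`kabsch_superpose()` is the SVD Kabsch algorithm with explicit reflection
correction (the smallest singular direction is sign-flipped whenever the
raw solution has determinant −1), so the returned rotation is always
proper. Model comparison uses CA atoms only: CA-RMSD is the standard for
cross-model comparison and is insensitive to side-chain rebuilds. An
alignment-derived position map can drive the pairing when chains carry
homologous but non-identical sequences; masked residues and residues
missing a CA are skipped and the retained pairing is reported. Inputs with
fewer than 3 pairs or (near-)collinear geometry are rejected rather than
silently returning an ill-conditioned rotation. RMSD after two independent
refits is not a metric; the comparison matrix is only guaranteed symmetric
with a zero diagonal, and the tests assert nothing stronger.

# Binding model and fitting

Titrations are modelled as initial-fluorescence readings of a labeled
receptor (the E3) held constant while the ligand (E2) is serially diluted:
16 points, 2-fold dilution by default. With the receptor at 10 nM and the
tightest affinity near 80 nM, ligand depletion is not negligible at the
low end, so the exact quadratic solution of the 1:1 mass-action
equilibrium is used throughout:

$$ f = \frac{(K_d + L + R) - \sqrt{(K_d + L + R)^2 - 4LR}}{2R}, $$

evaluated as $2L / (S + \sqrt{S^2 - 4LR})$ with $S = K_d + L + R$ to stay
numerically stable as $f \to 0$. The hyperbolic limit $L/(L+K_d)$ is a
test property (relative error below $10^{-3}$ at $R = 10^{-6} K_d$), not a
fitting option that could be confused with the exact form.

The fit `signal = baseline + amplitude × f(L; R, K_d)` exploits the
model's structure: at fixed $K_d$, baseline and amplitude are a linear
least-squares solve, so $K_d$ is the only nonlinear parameter. It is
profiled on a $\log_{10}$ grid of 61 points spanning
$[c_\mathrm{min}/100,\; c_\mathrm{max} \times 100]$ and the best bracket
is refined by 1-D minimisation. This variable-projection scheme is
deterministic, needs no starting values, and cannot step outside
positivity ($K_d$ lives on the log scale). The amplitude sign is free —
fluorescence may rise or fall on binding. A warning (not an error) is
raised when the fitted $K_d$ falls outside the titrated range, i.e. the
series does not span the transition.

Uncertainty comes from a seeded residual-resampling bootstrap (default
1000 draws; percentile 2.5/97.5 interval). Residual resampling was chosen
because replicate counts in this kind of assay are small (two or three),
too few to bootstrap over replicates, and the instrument-software
convention for intervals is not public. Identical seeds give bit-identical
intervals, and the fitter restores the global RNG state afterwards.

Reliability uses the signal-to-noise criterion S/N ≥ 10, with S/N defined
as the **response realised over the titrated range** —
`|amplitude| × span(f)` — divided by the RMS residual. The realised-span
form matters for degenerate data: a flat series can be fitted with an
arbitrarily large nominal amplitude over a vanishing fraction-bound span,
which would let the naive `|amplitude|/RMS` ratio report high S/N for
pure noise. For any well-sampled curve the span is close to 1 and the two
definitions agree.

Fold changes are $K_d$ ratios with confidence intervals from paired
bootstrap draws; both fits must have converged.

# Synthetic data: what it emulates, and what it does not

The generators exist so that every pipeline stage is testable against a
machine-readable ground truth without any external download.

`make_complex()` builds two-chain toy structures from 4-atom residues
(N, CA, C, O; zinc-anchor residues become cysteines with an SG atom).
Planted cross-chain pairs are placed in isolated spatial cells and their
separation is solved by 1-D root finding until the minimum heavy-atom
distance matches the target within 0.05 Å; all non-planted cross-chain
pairs are guaranteed beyond a floor (default 6 Å). The construction is
re-verified by a vectorised all-pairs scan before the model is returned,
so an infeasible request fails loudly instead of producing a silently
wrong fixture. Confidence profiles are written into the B-factor column so
that parsing exercises the same path as real predicted-model files. The
toys are geometrically exact but stereochemically meaningless: no
Ramachandran plausibility, no side-chain packing, no realistic secondary
structure. Passing tests therefore demonstrate the correctness of the
*bookkeeping* (distances, masking, projection, classification), not any
ability to judge real structural models.

`make_panel()` instantiates one complex per E2 sequence — by default the
real working sequences, so the position map exercised in tests is the real
one while coordinates remain synthetic — and plants keys per an intended
class plan. The plan is validated up front: intended classes must equal
what the classification rules would produce (a "common" key sitting on
canonical positions is a plan conflict), selective keys need an owner, and
a reference position without an equivalent in some panel member is
unrealizable. One geometric limitation is documented: a single E2 residue
cannot be planted against two different E3 residues (each B-side residue
has one location), and such plans are rejected; panels generated from
distinct reference positions never encounter this.

`simulate_titration()` draws additive Gaussian noise with a standard
deviation expressed as a fraction of the amplitude (default 2%, matching
the quality of a well-behaved fluorescence titration), on top of the exact
isotherm at the true $K_d$, with baseline 1000 and amplitude 300 arbitrary
units by default and a top concentration of $50 \times K_d$ (comfortably
above the transition; the dilution step and count are configurable since
assay descriptions often leave the step factor ambiguous). Real titration
artefacts — pipetting series correlation, meniscus/aggregation outliers,
amplitude drift between replicates — are deliberately not modelled; the
simulations measure estimator performance under the stated noise model,
nothing more.

The MuRF3-like RING sequence returned by `murf3_like_ring()` is a clearly
labelled **synthetic surrogate**, not a database record: it applies to the
packaged MuRF1 RING (residues 22-86) the documented divergence pattern of
the MuRF1/MuRF3 RING pair — five substitutions to similar residues
(positive BLOSUM62 score) and five to dissimilar ones, out of 65
positions, sparing the zinc ligands, the conserved proline, the linchpin
arginine and the E2-interaction positions, which are conserved between the
two ligases. Aligning the construct against the surrogate reproduces the
conservation statistics of the real pair (84.6% identity, 92.3%
similarity) by construction of the divergence pattern; any analysis that
needs the true TRIM54 residue identities at the ten substituted positions
must supply the database sequence instead.

# Problem sizes and determinism

The shipped test-suite and acceptance-script sizes are chosen to give
stable statistics at interactive runtimes: 100 random fixtures for the
contact-engine equivalence, 200 random presence panels for the
classification oracle, 50 random end-to-end plans, 50 random alignment
pairs of length ≤ 6 against exhaustive enumeration, and 100 simulated
titrations per affinity (median recovery; the median is robust to the
occasional fit pulled by a noisy top point). All randomness is seeded;
every generator returns identical output for identical seeds, and the
acceptance script derives disjoint seed streams per affinity panel from
its single `--seed` argument.

# Known limitations

* Interface presence is binary at the cutoff; near-threshold contacts
  flip classes under sub-Ångström coordinate changes. This mirrors the
  sharp-cutoff convention of the analysis the package implements, but a
  sensitivity sweep over the cutoff is advisable on real models.
* The E3 side of an equivalence key uses the shared E3's own numbering;
  panels mixing E3 constructs with different numbering are not supported.
* No solvent accessibility, interaction energetics, or hydrogen-bond
  geometry: contact classes say where complexes differ, not why they
  bind.
* Multi-model (NMR-style) files contribute only their first model;
  assemblies are not expanded.
* The bootstrap quantifies fit uncertainty under the 1:1 model; it cannot
  detect model misspecification (cooperativity, aggregation, fluorescent
  impurities).
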