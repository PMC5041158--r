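---
title: "Methods: cross-beta core modelling, contact statistics and assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-beta core modelling, contact statistics and assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

`crossbeta` studies how a short amyloidogenic peptide — the 49–64
fragment of hen egg white lysozyme, with the terminal cysteine mutated
to serine (`GSTDYGILQINSRWWS`) — assembles into a cross-β amyloid core,
and how small ligands may compete with that assembly. This vignette is
the package's own account of the underlying model: what is computed,
under which assumptions, with which defaults, and what the synthetic
data do and do not establish.

## The structural model

A peptide monomer is represented at coarse resolution: the full
backbone (N, Cα, C, O, amide H) at ideal bond lengths and angles, plus
Cβ and a single side-chain centroid pseudo-site ("SC") per residue
carrying that residue's interaction character (radius, charge class for
Asp/Glu/Arg/Lys, hydrogen-bond donor/acceptor capability, aromatic
flag). Full-atom rotamers are deliberately out of scope: the contact
and energy statistics of interest are reported at residue resolution,
and a centroid site is sufficient to carry them.

Three conformer classes exist. The β-strand ("B") is built from the
ideal antiparallel-sheet dihedrals φ = −139°, ψ = +135°; the α-helix
("H") from φ = −57°, ψ = −47°; both with trans peptide bonds (ω =
180°). The interactive builder originally used for these systems leaves
no parameter trail, so these canonical textbook values are the
package's fixed choice. The native conformer ("N") is template-derived
only: it must be read from a user-supplied coordinate file, because a
native fold cannot be meaningfully reconstructed from ideal dihedrals.

Internal coordinates are converted to Cartesian positions by the
natural-extension-reference-frame construction, and every conformer is
canonicalized deterministically: strand axis along x (N→C positive),
carbonyl/amide plane along y, side chains along z. Torsions follow the
IUPAC sign convention; the Cβ improper (N–C–Cα–Cβ ≈ +122.6°) fixes
L-chirality.

### Sheets

`stack_strands()` stacks copies of one conformer at 4.8 Å inter-strand
spacing (the canonical β-sheet hydrogen-bond register; 10 Å for helix
and native stacks, which exist as energy references). Antiparallel
topology alternates strand direction (rotation about the sheet normal);
the side-chain phase is controlled independently: `BA1` leaves all side
chains pointing the same way, `BA2` flips alternate strands about the
strand axis, `BP` is the all-parallel stack, and `BAa` searches all 2^n
flip combinations exhaustively (n ≤ 6; ties resolved to the first,
lexicographically) for the lowest coarse score.

One registry degree of freedom remains: the along-strand offset between
neighbouring strands. The builder grid-searches this shift once (second
strand against the first, −3…3 Å in 0.25 Å steps, minimizing the coarse
pair energy — the hydrogen-bond term rewards the canonical N···O
ladder) and repeats it according to the sheet's screw symmetry. A
consequence worth knowing: antiparallel interfaces alternate between
the two hydrogen-bond ring types of a real antiparallel sheet, so
successive interfaces carry ladder widths that differ by up to two
bonds around their mean (14/16 for the study peptide).

`enumerate_assembly_series()` builds the largest assembly once and
returns strand prefixes. This guarantees two contracts at once — series
elements share all geometry parameters, and element k contains element
k−1's coordinates unchanged — and makes the `BAa` series well defined
(the flip search runs once, at the final strand count).

### Cores

`pair_sheets()` samples rigid poses of a second sheet flipped face-down
over the first: spin about the sheet normal (0° or 180° ± 15° jitter),
1 Å translation grid in the sheet plane, separation drawn uniformly
inside the 8–12 Å mean-plane window (canonical steric-zipper packing),
followed by steepest-descent refinement of the rigid translation
(numeric gradient, halving step, ≤ 25 iterations, separation clamped to
the window). Poses with any inter-sheet heavy-atom pair below the 2.0 Å
clash floor are discarded; survivors are sorted by energy with ties in
generation order. All sampling is driven by an explicit seed recorded
in the pose metadata.

## The coarse potential

`score_structure()` sums, over all non-bonded site pairs (same-strand
pairs within one residue of each other are excluded as bonded):

* **Lennard-Jones**: ε·((r₀/r)¹² − 2(r₀/r)⁶) with r₀ the sum of the two
  site radii (backbone roles 1.6–1.9 Å, side-chain centroids 1.8–2.6 Å)
  and ε the geometric mean of the site depths (0.08–0.15 kcal/mol);
* **screened Coulomb**: 332.06·q₁q₂/(4r·r), a distance-dependent
  dielectric ε(r) = 4r; formal side-chain charges (±1 for D/E/R/K) are
  scaled by 0.5, backbone amides carry a ±0.2 dipole;
* **directional hydrogen bonds**: a Gaussian well of depth 2.5 kcal/mol
  centred at 2.9 Å (width 0.4 Å, cutoff 4 Å) for each ordered
  donor→acceptor pair; for backbone N donors the well is weighted by
  cos² of the N–H···acceptor alignment, side-chain donors (one centroid
  site, no explicit hydrogen) are distance-only;
* **clash penalty**: pairs below the 2.0 Å floor contribute a finite
  1000 kcal/mol each, with the other terms evaluated at the floor — the
  score is always finite and deterministic.

These constants live in `scorer_defaults()` and are chosen to put the
potential on a physically reasonable scale, not to reproduce any
molecular-mechanics force field: **absolute energies are not
comparable to published force-field values**; only the bookkeeping
identities (ΔE_n, ΔEp_core), orderings and trends are contract. The
potential is pairwise additive, so the identity
`score(core) = score(sheet1) + score(sheet2) + interaction` holds
exactly, and rigid transforms change the score by < 10⁻⁶ kcal/mol.

## Energy bookkeeping and the inhibitor rule

The growth gain is reported per monomer, ΔE_n = (E_n − n·E₁)/n. The
formula is sometimes printed as `En − (E1 × n)/n`, whose literal
precedence collapses to E_n − E₁ and cannot reproduce per-monomer
values on the order of −540 kcal/mol for a 4-strand total of −2166;
`delta_e_per_monomer(literal = TRUE)` exposes the literal reading for
completeness. The pairing gain is ΔEp_core = Ep_core − 2·Ep_β-sheet.
Ledger averaging (`average_ledgers()`) follows the integer-kcal/mol
reporting policy: averaged Ep fields are rounded to whole numbers and
the pairing gain recomputed from the rounded averages, which is how a
consensus row of (−2137, −2121, −2166 | −4300, −4307, −4359) yields
(−2141, −4322, −40). One published antiparallel variant row (−2166,
−4359) implies −27 where −28 is printed — the package treats this as
rounding of unrounded inputs and asserts it only within ±1.

`classify_ligand()` encodes the competition rule: a ligand is
energy-competitive when its binding gain is at most the sheet-pairing
reference plus a tolerance (default 20 kcal/mol, the reported ±19
uncertainty rounded up); it is called **inhibitory** only if it is
energy-competitive *and* its hydrogen-bond map overlaps the stabilizing
positions of the sheet–sheet map — cosine similarity restricted to
cells with nonzero core counts, threshold 0.3. Both knobs are
arguments. If the reference map carries no hydrogen bonds at all there
is nothing to overlap with and the call is **indeterminate**; this is
the only indeterminate branch. The rule is monotone by construction:
making a ligand's gain more negative can never turn an inhibitory call
off.

## Contact maps

`detect_hbonds()` counts one contact per heavy-atom donor–acceptor pair
across two disjoint groups at distance strictly below the cutoff
(default 3.0 Å). The criterion is distance-only — no angular term —
because distance thresholds are the stated measurement convention for
these maps; the strict inequality is uniform across both cutoffs (the
boundary has measure zero). Donor/acceptor roles come from a fixed
chemistry table: backbone N donates (except proline), backbone O
accepts, side-chain centroids carry per-residue roles, ligand sites
their declared roles. `detect_vdw()` counts all remaining heavy-atom
pairs below 2.3 Å, excluding pairs already classified as hydrogen
bonds — the two classes are disjoint by a priority rule, so a
donor–acceptor pair at 2.2 Å is one hydrogen bond, not one of each.

`accumulate_map()` sums per-frame detections into (strand, position)
cells on the first group's side; counts are per-pair-per-frame (a pair
present in k frames contributes k). Totals attributed to either sheet
of a core are equal by construction, counts are monotone in the cutoff,
and accumulation is linear over frames. `map_overlap()` is the cosine
of the flattened count vectors, defined as 0 when either map is empty.

## Assay analysis

ThT traces are baseline-corrected (mean dye-only signal), then
normalized to the sample nearest the anchor time (ties to the earlier
point; typical anchors are the 300 h / 30 h plateau times of the
full-length protein and the peptide). Fitting uses bounded
Levenberg–Marquardt with data-driven starts: Ai = min F, Af = max F,
t½ at the half-range crossing, k = 4/(t90 − t10), k bounded in
(0, 10] h⁻¹. Non-convergence is flagged in the result object with the
solver message, never thrown. Percent inhibition is
100·(1 − plateau_treated/plateau_control), invariant under common
rescaling.

Congo red difference spectra are R = D − C − B on a common 400–700 nm
grid (buffer background pre-subtracted). The amyloid call requires a
local maximum of R within 540 ± 10 nm exceeding a noise floor of 3× the
median absolute deviation of R outside 500–600 nm; an absolute floor of
10⁻⁹ absorbance units guards the exact-cancellation case D = C + B,
where floating-point dust would otherwise qualify as a "peak" above a
zero MAD.

## Synthetic data: what it emulates, and what it does not

The generators stand in for molecular-dynamics snapshots and
plate-reader output. `make_trajectory()` adds seeded Gaussian jitter
(default σ = 0.3 Å — small enough to preserve the hydrogen-bond ladder
in most frames, large enough to vary counts) to a base assembly and
enforces each planted contact in exactly ⌊fraction·N⌋ seeded frames by
pulling the partner atom just inside the relevant cutoff (2.6 Å for
hydrogen bonds, 2.1 Å for van der Waals). For donor-only ligands a
planted hydrogen bond pairs the ligand donor with the residue's
acceptor instead. `make_trace()` and `make_cr_spectra()` evaluate the
kinetic and spectral models exactly and add seeded Gaussian noise.
Seeds are mandatory; generators save and restore the global RNG state.

Two placement modes exist for ligands. `dock_ligand()` is a seeded
coarse sampler that holds the best-scoring clash-free placement near a
sheet face — sufficient for energy ordering and for the demonstration
that an aromatic-only (ThT-like) ligand forms no hydrogen bonds.
`place_ligand()` holds the ligand at an 8 Å standoff so that a
trajectory's ligand contacts are *exactly* the planted ones; the
acceptance script uses it when constructing ligand maps whose ground
truth must be controlled, planting the rosmarinic-like ligand's bonds
on the Arg13 column (the dominant stabilizing ladder of the model core)
and the resveratrol-like ligand's on the two positions least involved
in the generated sheet–sheet map — the defining feature of a
non-competing binder.

What passing these tests shows: the counting, fitting and
classification machinery is correct on data with known truth. What it
does not show: anything about real conformational ensembles. The jitter
is isotropic and memoryless — no correlated motions, no side-chain
repacking, no unbinding events — and the ligand templates are role
clusters, not molecules. Conclusions about real systems require real
trajectories read through the same interfaces (multi-model PDB).

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty pose lists warn and
return empty; a flat trace yields a flagged non-converged fit; an
all-zero map has overlap 0; malformed PDB ATOM records fail with their
line number. PDB coordinates round-trip to the format's 10⁻³ Å
precision. Rounding of reported ledger energies uses R's `round()` to
whole kcal/mol.

The default problem sizes — 16-residue peptide, 4-strand sheets, 5-strand
growth series, 10 core poses, 50–200-frame synthetic trajectories, 200
noisy traces for fit-bias estimation — are the sizes at which the
assembly trends of interest (stabilization of the per-monomer gain by
the fourth strand, the Arg13-dominated sheet–sheet map, sub-5-hour
midpoint recovery) are already stable, and they keep the full test
suite and the acceptance script in the minutes range on one CPU.

## Known limitations

* The potential is not a force field; its constants are versioned
  package defaults, and comparisons to published absolute energies are
  meaningless by design.
* The BAa flip search is exhaustive and hence capped at six strands.
* Hydrogen-bond detection is distance-only; directionality exists only
  inside the scoring potential, not in the contact statistics.
* Contact counts are per-pair-per-frame; a per-residue-per-frame
  deduplicated convention would give smaller totals (the counting
  machinery, not any absolute count, is the contract).
* The native ("N") conformer depends entirely on the supplied template;
  no validation beyond sequence agreement is attempted.
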