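# crossbeta

Cross-β amyloid core modelling and aggregation-assay analysis in R.

Short amyloidogenic peptides — here the 16-residue fragment 49–64 of hen
egg white lysozyme (`GSTDYGILQINSRWWS`, the native C-terminal cysteine
replaced by serine) — aggregate into cross-β fibrils: stacked β-sheets
whose side chains interdigitate into a steric zipper. Small polyphenols
differ sharply in their ability to block this process; rosmarinic acid
inhibits aggregation of this peptide while resveratrol does not.
`crossbeta` implements the computational workflow behind that comparison
for structural bioinformaticians who want to reason about inhibition
mechanisms without full force-field machinery:

* **structures** — build idealized conformers from sequence (β-strand
  φ = −139°, ψ = +135°; α-helix φ = −57°, ψ = −47°; native from a
  template), stack them into parallel (BP) or antiparallel sheets with
  controllable side-chain phase (BA1 same direction, BA2 alternating,
  BAa exhaustively optimized), and pair two sheets face-to-face into
  candidate cross-β cores by seeded pose sampling.
* **energetics** — a coarse-grained site potential (Lennard-Jones +
  screened Coulomb + directional backbone hydrogen-bond term) and the
  bookkeeping of self-assembly:

  * per-monomer growth gain ΔE_n = (E_n − n·E_1)/n,
  * sheet-pairing gain ΔEp_core = Ep_core − 2·Ep_β-sheet,

  plus the inhibitor rule: a ligand is called **inhibitory** when its
  binding gain is at least comparable to the sheet-pairing reference
  (ΔEp_ligand ≤ ΔEp_core + 20 kcal/mol) **and** its hydrogen-bond
  contact map overlaps the stabilizing positions of the sheet–sheet map
  (restricted cosine ≥ 0.3).
* **contacts** — per-strand, per-residue hydrogen-bond (< 3 Å,
  heavy-atom donor–acceptor) and van der Waals (< 2.3 Å) contact maps
  accumulated over multi-frame trajectories.
* **kinetics** — Thioflavin-T trace normalization and fitting of the
  Boltzmann sigmoid F(t) = Ai + (Af − Ai)/(1 + exp((t½ − t)·k)) and the
  lag-free mono-exponential F(t) = A·(1 − exp(−k·t)); percent inhibition
  100·(1 − plateau_treated/plateau_control); Congo red difference
  spectra R = D − C − B with the 540 nm red-shift amyloid call.
* **synthetic_data** — seeded generators for jittered trajectories with
  planted contacts, noisy kinetic traces and four-component CR spectra,
  so every stage can be tested against known ground truth.

Absolute energies live on the coarse potential's own scale; only
bookkeeping identities, orderings and trends are meaningful.

## Worked example

```r
library(crossbeta)

mono  <- build_monomer("GSTDYGILQINSRWWS", "B")
sheet <- stack_strands(mono, 4, phase = "BA2")
sheet
#> <sheet_assembly> 4 strand(s), phase=BA2, antiparallel, spacing=4.8 A, 64 residues

# growth energetics of an antiparallel stack
assembly_energy_series(enumerate_assembly_series(mono, 5, phase = "BA1"))
#> <energy_ledger> BA1
#>   E_n: -4.4, -75.6, -152.7, -224.8, -302.1
#>   dE_n: 0, -33.4, -46.5, -51.8, -56

# pair two sheets into a cross-beta core
core <- pair_sheets(sheet, sheet, n_poses = 10, seed = 1)[[1]]
delta_ep_core(score_structure(core), score_structure(sheet))
#> [1] -78.8

# contact map of a jittered trajectory with an enforced Arg13 ladder
planted <- data.frame(strand = LETTERS[1:4], position = 13,
                      partner = "sheet2", type = "hbond", fraction = 0.8)
traj <- make_trajectory(trajectory_spec(core, 50, sigma = 0.3,
                                        planted = planted, seed = 2))
map <- accumulate_map(traj, "sheet1", "sheet2")
map
#> <contact_map> 16 x 4 (position x strand), partner=sheet2, frames=50,
#>               hbond=280 vdw=0 (cutoffs 3.0/2.3 A)
apply(map$counts[, , "hbond"], 2, which.max)
#>  A  B  C  D
#> 13 13 13 13

# ThT kinetics: plateau-based inhibition
ctrl <- fit_sigmoid(make_trace(trace_spec("sigmoid",
          list(Ai = 0, Af = 1, t_half = 100, k_agg = 0.05),
          seq(0, 300, 5), sigma = 0.02, seed = 3)))
ctrl
#> <sigmoid_fit> Ai=-0.001108 Af=0.9997 t_half=100.4 h k_agg=0.0508 /h (converged)
trt <- fit_sigmoid(make_trace(trace_spec("sigmoid",
          list(Ai = 0, Af = 0.165, t_half = 100, k_agg = 0.05),
          seq(0, 300, 5), sigma = 0.02, seed = 4)))
inhibition_percent(plateau(trt), plateau(ctrl))
#> [1] 83.7
```

The per-monomer gain stabilizes after the fourth strand (dE_n increments
shrink from −33 to −4 kcal/mol), the enforced Arg13 column dominates the
sheet–sheet hydrogen-bond map in every strand, and the fitted plateaus
recover the ~83.5 % inhibition encoded in the treated trace.

A thin command-line interface wraps the same functions
(`exec/crossbeta`): `build-core`, `score`, `contacts`, `classify`,
`fit-kinetics`, `cr-call`, `simulate`, each accepting `--config
run.yaml` and exiting 2 on validation errors.

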