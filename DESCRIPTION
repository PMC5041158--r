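Package: crossbeta
Title: Cross-Beta Amyloid Core Modelling and Aggregation Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying amyloid self-assembly of short peptides and
    its inhibition by small ligands. Builds idealized peptide conformers and
    stacks them into parallel or antiparallel beta-sheets and face-to-face
    cross-beta core models; scores assemblies with a coarse-grained
    site-based potential and tracks the energy bookkeeping of sheet growth
    and sheet pairing; accumulates per-strand, per-residue hydrogen-bond and
    van der Waals contact maps over multi-frame trajectories; classifies
    candidate inhibitors by an energy-competition rule combined with
    contact-map overlap; and fits Thioflavin-T aggregation kinetics
    (sigmoidal and mono-exponential models) and Congo red difference
    spectra. A synthetic-data module generates jittered trajectories with
    planted contacts, noisy kinetic traces, and four-component absorbance
    spectra with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
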