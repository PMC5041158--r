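# Energy bookkeeping: per-monomer gains of sheet growth, sheet-pairing
# gain of core formation, ledger averaging, and the inhibitor classifier.

#' Per-monomer energy gain of sheet growth
#'
#' Gain of assembling `n` monomers into one sheet, normalized per monomer:
#' `(E_n - n * E_1) / n`. With `literal = TRUE` the alternative operator
#' precedence `E_n - (E_1 * n) / n = E_n - E_1` is used instead; the
#' default reading is the one consistent with reported per-monomer gains.
#'
#' @param E_n Energy of the n-monomer assembly (kcal/mol).
#' @param E_1 Energy of the isolated monomer (kcal/mol).
#' @param n Number of monomers (>= 1).
#' @param literal Use the literal precedence reading (default `FALSE`).
#' @return Gain in kcal/mol (per monomer unless `literal`).
#' @examples
#' delta_e_per_monomer(-2166, -1.9, 4) # -539.6
#' @export
delta_e_per_monomer <- function(E_n, E_1, n, literal = FALSE) {
  if (any(n < 1)) stop("`n` must be >= 1")
  if (literal) E_n - E_1 else (E_n - n * E_1) / n
}

#' Sheet-pairing energy gain of core formation
#'
#' Gain of pairing two equal sheets into the cross-beta core:
#' `Ep_core - 2 * Ep_sheet`.
#'
#' @param Ep_core Energy of the paired-sheet core (kcal/mol).
#' @param Ep_sheet Energy of one sheet (kcal/mol).
#' @return Gain in kcal/mol.
#' @examples
#' delta_ep_core(-4211, -2074) # -63
#' @export
delta_ep_core <- function(Ep_core, Ep_sheet) {
  if (!all(is.finite(Ep_core)) || !all(is.finite(Ep_sheet)))
    stop("energies must be finite")
  Ep_core - 2 * Ep_sheet
}

#' Create an energy ledger
#'
#' Collects the energies tracked while designing an amyloid core: the
#' monomer energy `E_1`, the sheet-growth series `E_n`, the 4-strand sheet
#' energy `Ep_sheet` and the paired-core energy `Ep_core`, with optional
#' per-entry uncertainties. Derived per-monomer gains `dE_n` and the
#' pairing gain `dEp_core` are computed on construction; `dE_1` is 0 by
#' definition.
#'
#' @param E_1 Monomer energy (kcal/mol). Defaults to `E_n[1]` when a
#'   series is given.
#' @param E_n Energy series for n = 1, 2, ... monomers.
#' @param Ep_sheet,Ep_core Sheet and core energies (kcal/mol).
#' @param se Optional named list of uncertainties.
#' @param label Optional label (e.g. the sheet phase).
#' @return An `energy_ledger`.
#' @export
energy_ledger <- function(E_1 = NULL, E_n = NULL, Ep_sheet = NULL,
                          Ep_core = NULL, se = list(), label = NULL) {
  if (is.null(E_1) && !is.null(E_n)) E_1 <- E_n[1]
  dE_n <- if (!is.null(E_n) && !is.null(E_1))
    delta_e_per_monomer(E_n, E_1, seq_along(E_n)) else NULL
  dEp_core <- if (!is.null(Ep_core) && !is.null(Ep_sheet))
    delta_ep_core(Ep_core, Ep_sheet) else NULL
  structure(list(label = label, E_1 = E_1, E_n = E_n, dE_n = dE_n,
                 Ep_sheet = Ep_sheet, Ep_core = Ep_core,
                 dEp_core = dEp_core, se = se),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat("<energy_ledger>", if (!is.null(x$label)) x$label, "\n")
  if (!is.null(x$E_n))
    cat("  E_n:", paste(round(x$E_n, 1), collapse = ", "), "\n",
        "  dE_n:", paste(round(x$dE_n, 1), collapse = ", "), "\n")
  if (!is.null(x$Ep_sheet))
    cat("  Ep_sheet:", round(x$Ep_sheet), " Ep_core:", round(x$Ep_core),
        " dEp_core:", round(x$dEp_core), "\n")
  invisible(x)
}

#' Average a set of energy ledgers
#'
#' Arithmetic mean of each energy field across ledgers. With
#' `rounding = TRUE` (the reporting policy) averaged `Ep` fields are
#' rounded to the nearest integer kcal/mol and the pairing gain
#' `dEp_core` is recomputed from the rounded averages.
#'
#' @param ledgers List of congruent `energy_ledger` objects.
#' @param rounding Apply the integer reporting policy (default `TRUE`).
#' @return An `energy_ledger` holding the averages.
#' @examples
#' ba <- list(energy_ledger(Ep_sheet = -2137, Ep_core = -4300),
#'            energy_ledger(Ep_sheet = -2121, Ep_core = -4307),
#'            energy_ledger(Ep_sheet = -2166, Ep_core = -4359))
#' average_ledgers(ba) # Ep_sheet -2141, Ep_core -4322, dEp_core -40
#' @export
average_ledgers <- function(ledgers, rounding = TRUE) {
  if (!length(ledgers)) stop("need at least one ledger")
  if (!all(vapply(ledgers, inherits, TRUE, "energy_ledger")))
    stop("all elements must be energy_ledger objects")
  fld <- function(name) {
    vals <- lapply(ledgers, `[[`, name)
    if (any(vapply(vals, is.null, TRUE))) {
      if (!all(vapply(vals, is.null, TRUE))) stop("ledger fields not congruent")
      return(NULL)
    }
    lens <- vapply(vals, length, 0L)
    if (length(unique(lens)) != 1) stop("ledger fields not congruent")
    m <- rowMeans(matrix(unlist(vals), ncol = length(vals)))
    if (rounding) round(m) else m
  }
  energy_ledger(E_1 = fld("E_1"), E_n = fld("E_n"),
                Ep_sheet = fld("Ep_sheet"), Ep_core = fld("Ep_core"),
                label = "average")
}

#' Energy series of a growing assembly
#'
#' Scores each assembly of [enumerate_assembly_series()] output and
#' returns an `energy_ledger` with the `E_n` and per-monomer `dE_n`
#' series.
#'
#' @param series List of `sheet_assembly` objects with strand counts
#'   1, 2, ...
#' @param params Scorer constants.
#' @return An `energy_ledger`.
#' @export
assembly_energy_series <- function(series, params = scorer_defaults()) {
  E_n <- vapply(series, score_structure, 0, params = params)
  energy_ledger(E_n = E_n, label = series[[1]]$phase)
}

#' Classify a candidate aggregation inhibitor
#'
#' Energy-competition rule: a ligand competes with cross-beta core
#' formation when its binding gain is at least comparable to the
#' sheet-pairing reference gain (`ligand_dE <= ref_dE + tolerance`), and
#' it is called inhibitory only if, in addition, its hydrogen-bond contact
#' map overlaps the stabilizing positions of the sheet-sheet map (cosine
#' similarity restricted to cells with nonzero core counts >=
#' `overlap_threshold`). If the core map carries no hydrogen-bond counts
#' at all the call is indeterminate.
#'
#' @param ligand_dE Ligand binding gain (kcal/mol, negative = favourable).
#' @param ref_dE Reference sheet-pairing gain (kcal/mol).
#' @param ligand_map,core_map `contact_map` objects over the same
#'   (strand, position) index set.
#' @param tolerance Energy tolerance for "comparable" (kcal/mol).
#' @param overlap_threshold Minimum restricted cosine similarity.
#' @return A `ligand_verdict` with the boolean competition flag, the
#'   overlap score and the final call.
#' @export
classify_ligand <- function(ligand_dE, ref_dE, ligand_map, core_map,
                            tolerance = 20, overlap_threshold = 0.3) {
  stopifnot(inherits(ligand_map, "contact_map"), inherits(core_map, "contact_map"))
  if (!identical(dim(ligand_map$counts), dim(core_map$counts)))
    stop("contact maps have mismatched shapes")
  competitive <- ligand_dE <= ref_dE + tolerance
  lig_hb <- ligand_map$counts[, , "hbond"]
  core_hb <- core_map$counts[, , "hbond"]
  stabilizing <- core_hb > 0
  if (!any(stabilizing)) {
    call <- "indeterminate"
    overlap <- 0
  } else {
    overlap <- cosine_similarity(lig_hb[stabilizing], core_hb[stabilizing])
    call <- if (competitive && overlap >= overlap_threshold)
      "inhibitory" else "non-inhibitory"
  }
  structure(list(ligand = ligand_map$partner, ligand_dE = ligand_dE,
                 ref_dE = ref_dE, energy_competitive = competitive,
                 overlap = overlap, tolerance = tolerance,
                 overlap_threshold = overlap_threshold, call = call),
            class = "ligand_verdict")
}

#' @export
print.ligand_verdict <- function(x, ...) {
  cat("<ligand_verdict> ", if (!is.null(x$ligand)) x$ligand, ": ", x$call,
      sprintf(" (dE %.1f vs ref %.1f +/- %.0f kcal/mol, overlap %.2f)",
              x$ligand_dE, x$ref_dE, x$tolerance, x$overlap), "\n", sep = "")
  invisible(x)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
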