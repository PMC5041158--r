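# Multi-model PDB input/output. Chain IDs encode strand labels; the second
# sheet of a core model is written with lowercase chain IDs and the ligand
# as HETATM records with residue name LIG on chain L. Reading and writing
# delegate to bio3d; a light pre-validation pass reports malformed ATOM
# records with their line numbers.

pdb_chain_for <- function(sites) {
  ifelse(sites$unit == "ligand", "L",
         ifelse(sites$unit == "sheet2", tolower(sites$strand), sites$strand))
}

#' Write a structure or trajectory to multi-model PDB
#'
#' Conformers, sheet assemblies and core models are written as one MODEL;
#' trajectories as one MODEL per frame. Side-chain centroid pseudo-sites
#' appear as atoms named `SC`; ligand sites as HETATM `LIG` records whose
#' atom names encode their roles (`D*` donor, `A*` acceptor, `R*`
#' aromatic).
#'
#' @param x A structure (`conformer`, `sheet_assembly`, `core_model`,
#'   `ligand_pose`) or `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(x, path) {
  if (inherits(x, "trajectory")) {
    sites <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    sites <- if (is.data.frame(x)) x else x$sites
    xyz <- matrix(as.vector(t(coords_of(sites))), nrow = 1)
  }
  lig <- sites$unit == "ligand"
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(lig, "HETATM", "ATOM"),
    resno = sites$resi,
    resid = ifelse(lig, "LIG", AA3[sites$resn]),
    eleno = seq_len(nrow(sites)),
    elety = sites$atom,
    chain = pdb_chain_for(sites),
    o = rep(1, nrow(sites)), b = rep(0, nrow(sites)))
  invisible(path)
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(
        substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)))))
    if (!ok) stop("malformed ATOM record at line ", i, ": ", ln)
  }
  if (!any(rec)) stop("no ATOM/HETATM records found in ", path)
  invisible(lines)
}

rebuild_peptide_flags <- function(df) {
  # df: strand, resi, resn(1-letter), atom, unit, het, x, y, z
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$het) {
      role <- switch(substr(r$atom, 1, 1), D = "donor", A = "acceptor",
                     R = "aromatic", "aromatic")
      out <- ligand_site_row(role, c(r$x, r$y, r$z),
                             substr(r$atom, 2, nchar(r$atom)))
      out$atom <- r$atom
      return(out)
    }
    out <- make_site_rows(r$resn, r$resi, stats::setNames(
      list(c(r$x, r$y, r$z)), r$atom))
    out$strand <- r$strand
    out
  })
  out <- do.call(rbind, rows)
  out$unit <- df$unit
  rownames(out) <- NULL
  out
}

#' Read a multi-model PDB file
#'
#' One MODEL yields a structure (site table with chain-to-strand mapping
#' preserved); two or more MODELs yield a `trajectory`. Lowercase chains
#' are interpreted as the second sheet of a core model, chain L as the
#' ligand. Malformed ATOM records are reported with their line number.
#'
#' @param path PDB file path.
#' @return An `xbeta_structure` or a `trajectory`.
#' @export
read_pdb_models <- function(path) {
  validate_pdb_lines(path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (length(pdb$xyz) %% (3 * nrow(at)) != 0)
    stop("inconsistent topology across models in ", path)
  aa1 <- names(AA3)[match(at$resid, AA3)]
  het <- at$type == "HETATM" | at$resid == "LIG"
  if (any(is.na(aa1) & !het))
    stop("unknown residue name(s): ",
         paste(unique(at$resid[is.na(aa1) & !het]), collapse = ", "))
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  lower <- chain %in% letters & !het
  unit <- ifelse(het, "ligand", ifelse(lower, "sheet2",
                 if (any(lower)) "sheet1" else "mono"))
  df <- data.frame(strand = ifelse(het, "L", toupper(chain)),
                   resi = at$resno, resn = ifelse(het, "X", aa1),
                   atom = at$elety, unit = unit, het = het,
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  sites <- rebuild_peptide_flags(df)
  if (n_models == 1)
    return(structure(list(sites = sites), class = "xbeta_structure"))
  frames <- lapply(seq_len(n_models), function(m)
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE))
  sites <- set_coords(sites, frames[[1]])
  trajectory(sites, frames, meta = list(source = path))
}
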