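# Delimited-text IO: contact maps as CSV with a commented metadata header,
# kinetic traces and spectra as plain CSV, fits and verdicts as JSON.

#' Write a contact map to CSV
#'
#' Rows are residue positions; columns are `<strand>_<type>` count cells.
#' Metadata (cutoffs, frame count, partner) is stored in `#`-prefixed
#' header lines so the file round-trips losslessly.
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  d <- dim(map$counts)
  strands <- dimnames(map$counts)$strand
  types <- dimnames(map$counts)$type
  wide <- data.frame(position = seq_len(d[1]))
  for (s in strands) for (ty in types)
    wide[[paste(s, ty, sep = "_")]] <- map$counts[, s, ty]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# contact_map"),
    sprintf("# hb_cutoff: %g", map$hb_cutoff),
    sprintf("# vdw_cutoff: %g", map$vdw_cutoff),
    sprintf("# frames: %d", map$frames),
    sprintf("# partner: %s", map$partner)), con)
  utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contact map from CSV
#'
#' @param path Path written by [write_map_csv()] (or hand-written in the
#'   same layout).
#' @return A `contact_map`.
#' @export
read_map_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(hb_cutoff = 3.0, vdw_cutoff = 2.3, frames = 0L,
               partner = "partner")
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.+)$", h))[[1]]
    if (length(kv) == 3)
      meta[[kv[2]]] <- if (kv[2] %in% c("hb_cutoff", "vdw_cutoff"))
        as.numeric(kv[3]) else if (kv[2] == "frames") as.integer(kv[3]) else kv[3]
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  if (names(df)[1] != "position") stop("first column must be `position`")
  cells <- names(df)[-1]
  parts <- strsplit(cells, "_")
  if (any(vapply(parts, length, 0L) != 2))
    stop("cell columns must be named <strand>_<type>")
  strands <- unique(vapply(parts, `[`, "", 1))
  types <- unique(vapply(parts, `[`, "", 2))
  if (!all(types %in% c("hbond", "vdw"))) stop("unknown interaction type")
  map <- empty_contact_map(nrow(df), strands, meta$partner,
                           meta$hb_cutoff, meta$vdw_cutoff)
  for (k in seq_along(cells)) {
    s <- parts[[k]][1]; ty <- parts[[k]][2]
    map$counts[, s, ty] <- as.integer(df[[cells[k]]])
  }
  map$frames <- meta$frames
  map
}

#' Read a kinetic trace from a two-column CSV
#'
#' @param path CSV with columns time (h) and value.
#' @return A `kinetic_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("trace CSV needs two columns (time, value)")
  kinetic_trace(df[[1]], df[[2]])
}

#' Write a kinetic trace to CSV
#' @param trace A `kinetic_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, value = trace$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a Congo red spectrum set from CSV
#'
#' @param path CSV with columns wavelength, B, C, D.
#' @return A `spectrum_set`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength", "B", "C", "D")
  if (!all(need %in% names(df)))
    stop("spectra CSV needs columns: ", paste(need, collapse = ", "))
  spectrum_set(df$wavelength, df$B, df$C, df$D)
}

#' Write a Congo red spectrum set to CSV
#' @param spectra A `spectrum_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  utils::write.csv(data.frame(wavelength = spectra$wavelength,
                              B = spectra$B, C = spectra$C, D = spectra$D),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a fit, ledger or verdict as JSON
#'
#' @param x A fit result, `energy_ledger` or `ligand_verdict`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' Cutoffs, scorer constants, classifier thresholds, reporting policy and
#' seed defaults used by the command-line interface; any subset can be
#' overridden from a YAML file via [read_config()].
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(hb_cutoff = 3.0, vdw_cutoff = 2.3,
       scorer = scorer_defaults(), geometry = geometry_defaults(),
       tolerance = 20, overlap_threshold = 0.3,
       rounding = "integer-kcal", seed = 1)
}

#' Read a YAML run configuration
#'
#' Values in the file override [default_config()]; unknown keys are kept.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!(all(vapply(cfg[c("hb_cutoff", "vdw_cutoff")], is.numeric, TRUE))))
    stop("cutoffs must be numeric")
  cfg[names(user)] <- user
  if (cfg$hb_cutoff <= 0 || cfg$vdw_cutoff <= 0)
    stop("cutoffs must be positive")
  cfg
}
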