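#' Read a PLUMED COLVAR-dialect file
#'
#' Whitespace-separated numeric table preceded by a \code{#! FIELDS ...}
#' header naming the columns; further comment lines (leading \code{#})
#' are skipped. Row widths are validated against the header and the time
#' column must be strictly increasing.
#'
#' @param path File path.
#' @param timeColumn Name of the time column (default "time").
#' @return data.frame with the header's columns, plus attribute
#'   \code{fields}.
#' @export
readColvar <- function(path, timeColumn = "time") {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS\\b", lines)
  if (!length(hdr)) .stopf("format error: missing '#! FIELDS' header in %s", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[hdr[1L]]), "\\s+")[[1L]]
  dataIdx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- strsplit(trimws(lines[dataIdx]), "\\s+")
  widths <- lengths(rows)
  bad <- which(widths != length(fields))
  if (length(bad))
    .stopf("format error at line %d of %s: %d value(s) under a %d-field header",
           dataIdx[bad[1L]], path, widths[bad[1L]], length(fields))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    badRow <- dataIdx[ceiling(which(is.na(vals))[1L] / length(fields))]
    .stopf("format error at line %d of %s: non-numeric value", badRow, path)
  }
  df <- as.data.frame(matrix(vals, ncol = length(fields), byrow = TRUE))
  names(df) <- fields
  if (timeColumn %in% fields && any(diff(df[[timeColumn]]) <= 0))
    .stopf("validation error in %s: time column not strictly increasing", path)
  attr(df, "fields") <- fields
  df
}

#' Write a COLVAR-dialect file
#'
#' Values are written with enough digits that a read/write round trip is
#' numerically faithful to better than 1e-10 relative tolerance.
#'
#' @param df data.frame of numeric columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeColvar <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  body <- apply(df, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Convert a COLVAR table to a BiasedTrajectory
#'
#' @param colvar data.frame from \code{\link{readColvar}}.
#' @param ligandId Ligand id to stamp.
#' @param temperature Temperature in Kelvin.
#' @param biasColumn Name of the instantaneous bias column; PLUMED
#'   dialects differ ("metad.bias" vs "bias"), so it is configurable.
#' @param zColumn,contactsColumn,timeColumn Column names.
#' @return A \linkS4class{BiasedTrajectory}.
#' @export
colvarToTrajectory <- function(colvar, ligandId, temperature = 300,
                               biasColumn = "metad.bias", zColumn = "z",
                               contactsColumn = "contacts",
                               timeColumn = "time") {
  for (cn in c(timeColumn, zColumn, contactsColumn, biasColumn))
    if (!cn %in% names(colvar)) .stopf("COLVAR table lacks column '%s'", cn)
  BiasedTrajectory(ligandId,
    data.frame(time = colvar[[timeColumn]], z = colvar[[zColumn]],
               contacts = colvar[[contactsColumn]],
               bias = colvar[[biasColumn]]),
    temperature = temperature)
}

#' Write a BiasedTrajectory as a COLVAR file
#'
#' @param traj A \linkS4class{BiasedTrajectory}.
#' @param path Output path.
#' @param biasColumn Bias column name to emit.
#' @return \code{path}, invisibly.
#' @export
trajectoryToColvar <- function(traj, path, biasColumn = "metad.bias") {
  fr <- frames(traj)
  names(fr)[names(fr) == "bias"] <- biasColumn
  writeColvar(fr, path)
}

#' Read a ligand metadata table
#'
#' CSV with one row per ligand: ligand_id, smiles, substituent_class
#' (parent / R2_modified / R1_R4_modified / morphinan) and optional
#' positive-valued columns tau_cal_s, tau_exp_s, kd_nM, ki_nlx_nM; blank
#' cells become NA (a quantity not measured for that compound).
#'
#' @param path CSV path.
#' @return Validated data.frame of ligand records.
#' @export
readLigandTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ligand_id = "character"))
  need <- c("ligand_id", "smiles", "substituent_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("ligand table is missing column(s): %s", paste(miss, collapse = ", "))
  dup <- df$ligand_id[duplicated(df$ligand_id)]
  if (length(dup))
    .stopf("validation error: duplicate ligand_id '%s'", dup[1L])
  bad <- setdiff(unique(df$substituent_class), .LIGAND_CLASSES)
  if (length(bad))
    .stopf("validation error: unknown substituent class '%s'", bad[1L])
  for (cn in intersect(c("tau_cal_s", "tau_exp_s", "kd_nM", "ki_nlx_nM"),
                       names(df))) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (any(df[[cn]] <= 0, na.rm = TRUE))
      .stopf("validation error: non-positive value in '%s'", cn)
  }
  df
}

#' Write a ligand metadata table
#'
#' @param records Ligand record data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLigandTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an interaction-energy table
#'
#' @param path CSV path with the schema of
#'   \code{\link{validateEnergyTable}}.
#' @return Validated energy table.
#' @export
readEnergyTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ligand_id = "character"))
  validateEnergyTable(df)
  df
}

#' Write result tables with a schema sidecar
#'
#' Each named data.frame is written to \code{<outdir>/<name>.csv}; a
#' \code{schema.txt} sidecar documents the column units.
#'
#' @param tables Named list of data.frames.
#' @param outdir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
writeResults <- function(tables, outdir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "")
    p
  }, character(1))
  units <- c(
    "times: ps in trajectory frames, ns for wall times, s for residence times",
    "energies and free energies: kcal/mol", "distances (z): Angstrom",
    "targets: log10 of residence time in seconds",
    "affinities (kd_nM, ki_nlx_nM): nM")
  writeLines(c("MetadKinetics output schema", units),
             file.path(outdir, "schema.txt"))
  invisible(paths)
}

#' Read a flat key = value run configuration
#'
#' Sections in square brackets namespace the keys
#' (\code{section.key = value}); unknown keys are rejected.
#'
#' @param path Config file path.
#' @return Named list of values (numerics parsed where possible).
#' @export
readRunConfig <- function(path) {
  known <- c("temperature", "z_threshold", "ks_threshold",
             "bootstrap.n_boot", "bootstrap.size",
             "filter.magnitude_cutoff", "filter.spread_cutoff",
             "augment.block_size", "augment.n_aug",
             "ml.split", "ml.folds", "ml.trials", "ml.models", "ml.top_k",
             "seed", "paths.input", "paths.output", "colvar.bias_column",
             "simulate.tau_true_s", "simulate.n_traj", "simulate.hill_height",
             "simulate.n_ligands", "simulate.n_pairs",
             "simulate.frames_per_ligand")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) .stopf("config parse error: '%s'", ln)
    key <- trimws(kv[1L])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    if (!key %in% known) .stopf("unknown config key: '%s'", key)
    val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
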