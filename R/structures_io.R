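#' Read molecular structures or a descriptor table
#'
#' Supported inputs: SMILES files (one molecule per line, whitespace
#' separated `SMILES id`, missing id -> `mol<line>`), SDF V2000, and CSV
#' descriptor tables with the case-sensitive columns `MW, LogP, HBA, HBD,
#' RB, arR` (optionally `arB` and `id`). Unparseable structure entries are
#' skipped, counted and reported with their line numbers via a warning and
#' the `"skipped"` attribute — never silently dropped.
#'
#' @param path Input file path.
#' @param format One of `"smiles"`, `"sdf"`, `"csv"`; default inferred
#'   from the file extension (`.smi`/`.smiles`, `.sdf`, `.csv`).
#' @return A data frame of class `"molecule_set"` with columns `id`,
#'   `smiles` (NA for descriptor tables), `source_line`, plus descriptor
#'   columns for CSV input. Duplicated ids are suffixed deterministically.
#' @export
read_structures <- function(path, format = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smiles", smiles = "smiles", sdf = "sdf",
                     csv = "csv",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format="))
  }
  format <- match.arg(format, c("smiles", "sdf", "csv"))
  out <- switch(format,
                smiles = read_smiles_file(path),
                sdf = read_sdf_file(path),
                csv = read_descriptor_csv(path))
  if (nrow(out) == 0L) stop("no parseable records in ", path)
  out$id <- make.unique(as.character(out$id), sep = "_")
  class(out) <- c("molecule_set", "data.frame")
  out
}

smiles_parses <- function(smi) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(smi, "\n"))),
    error = function(e) "")
  nzchar(trimws(out))
}

read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list(); skipped <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2L) paste(parts[-1], collapse = " ")
          else paste0("mol", i)
    if (!smiles_parses(smi)) { skipped <- c(skipped, i); next }
    recs[[length(recs) + 1L]] <- data.frame(id = id, smiles = smi,
                                            source_line = i)
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(id = character(0), smiles = character(0),
                         source_line = integer(0))
  if (length(skipped))
    warning(length(skipped), " unparseable SMILES skipped (lines ",
            paste(skipped, collapse = ", "), ")")
  attr(out, "skipped") <- skipped
  out
}

read_sdf_file <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdf)
  skipped <- which(!ok)
  sdf <- sdf[ok]
  if (length(sdf) == 0L)
    return(structure(data.frame(id = character(0), smiles = character(0),
                                source_line = integer(0)),
                     skipped = skipped))
  ids <- as.character(ChemmineR::sdfid(sdf))
  ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  out <- data.frame(id = ids, smiles = smi, source_line = which(ok))
  if (length(skipped))
    warning(length(skipped), " invalid SDF records skipped (positions ",
            paste(skipped, collapse = ", "), ")")
  attr(out, "skipped") <- skipped
  out
}

descriptor_columns <- c("MW", "LogP", "HBA", "HBD", "RB", "arR")

read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(descriptor_columns, names(df))
  if (length(missing_cols))
    stop("descriptor CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  id <- if ("id" %in% names(df)) as.character(df$id)
        else paste0("mol", seq_len(nrow(df)))
  keep <- intersect(c(descriptor_columns, "arB"), names(df))
  extra <- setdiff(names(df), c("id", keep))
  out <- data.frame(id = id, smiles = NA_character_,
                    source_line = seq_len(nrow(df)),
                    df[, c(keep, extra), drop = FALSE],
                    check.names = FALSE)
  attr(out, "skipped") <- integer(0)
  out
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("Molecule set: %d records (%s)\n", nrow(x),
              if (all(is.na(x$smiles))) "descriptor table"
              else "structures"))
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped input entries:", length(sk), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Normalize a molecular structure
#'
#' Reduces each structure to its largest fragment (salt stripping),
#' neutralizes charges where chemically valid (quaternary centres are left
#' as drawn), and canonicalizes the SMILES. The operation is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of normalized canonical SMILES; `NA` where
#'   normalization failed (failures are reported via a warning).
#' @examples
#' \dontrun{normalize_structure("CC(=O)[O-].[Na+]")  # "CC(=O)O"}
#' @export
normalize_structure <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste0(s, "\n"),
        options = data.frame(names = c("r", "neutralize"),
                             args = c("", "")))),
      error = function(e) "")
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else strsplit(out, "[[:space:]]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname normalize_structure
#' @param mols A `"molecule_set"` with structures.
#' @return For `normalize_structures()`: the set with `smiles` replaced by
#'   normalized SMILES; failed records are dropped with a warning and
#'   recorded in the `"norm_failed"` attribute.
#' @export
normalize_structures <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"))
  if (all(is.na(mols$smiles)))
    stop("molecule set has no structures (descriptor-table input)")
  norm <- normalize_structure(mols$smiles)
  failed <- which(is.na(norm))
  if (length(failed))
    warning(length(failed), " structure(s) failed normalization (ids: ",
            paste(mols$id[failed], collapse = ", "), "); excluded")
  out <- mols[setdiff(seq_len(nrow(mols)), failed), , drop = FALSE]
  out$smiles <- norm[setdiff(seq_along(norm), failed)]
  attr(out, "norm_failed") <- mols$id[failed]
  attr(out, "skipped") <- attr(mols, "skipped")
  class(out) <- class(mols)
  out
}

#' Write a score report CSV
#'
#' One row per molecule: id, the six descriptors, the five likeness scores
#' (4 decimal places) and, when present, filter pass/violation columns.
#'
#' @param scores A data frame as returned by [score_batch()] (optionally
#'   merged with descriptors/filters).
#' @param path Output path.
#' @export
write_score_csv <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1)) &
    names(out) %in% c("QEH", "QEI", "QEF", "QEPmax", "QEPavg")
  out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
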