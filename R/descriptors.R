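#' Compute the six scoring descriptors (plus aromatic-bond count)
#'
#' For each structure: molecular weight (`MW`, average atomic masses, Da),
#' a Crippen-type atom-contribution `LogP`, hydrogen-bond acceptor and
#' donor counts (`HBA`, `HBD`, toolkit perception), rotatable-bond count
#' (`RB`: acyclic single bonds between two non-terminal heavy atoms, amide
#' C-N excluded), aromatic-ring count (`arR`: aromatic members of the
#' smallest set of smallest rings) and aromatic-bond count (`arB`, used
#' only by the Hao filter).
#'
#' Perception is delegated to OpenBabel via \pkg{ChemmineOB}/\pkg{ChemmineR};
#' the rotatable-bond definition is enforced by SMARTS
#' (`[!D1]-!@[!D1]` minus acyclic amide `[CX3](=O)-!@[NX3;!D1]` matches).
#'
#' @param x A `"molecule_set"` with structures (see [read_structures()]),
#'   or a character vector of SMILES.
#' @return A data frame with columns `id, MW, LogP, HBA, HBD, RB, arR, arB`.
#' @examples
#' \dontrun{compute_descriptors(c(benzene = "c1ccccc1"))}
#' @export
compute_descriptors <- function(x) {
  if (inherits(x, "molecule_set")) {
    if (all(is.na(x$smiles)))
      stop("molecule set has no structures; use the descriptor-table ",
           "columns directly")
    smiles <- x$smiles
    ids <- x$id
  } else if (is.character(x)) {
    smiles <- unname(x)
    ids <- if (!is.null(names(x))) names(x)
           else paste0("mol", seq_along(x))
  } else stop("x must be a molecule_set or a character vector of SMILES")
  if (length(smiles) == 0L) stop("no structures to process")

  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
  props <- ChemmineR::propOB(sdf)
  rb_all <- ChemmineR::smartsSearchOB(sdf, "[!D1]-!@[!D1]")
  rb_amide <- ChemmineR::smartsSearchOB(sdf, "[CX3](=O)-!@[NX3;!D1]")
  ar <- aromatic_ring_counts(sdf)

  data.frame(id = ids,
             MW = as.numeric(props$MW),
             LogP = as.numeric(props$logP),
             HBA = as.integer(props$HBA2),
             HBD = as.integer(props$HBD),
             RB = as.integer(rb_all - rb_amide),
             arR = ar$arR, arB = ar$arB,
             row.names = NULL)
}

# Aromatic ring (SSSR) and aromatic bond counts from ChemmineR ring
# perception; arB is the union of ring-edge bonds over aromatic rings, so
# fused systems count shared bonds once (naphthalene: 2 rings, 11 bonds).
aromatic_ring_counts <- function(sdf) {
  r <- ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = TRUE)
  # single-molecule input returns an unnested list
  if (!is.null(names(r)) && all(c("RINGS", "AROMATIC") %in% names(r)))
    r <- list(r)
  res <- vapply(r, function(m) {
    arom <- as.logical(unlist(m$AROMATIC))
    if (length(arom) == 0L || !any(arom)) return(c(arR = 0L, arB = 0L))
    rings <- m$RINGS[arom]
    edges <- unlist(lapply(rings, function(at) {
      n <- length(at)
      vapply(seq_len(n), function(i)
        paste(sort(c(at[i], at[i %% n + 1L])), collapse = "|"),
        character(1))
    }))
    c(arR = sum(arom), arB = length(unique(edges)))
  }, integer(2))
  list(arR = unname(res["arR", ]), arB = unname(res["arB", ]))
}

#' Assemble a descriptor table from mixed input
#'
#' Convenience dispatcher: descriptor-table molecule sets pass through
#' (validated); structure sets are normalized and descriptors computed.
#'
#' @param mols A `"molecule_set"`.
#' @param normalize Normalize structures first (default `TRUE`).
#' @param logp_column Optional name of a column holding vendor-supplied
#'   logP values to use instead of the built-in estimator (descriptor-table
#'   input only).
#' @return Descriptor data frame with `id` plus `MW, LogP, HBA, HBD, RB,
#'   arR` and, when available, `arB`.
#' @export
descriptor_table <- function(mols, normalize = TRUE, logp_column = NULL) {
  stopifnot(inherits(mols, "molecule_set"))
  if (all(is.na(mols$smiles))) {
    out <- as.data.frame(mols)
    if (!is.null(logp_column)) {
      if (!logp_column %in% names(out))
        stop("logP column '", logp_column, "' not found")
      out$LogP <- as.numeric(out[[logp_column]])
    }
    for (col in descriptor_columns)
      out[[col]] <- as.numeric(out[[col]])
    bad <- descriptor_columns[vapply(descriptor_columns,
                                     function(cl) anyNA(out[[cl]]),
                                     logical(1))]
    if (length(bad))
      stop("non-numeric or missing values in column(s): ",
           paste(bad, collapse = ", "))
    keep <- intersect(c("id", descriptor_columns, "arB"), names(out))
    return(out[, keep, drop = FALSE])
  }
  if (normalize) mols <- normalize_structures(mols)
  compute_descriptors(mols)
}
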