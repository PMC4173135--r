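#' Synthetic descriptor populations
#'
#' Generates labelled descriptor populations for fitting and for
#' active-vs-decoy enrichment tests. Pesticide-class populations draw each
#' descriptor independently from a zero-offset Gumbel-peak density (the
#' same family the profiles fit); decoys draw uniformly over broad ranges
#' straddling all class modes. Everything is reproducible from the seed.
#'
#' The default class shapes emulate the physicochemical profiles of the
#' three pesticide classes — rotatable-bond peaks at 2 (fungicides),
#' 5 (herbicides) and 6 (insecticides); insecticides most hydrophobic
#' with maximal desirability near logP 5 and at zero aromatic rings;
#' herbicides and fungicides more hydrophilic; molecular weights centred
#' in the 300-360 Da range typical of marketed pesticides.
#'
#' @param class_label `"H"`, `"I"`, `"F"` or `"decoy"`.
#' @param n Number of molecules, > 0.
#' @param seed Integer seed.
#' @param params Optional per-descriptor generating parameters; for
#'   pesticide classes a named list of `list(o, a, b, c)` per descriptor,
#'   for decoys a named list of `c(lo, hi)` ranges. Defaults are the
#'   packaged reference shapes.
#' @return For `population_spec()`: an object of class
#'   `"population_spec"`.
#' @export
population_spec <- function(class_label = c("H", "I", "F", "decoy"),
                            n, seed = 1L, params = NULL) {
  class_label <- match.arg(class_label)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  if (is.null(params)) params <- default_population_params(class_label)
  structure(list(class_label = class_label, n = as.integer(n),
                 seed = as.integer(seed), params = params),
            class = "population_spec")
}

discrete_descriptors <- c("HBA", "HBD", "RB", "arR")

#' @rdname population_spec
#' @export
default_population_params <- function(class_label) {
  peaks <- switch(class_label,
    H = list(MW = c(b = 330, c = 60), LogP = c(b = 3.0, c = 1.0),
             HBA = c(b = 3, c = 1.2), HBD = c(b = 1, c = 0.7),
             RB = c(b = 5, c = 1.8), arR = c(b = 1, c = 0.8)),
    I = list(MW = c(b = 360, c = 70), LogP = c(b = 5.0, c = 1.2),
             HBA = c(b = 2, c = 1.0), HBD = c(b = 0, c = 0.8),
             RB = c(b = 6, c = 2.0), arR = c(b = 0, c = 0.9)),
    F = list(MW = c(b = 300, c = 55), LogP = c(b = 3.0, c = 1.1),
             HBA = c(b = 2, c = 1.0), HBD = c(b = 1, c = 0.6),
             RB = c(b = 2, c = 1.2), arR = c(b = 2, c = 0.8)),
    decoy = NULL)
  if (class_label == "decoy")
    return(list(MW = c(50, 1200), LogP = c(-5, 12), HBA = c(0, 25),
                HBD = c(0, 10), RB = c(0, 25), arR = c(0, 10)))
  lapply(peaks, function(p) list(o = 0, a = 1, b = p[["b"]], c = p[["c"]]))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# rejection sampler from the zero-offset peak density on [b-10c, b+10c];
# acceptance rate is e/20 ~ 13.6% analytically, guarded at 1%
sample_peak <- function(n, o, a, b, cw, max_tries = 400L) {
  lo <- b - 10 * cw; hi <- b + 10 * cw
  height <- o + a
  out <- numeric(0); proposed <- 0L
  for (k in seq_len(max_tries)) {
    m <- max(1000L, 4L * (n - length(out)))
    x <- stats::runif(m, lo, hi)
    u <- stats::runif(m, 0, height)
    acc <- u <= gumbel_peak(x, o, a, b, cw)
    out <- c(out, x[acc])
    proposed <- proposed + m
    if (length(out) >= n) break
    if (proposed > 2000L && length(out) / proposed < 0.01)
      stop("rejection acceptance rate below 1%; degenerate spec")
  }
  if (length(out) < n)
    stop("rejection sampling failed to reach n = ", n)
  out[seq_len(n)]
}

#' @rdname population_spec
#' @param spec A `"population_spec"`.
#' @return For `sample_population()`: a descriptor data frame with
#'   columns `MW, LogP, HBA, HBD, RB, arR` and attribute `"class_label"`;
#'   integer descriptors are rounded and clamped at zero.
#' @examples
#' head(sample_population(population_spec("H", n = 100, seed = 7)))
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    cols <- lapply(names(spec$params), function(d) {
      p <- spec$params[[d]]
      x <- if (spec$class_label == "decoy")
        stats::runif(spec$n, p[[1]], p[[2]])
      else sample_peak(spec$n, p$o, p$a, p$b, p$c)
      if (d %in% discrete_descriptors) pmax(0, round(x)) else x
    })
    names(cols) <- names(spec$params)
    out <- as.data.frame(cols)
    if ("MW" %in% names(out)) out$MW <- pmax(out$MW, 1e-6)
    attr(out, "class_label") <- spec$class_label
    out
  })
}

#' Frozen fixture molecules with hand-verified descriptors
#'
#' A small set of hand-checkable molecules with expected descriptor
#' values frozen under the package's documented conventions: MW by
#' summation of average atomic masses; HBA as the
#' Lipinski-style nitrogen-plus-oxygen count (amide N included: urea has
#' 3); HBD as donor heavy atoms bearing at least one H, not H count
#' (urea has 2); RB as
#' acyclic single bonds between non-terminal heavy atoms with amide C-N
#' excluded; arR as aromatic smallest-set-of-smallest rings; arB as the
#' union of their bonds. logP is not frozen (estimator-specific).
#'
#' @return Data frame: `id, smiles, MW, HBA, HBD, RB, arR, arB`.
#' @export
fixture_molecules <- function() {
  utils::read.csv(text = 'id,smiles,MW,HBA,HBD,RB,arR,arB
benzene,c1ccccc1,78.11184,0,0,0,1,6
toluene,Cc1ccccc1,92.13842,0,0,0,1,6
n-propylbenzene,CCCc1ccccc1,120.19158,0,0,2,1,6
biphenyl,c1ccccc1-c1ccccc1,154.2078,0,0,1,2,12
naphthalene,c1ccc2ccccc2c1,128.17052,0,0,0,2,11
styrene,C=Cc1ccccc1,104.14912,0,0,1,1,6
cyclohexane,C1CCCCC1,84.15948,0,0,0,0,0
n-hexane,CCCCCC,86.17536,0,0,3,0,0
ethanol,CCO,46.06844,1,1,0,0,0
acetic acid,CC(=O)O,60.05196,2,1,0,0,0
acetone,CC(=O)C,58.07914,1,0,0,0,0
urea,NC(=O)N,60.05526,3,2,0,0,0
N-methylacetamide,CC(=O)NC,73.09378,2,1,0,0,0
phenol,Oc1ccccc1,94.11124,1,1,0,1,6
aniline,Nc1ccccc1,93.12648,1,1,0,1,6
pyridine,c1ccncc1,79.0999,1,0,0,1,6
furan,c1ccoc1,68.07396,1,0,0,1,5
benzamide,NC(=O)c1ccccc1,121.13658,2,1,1,1,6
anisole,COc1ccccc1,108.13782,1,0,1,1,6
benzonitrile,N#Cc1ccccc1,103.1213,1,0,1,1,6',
    check.names = FALSE, stringsAsFactors = FALSE)
}
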