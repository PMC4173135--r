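# Shared helpers: independent oracles and fixture builders.

# noiseless histogram-like object generated from known peak parameters
peak_histogram <- function(o, a, b, cw, n_bins = 30, span = c(-5, 9),
                           descriptor = "MW") {
  centers <- seq(b + span[1] * cw, b + span[2] * cw, length.out = n_bins)
  t <- (centers - b) / cw
  list(centers = centers, counts = o + a * exp(-exp(-t) - t + 1),
       descriptor = descriptor)
}

# brute-force pairwise AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counting one half
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# independent Shimazaki-Shinomoto cost: rebin by explicit comparison loops
# (deliberately not the package's findInterval/tabulate path)
oracle_ss_cost <- function(values, width) {
  lo <- min(values)
  m <- max(1, ceiling((max(values) - lo) / width))
  edges <- lo + width * (0:m)
  if (edges[m + 1] < max(values)) edges <- c(edges, edges[m + 1] + width)
  k <- vapply(seq_len(length(edges) - 1), function(i) {
    hi_edge <- edges[i + 1]
    if (i == length(edges) - 1)
      sum(values >= edges[i] & values <= hi_edge)
    else sum(values >= edges[i] & values < hi_edge)
  }, numeric(1))
  kbar <- mean(k)
  (2 * kbar - mean((k - kbar)^2)) / width^2
}

# three fitted class profiles on small synthetic populations, cached per
# test run (fitting is deterministic given the seeds)
fitted_test_profiles <- local({
  cache <- NULL
  function(n = 1500) {
    if (is.null(cache)) {
      cache <<- lapply(c(H = "H", I = "I", F = "F"), function(cl) {
        seed <- c(H = 31L, I = 32L, F = 33L)[[cl]]
        pesticide_profile(
          sample_population(population_spec(cl, n = n, seed = seed)),
          class_label = cl, seed = 1)
      })
    }
    cache
  }
})

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "qepest", package = "qepest")

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(rscript_bin(), c(cli_path(), args), stdout = TRUE,
            stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
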