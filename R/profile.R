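#' Fit a pesticide-class desirability profile
#'
#' The central model fit: for one compound class (herbicide `"H"`,
#' insecticide `"I"` or fungicide `"F"`), fits the shared Gumbel-peak
#' desirability function to the distribution of each of the six
#' descriptors. Continuous descriptors (`MW`, `LogP`) are binned at the
#' Shimazaki-Shinomoto optimal width; integer descriptors (`HBA`, `HBD`,
#' `RB`, `arR`) use unit bins. Each fitted peak is scaled by its analytic
#' maximum `o + a` so the per-descriptor desirability lies in `[0, 1]`.
#'
#' @param data Descriptor data frame with the columns
#'   `MW, LogP, HBA, HBD, RB, arR` (e.g. from [descriptor_table()] or
#'   [sample_population()]); at least 50 rows.
#' @param class_label One of `"H"`, `"I"`, `"F"`.
#' @param n_starts Multi-start count passed to [fit_desirability()].
#' @param seed Seed for the fit starts (deterministic).
#' @return An object of class `"pesticide_profile"`: the six scaled
#'   [desirability_params()] (`$params`), the underlying fits (`$fits`),
#'   histograms (`$histograms`), `$class_label` and `$n`.
#' @seealso [predict.pesticide_profile()], [score_batch()],
#'   [write_profiles()]
#' @export
pesticide_profile <- function(data, class_label = c("H", "I", "F"),
                              n_starts = 8L, seed = 1L) {
  class_label <- match.arg(class_label)
  data <- as.data.frame(data)
  missing_cols <- setdiff(descriptor_columns, names(data))
  if (length(missing_cols))
    stop("data is missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(data) < 50L)
    stop("need at least 50 molecules to fit a class profile (got ",
         nrow(data), ")")

  continuous <- c("MW", "LogP")
  params <- list(); fits <- list(); hists <- list()
  for (d in descriptor_columns) {
    v <- as.numeric(data[[d]])
    h <- tryCatch({
      if (d %in% continuous) {
        w <- optimal_bin_width(v)$width
        histogram_continuous(v, w, descriptor = d)
      } else histogram_discrete(v, descriptor = d)
    }, error = function(e)
      stop("histogram failed for descriptor ", d, " (class ", class_label,
           "): ", conditionMessage(e)))
    fit <- fit_desirability(h, n_starts = n_starts, seed = seed)
    if (is.null(fit$params))
      stop("desirability fit failed for descriptor ", d, " (class ",
           class_label, ")")
    fit$params$class_label <- class_label
    params[[d]] <- fit$params
    fits[[d]] <- fit
    hists[[d]] <- h
  }
  structure(list(class_label = class_label, params = params, fits = fits,
                 histograms = hists, n = nrow(data)),
            class = "pesticide_profile")
}

#' @export
print.pesticide_profile <- function(x, ...) {
  cat(sprintf("Pesticide-class desirability profile (class %s, n = %s)\n",
              x$class_label, x$n %||% "?"))
  print(coef(x))
  invisible(x)
}

#' @export
coef.pesticide_profile <- function(object, ...) {
  t(vapply(object$params, function(p)
    c(o = p$o, a = p$a, b = p$b, c = p$c, max_value = p$max_value),
    numeric(5)))
}

#' @export
summary.pesticide_profile <- function(object, ...) {
  cf <- coef(object)
  sse <- vapply(object$fits %||% list(), function(f) f$sse, numeric(1))
  out <- list(class_label = object$class_label, n = object$n,
              coefficients = cf,
              sse = if (length(sse)) sse else NULL)
  class(out) <- "summary.pesticide_profile"
  out
}

#' @export
print.summary.pesticide_profile <- function(x, ...) {
  cat(sprintf("Class %s profile fitted on %s molecules\n", x$class_label,
              x$n %||% "?"))
  cf <- x$coefficients
  if (!is.null(x$sse)) cf <- cbind(cf, SSE = x$sse)
  print(cf)
  invisible(x)
}

#' Score molecules against a fitted class profile
#'
#' @param object A `"pesticide_profile"`.
#' @param newdata Descriptor data frame (columns `MW, LogP, HBA, HBD, RB,
#'   arR`).
#' @param type `"score"` for the geometric-mean class score (QEX),
#'   `"desirability"` for the six per-descriptor desirabilities.
#' @param ... Unused.
#' @return Numeric vector of scores, or a matrix of desirabilities.
#' @export
predict.pesticide_profile <- function(object, newdata,
                                      type = c("score", "desirability"),
                                      ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(descriptor_columns, names(newdata))
  if (length(missing_cols))
    stop("newdata is missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  dfm <- vapply(descriptor_columns, function(d)
    eval_df(as.numeric(newdata[[d]]), object$params[[d]]),
    numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) dfm <- matrix(dfm, nrow = 1L,
                                         dimnames = list(NULL,
                                                         descriptor_columns))
  if (type == "desirability") return(dfm)
  geometric_mean_rows(dfm)
}

#' @export
residuals.pesticide_profile <- function(object, ...) {
  if (is.null(object$fits)) stop("profile carries no fit residuals")
  lapply(object$fits, residuals)
}

#' @export
#' @method plot pesticide_profile
plot.pesticide_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (d in descriptor_columns) {
    p <- x$params[[d]]
    if (!is.null(x$fits)) {
      f <- x$fits[[d]]
      graphics::plot(f$x, f$y, pch = 16, cex = 0.6, xlab = d,
                     ylab = "count", main = d)
      xs <- seq(min(f$x), max(f$x), length.out = 200)
      graphics::lines(xs, eval_f(xs, p), col = "red", lwd = 2)
    } else {
      xs <- seq(p$b - 6 * abs(p$c), p$b + 10 * abs(p$c), length.out = 200)
      graphics::plot(xs, eval_df(xs, p), type = "l", col = "red",
                     lwd = 2, xlab = d, ylab = "df", main = d)
    }
  }
  invisible(x)
}

#' Simulate descriptor vectors from a fitted profile
#'
#' Draws synthetic molecules whose descriptors follow the profile's fitted
#' desirability peaks (rejection sampling on a bounded support of
#' `b +/- 10c`); integer descriptors are rounded and clamped at zero.
#'
#' @param object A `"pesticide_profile"`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed (required for reproducibility).
#' @param n Number of molecules per replicate.
#' @param ... Unused.
#' @return A list of `nsim` descriptor data frames (a single data frame if
#'   `nsim = 1`).
#' @export
simulate.pesticide_profile <- function(object, nsim = 1, seed = 1L,
                                       n = 1000L, ...) {
  specs <- lapply(seq_len(nsim), function(k) {
    population_spec(class_label = object$class_label, n = n,
                    seed = as.integer(seed) + (k - 1L),
                    params = lapply(object$params, function(p)
                      list(o = p$o, a = p$a, b = p$b, c = p$c)))
  })
  out <- lapply(specs, sample_population)
  if (nsim == 1) out[[1]] else out
}

#' Read and write desirability coefficient configurations
#'
#' Profiles are serialized as JSON with the schema
#' `{class: {descriptor: {o, a, b, c, max_value}}}`; `write_profiles()` is
#' the output of a fit, `read_profiles()` the input of scoring.
#'
#' @param profiles A named list of `"pesticide_profile"` objects (names
#'   `H`, `I`, `F`), or a single profile.
#' @param path JSON file path.
#' @return `read_profiles()`: a named list of `"pesticide_profile"`
#'   objects (coefficients only).
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "pesticide_profile"))
    profiles <- stats::setNames(list(profiles), profiles$class_label)
  payload <- lapply(profiles, function(pr)
    lapply(pr$params, function(p)
      list(o = p$o, a = p$a, b = p$b, c = p$c, max_value = p$max_value)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(payload), function(cl) {
    raw <- payload[[cl]]
    missing_d <- setdiff(descriptor_columns, names(raw))
    if (length(missing_d))
      stop("profile for class ", cl, " is missing descriptor(s): ",
           paste(missing_d, collapse = ", "))
    params <- lapply(descriptor_columns, function(d) {
      q <- raw[[d]]
      desirability_params(o = q$o, a = q$a, b = q$b, c = q$c,
                          max_value = q$max_value, descriptor = d,
                          class_label = cl)
    })
    names(params) <- descriptor_columns
    structure(list(class_label = cl, params = params, fits = NULL,
                   histograms = NULL, n = NA_integer_),
              class = "pesticide_profile")
  })
  stats::setNames(out, names(payload))
}

#' Packaged reference profiles
#'
#' Loads the profiles shipped with the package. These were fitted on the
#' packaged synthetic reference populations (see [population_spec()]) and
#' are labelled synthetic: they are the package's own calibration, not
#' coefficients from any external compound collection. Supply your own
#' profile JSON to [read_profiles()] to override them.
#'
#' @return Named list of `"pesticide_profile"` objects (`H`, `I`, `F`).
#' @export
default_profiles <- function() {
  path <- system.file("extdata", "synthetic_reference_profiles.json",
                      package = "qepest")
  if (!nzchar(path)) stop("packaged profile file not found")
  read_profiles(path)
}
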