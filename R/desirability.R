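#' Desirability parameter set
#'
#' Container for the coefficients of the shared desirability peak used for
#' every descriptor/class pair:
#' \deqn{f(x) = o + a \exp\left(-e^{-(x-b)/c} - \frac{x-b}{c} + 1\right)}
#' a Gumbel-shaped single peak with baseline offset `o`, amplitude `a`,
#' mode `b` (descriptor units) and width `c` (descriptor units). The scaled
#' desirability is `df(x) = f(x) / max_value`, clamped to `[0, 1]`.
#'
#' @param o Baseline offset (>= 0 for a valid desirability).
#' @param a Amplitude, > 0.
#' @param b Mode location, in descriptor units.
#' @param c Width, in descriptor units; must be non-zero.
#' @param max_value Scaling divisor; `NA` until [scale_desirability()] is
#'   applied. When set it must be positive.
#' @param descriptor Optional descriptor label (`"MW"`, `"LogP"`, `"HBA"`,
#'   `"HBD"`, `"RB"`, `"arR"`).
#' @param class_label Optional class label (`"H"`, `"I"`, `"F"`).
#' @return An object of class `"desirability_params"`.
#' @examples
#' p <- desirability_params(o = 0, a = 1, b = 0, c = 1)
#' eval_f(0, p)  # o + a = 1 at the mode
#' @export
desirability_params <- function(o, a, b, c, max_value = NA_real_,
                                descriptor = NA_character_,
                                class_label = NA_character_) {
  stopifnot(is.numeric(o), is.numeric(a), is.numeric(b), is.numeric(c),
            length(o) == 1L, length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (c == 0) stop("width parameter 'c' must be non-zero")
  if (a <= 0) stop("amplitude 'a' must be positive")
  if (!is.na(max_value) && max_value <= 0)
    stop("'max_value' must be positive when set")
  structure(
    list(o = as.numeric(o), a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), max_value = as.numeric(max_value),
         descriptor = descriptor, class_label = class_label),
    class = "desirability_params"
  )
}

#' @export
print.desirability_params <- function(x, ...) {
  lab <- if (!is.na(x$descriptor)) paste0(" [", x$descriptor,
                                          if (!is.na(x$class_label))
                                            paste0("/", x$class_label), "]")
         else ""
  cat(sprintf("Desirability peak%s: o=%.6g a=%.6g b=%.6g c=%.6g", lab,
              x$o, x$a, x$b, x$c))
  if (!is.na(x$max_value))
    cat(sprintf("  (scaled, max=%.6g)", x$max_value))
  cat("\n")
  invisible(x)
}

# Vectorised core of the peak. Stable for arguments as extreme as
# |(x-b)/c| ~ 700: exp(-t) overflows to Inf there, the outer exponent
# becomes -Inf and the value underflows cleanly to o (never NaN).
gumbel_peak <- function(x, o, a, b, cw) {
  t <- (x - b) / cw
  o + a * exp(-exp(-t) - t + 1)
}

#' Evaluate the unscaled desirability peak
#'
#' @param x Numeric vector of descriptor values.
#' @param params A [desirability_params()] object.
#' @return `f(x)`, same length as `x`.
#' @examples
#' p <- desirability_params(o = 0.1, a = 2, b = 5, c = 2)
#' eval_f(5, p)  # 2.1, the analytic maximum o + a
#' @export
eval_f <- function(x, params) {
  stopifnot(inherits(params, "desirability_params"))
  if (params$c == 0) stop("width parameter 'c' must be non-zero")
  gumbel_peak(x, params$o, params$a, params$b, params$c)
}

#' Scale a desirability peak to the unit interval
#'
#' Sets the scaling divisor to the analytic maximum `o + a`, attained at
#' `x = b`, so that the scaled desirability satisfies `df(b) = 1`.
#'
#' @param params A [desirability_params()] object with `a > 0`.
#' @return The same parameters with `max_value = o + a`.
#' @export
scale_desirability <- function(params) {
  stopifnot(inherits(params, "desirability_params"))
  m <- params$o + params$a
  if (m <= 0) stop("non-positive maximum o + a; cannot scale")
  params$max_value <- m
  params
}

#' Evaluate the scaled desirability
#'
#' `df(x) = max(f(x), 0) / max_value`, clamped to `[0, 1]`.
#'
#' @inheritParams eval_f
#' @return Values in `[0, 1]`, same length as `x`.
#' @export
eval_df <- function(x, params) {
  stopifnot(inherits(params, "desirability_params"))
  if (is.na(params$max_value))
    stop("params are unscaled; call scale_desirability() first")
  f <- eval_f(x, params)
  pmin(pmax(f, 0) / params$max_value, 1)
}

#' Fit the desirability peak to a descriptor histogram
#'
#' Minimises the sum of squared errors between bin counts and the peak
#' evaluated at bin centers, by bounded Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}) with deterministic multi-start. Start 1 uses a
#' heuristic initialisation (o = min count, a = max - min count, b = modal
#' bin center, c = count-weighted standard deviation of the bin centers);
#' the remaining starts perturb b and c by up to +/-50%. Bounds: `a > 0`,
#' `c > 0`, `o >= 0`; `b` free.
#'
#' @param hist A [histogram_continuous()] / [histogram_discrete()] object,
#'   or anything with `$counts` and bin centers (`$centers`).
#' @param n_starts Number of optimisation starts (>= 1).
#' @param seed Integer seed controlling the start perturbations only; the
#'   caller's RNG state is left untouched.
#' @return An object of class `"desirability_fit"` with elements `params`
#'   (scaled [desirability_params()]), `sse`, `converged`, `n_points`,
#'   `fitted`, `residuals` and `starts` (per-start SSE trace).
#' @examples
#' p <- desirability_params(o = 2, a = 40, b = 300, c = 60)
#' x <- seq(100, 600, length.out = 30)
#' h <- list(centers = x, counts = eval_f(x, p), descriptor = "MW")
#' fit <- fit_desirability(h)
#' coef(fit)
#' @export
fit_desirability <- function(hist, n_starts = 8L, seed = 1L) {
  x <- hist$centers
  y <- as.numeric(hist$counts)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L)
    stop("need at least 5 bins to fit the 4-parameter peak")
  if (sum(y) <= 0) stop("histogram has zero total count")

  wm <- sum(x * y) / sum(y)
  wsd <- sqrt(sum(y * (x - wm)^2) / sum(y))
  if (!is.finite(wsd) || wsd <= 0) wsd <- max(diff(range(x)) / 6, 1e-3)
  start1 <- c(o = max(min(y), 0), a = max(max(y) - min(y), 1e-6),
              b = x[which.max(y)], cw = wsd)

  perturb <- with_seed(seed, {
    n <- max(0L, n_starts - 1L)
    list(b = stats::runif(n, -0.5, 0.5), cw = stats::runif(n, -0.5, 0.5))
  })

  lower <- c(o = 0, a = 1e-12, b = -Inf, cw = 1e-12)
  dat <- data.frame(x = x, y = y)
  best <- NULL
  trace <- numeric(0)
  for (k in seq_len(max(1L, n_starts))) {
    st <- start1
    if (k > 1L) {
      st["b"] <- start1["b"] * (1 + perturb$b[k - 1L])
      st["cw"] <- max(start1["cw"] * (1 + perturb$cw[k - 1L]), 1e-6)
    }
    st <- pmax(st, lower + c(0, 0, -Inf, 0))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ o + a * exp(-exp(-(x - b) / cw) - (x - b) / cw + 1),
        data = dat, start = as.list(st), lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) { trace <- c(trace, NA_real_); next }
    sse <- sum(stats::resid(fit)^2)
    trace <- c(trace, sse)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse, converged = isTRUE(fit$convInfo$isConv))
  }
  if (is.null(best))
    return(structure(list(params = NULL, sse = Inf, converged = FALSE,
                          n_points = length(x), fitted = NULL,
                          residuals = NULL, starts = trace,
                          descriptor = hist$descriptor),
                     class = "desirability_fit"))

  cf <- stats::coef(best$fit)
  params <- scale_desirability(desirability_params(
    o = cf[["o"]], a = cf[["a"]], b = cf[["b"]], c = cf[["cw"]],
    descriptor = if (!is.null(hist$descriptor)) hist$descriptor
                 else NA_character_))
  structure(
    list(params = params, sse = best$sse, converged = best$converged,
         n_points = length(x), fitted = stats::fitted(best$fit),
         residuals = y - stats::fitted(best$fit), starts = trace,
         descriptor = params$descriptor, x = x, y = y),
    class = "desirability_fit"
  )
}

#' @export
coef.desirability_fit <- function(object, ...) {
  p <- object$params
  if (is.null(p)) return(c(o = NA_real_, a = NA_real_, b = NA_real_,
                           c = NA_real_, max_value = NA_real_))
  c(o = p$o, a = p$a, b = p$b, c = p$c, max_value = p$max_value)
}

#' @export
print.desirability_fit <- function(x, ...) {
  cat("Desirability peak fit",
      if (!is.na(x$descriptor)) paste0("(", x$descriptor, ")"), "\n")
  cat(sprintf("  %d bins, SSE = %.6g, converged: %s\n",
              x$n_points, x$sse, x$converged))
  if (!is.null(x$params)) {
    cf <- coef(x)
    cat(sprintf("  o=%.5g a=%.5g b=%.5g c=%.5g (max=%.5g)\n",
                cf["o"], cf["a"], cf["b"], cf["c"], cf["max_value"]))
  }
  invisible(x)
}

#' @export
predict.desirability_fit <- function(object, newdata = NULL,
                                     type = c("desirability", "response"),
                                     ...) {
  type <- match.arg(type)
  if (is.null(object$params)) stop("fit did not produce parameters")
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  if (type == "response") eval_f(x, object$params)
  else eval_df(x, object$params)
}

#' @export
residuals.desirability_fit <- function(object, ...) object$residuals

#' @export
#' @method plot desirability_fit
plot.desirability_fit <- function(x, ...) {
  if (is.null(x$params)) stop("nothing to plot: fit failed")
  graphics::plot(x$x, x$y, pch = 16, xlab = x$descriptor %||% "x",
                 ylab = "count", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, eval_f(xs, x$params), col = "red", lwd = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
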