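#' Likeness scores: geometric mean of descriptor desirabilities
#'
#' The class score QEX (X = H, I, F) is the unweighted geometric mean of
#' the six per-descriptor desirabilities,
#' \deqn{QEX = \exp\left(\frac{1}{n}\sum_{i=1}^{n}\ln df_i\right), n = 6,}
#' with the Derringer-Suich zero rule: if any \eqn{df_i \le 0} the score
#' is exactly 0 — one unacceptable property makes the molecule
#' unacceptable.
#'
#' @name scoring
NULL

#' Combine desirabilities into a likeness score
#'
#' The unweighted geometric mean with the zero rule: 0 exactly when any
#' component is `<= 0`. This is the combiner behind every class score.
#'
#' @param dfs Numeric vector of desirabilities in `[0, 1]`, or a matrix
#'   (one molecule per row).
#' @return A single score, or one per matrix row.
#' @examples
#' qe_combine(c(1, 1, 1, 1, 1, 0.25))  # 0.25^(1/6)
#' qe_combine(c(1, 1, 0, 1, 1, 1))     # 0
#' @export
qe_combine <- function(dfs) {
  if (is.matrix(dfs)) return(geometric_mean_rows(dfs))
  geometric_mean_rows(matrix(dfs, nrow = 1L))[1L]
}

# rows of a [0,1] desirability matrix -> geometric mean with zero rule
geometric_mean_rows <- function(dfm) {
  out <- numeric(nrow(dfm))
  zero <- apply(dfm <= 0, 1L, any)
  ok <- !zero
  if (any(ok)) out[ok] <- exp(rowMeans(log(dfm[ok, , drop = FALSE])))
  out
}

#' Score one descriptor vector against a class profile
#'
#' @param dv A one-row descriptor data frame or named numeric vector with
#'   `MW, LogP, HBA, HBD, RB, arR`.
#' @param profile A `"pesticide_profile"`.
#' @return A single score in `[0, 1]`.
#' @examples
#' \dontrun{qe_score(c(MW = 330, LogP = 3, HBA = 3, HBD = 1, RB = 5,
#'                     arR = 1), profile)}
#' @export
qe_score <- function(dv, profile) {
  if (is.numeric(dv)) dv <- as.data.frame(as.list(dv))
  as.numeric(predict(profile, dv, type = "score"))
}

#' Score a batch of molecules against the three class profiles
#'
#' Computes QEH, QEI and QEF per molecule and fuses them into
#' `QEPmax = max(QEH, QEI, QEF)` and `QEPavg = (QEH + QEI + QEF) / 3`.
#' Input order is preserved.
#'
#' @param descriptors Descriptor data frame (an `id` column is carried
#'   through; otherwise ids `mol1..molN` are assigned).
#' @param profiles Named list with exactly the classes `H`, `I` and `F`
#'   (e.g. from [read_profiles()] or [default_profiles()]).
#' @return Data frame of class `"score_set"`: `id, QEH, QEI, QEF, QEPmax,
#'   QEPavg`, all in `[0, 1]`.
#' @export
score_batch <- function(descriptors, profiles) {
  missing_cl <- setdiff(c("H", "I", "F"), names(profiles))
  if (length(missing_cl))
    stop("missing class profile(s): ", paste(missing_cl, collapse = ", "))
  descriptors <- as.data.frame(descriptors)
  id <- if ("id" %in% names(descriptors)) as.character(descriptors$id)
        else paste0("mol", seq_len(nrow(descriptors)))
  qeh <- predict(profiles[["H"]], descriptors, type = "score")
  qei <- predict(profiles[["I"]], descriptors, type = "score")
  qef <- predict(profiles[["F"]], descriptors, type = "score")
  out <- data.frame(id = id, QEH = qeh, QEI = qei, QEF = qef,
                    QEPmax = pmax(qeh, qei, qef),
                    QEPavg = (qeh + qei + qef) / 3)
  class(out) <- c("score_set", "data.frame")
  out
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("Likeness scores for %d molecules\n", nrow(x)))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 4)
  print(utils::head(y, 10))
  if (nrow(y) > 10) cat("  ...\n")
  invisible(x)
}
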