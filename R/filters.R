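#' Rule-based likeness filters
#'
#' The four classical descriptor-range filters used as comparators for the
#' quantitative scores:
#' \describe{
#'   \item{Lipinski (drugs)}{MW <= 500, logP <= 5, HBD <= 5, HBA <= 10}
#'   \item{Tice herbicides}{150 <= MW <= 500, logP <= 3.5, HBD <= 3,
#'     2 <= HBA <= 12, RB < 12}
#'   \item{Tice insecticides}{150 <= MW <= 500, 0 <= logP <= 5, HBD <= 2,
#'     1 <= HBA <= 8, RB < 12}
#'   \item{Hao (pesticides)}{MW <= 435, logP <= 6, HBD <= 2, HBA <= 6,
#'     RB <= 9, aromatic bonds <= 17}
#' }
#' Range and `<=` bounds are inclusive; the Tice rotatable-bond bound is
#' strict (`< 12`). A molecule passes a rule iff it has zero violations.
#' All filters read the single `LogP` column of the input; supply vendor
#' logP values in that column (or via `logp_column` in
#' [descriptor_table()]) to reproduce a specific estimator.
#'
#' @param dv Descriptor data frame (one or more rows) or named numeric
#'   vector. Required columns per rule: Lipinski `MW, LogP, HBD, HBA`;
#'   Tice additionally `RB`; Hao additionally `arB`.
#' @return A data frame of class `"filter_result"` with columns `id`
#'   (when available), `rule`, `violations`, `passed`, and the list-column
#'   `violated_criteria`.
#' @examples
#' filter_lipinski(c(MW = 500, LogP = 5, HBD = 5, HBA = 10))  # passes
#' @name filters
NULL

filter_rules <- list(
  lipinski = list(
    MW = function(x) x <= 500, logP = function(x) x <= 5,
    HBD = function(x) x <= 5, HBA = function(x) x <= 10),
  tice_herbicide = list(
    MW = function(x) x >= 150 & x <= 500, logP = function(x) x <= 3.5,
    HBD = function(x) x <= 3, HBA = function(x) x >= 2 & x <= 12,
    RB = function(x) x < 12),
  tice_insecticide = list(
    MW = function(x) x >= 150 & x <= 500,
    logP = function(x) x >= 0 & x <= 5,
    HBD = function(x) x <= 2, HBA = function(x) x >= 1 & x <= 8,
    RB = function(x) x < 12),
  hao = list(
    MW = function(x) x <= 435, logP = function(x) x <= 6,
    HBD = function(x) x <= 2, HBA = function(x) x <= 6,
    RB = function(x) x <= 9, `aromatic bonds` = function(x) x <= 17)
)

# criterion name -> descriptor column
filter_column <- c(MW = "MW", logP = "LogP", HBD = "HBD", HBA = "HBA",
                   RB = "RB", `aromatic bonds` = "arB")

apply_rule <- function(dv, rule_name) {
  rule <- filter_rules[[rule_name]]
  if (is.numeric(dv)) dv <- as.data.frame(as.list(dv))
  dv <- as.data.frame(dv)
  if ("arb" %in% names(dv) && !"arB" %in% names(dv)) dv$arB <- dv$arb
  needed <- unname(filter_column[names(rule)])
  missing_cols <- setdiff(needed, names(dv))
  if (length(missing_cols)) {
    if (rule_name == "hao" && "arB" %in% missing_cols)
      stop("the Hao filter needs aromatic-bond counts (column 'arB')")
    stop("filter '", rule_name, "' is missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pass <- vapply(names(rule), function(cr)
    rule[[cr]](as.numeric(dv[[filter_column[[cr]]]])),
    logical(nrow(dv)))
  if (nrow(dv) == 1L) pass <- matrix(pass, nrow = 1L,
                                     dimnames = list(NULL, names(rule)))
  if (anyNA(pass)) stop("missing descriptor values in filter input")
  violated <- apply(pass, 1L, function(p) names(rule)[!p],
                    simplify = FALSE)
  out <- data.frame(rule = rule_name,
                    violations = vapply(violated, length, integer(1)))
  if ("id" %in% names(dv)) out <- cbind(id = as.character(dv$id), out)
  out$passed <- out$violations == 0L
  out$violated_criteria <- I(violated)
  class(out) <- c("filter_result", "data.frame")
  out
}

#' @rdname filters
#' @export
filter_lipinski <- function(dv) apply_rule(dv, "lipinski")

#' @rdname filters
#' @export
filter_tice_herbicide <- function(dv) apply_rule(dv, "tice_herbicide")

#' @rdname filters
#' @export
filter_tice_insecticide <- function(dv) apply_rule(dv, "tice_insecticide")

#' @rdname filters
#' @export
filter_hao <- function(dv) apply_rule(dv, "hao")

#' Apply several rule filters at once
#'
#' @param dv Descriptor data frame.
#' @param rules Subset of `c("lipinski", "tice_herbicide",
#'   "tice_insecticide", "hao")`.
#' @return Wide data frame: per rule, `<rule>_violations` and
#'   `<rule>_pass` columns; attribute `"pass_pct"` holds the percentage of
#'   molecules passing each rule with zero violations.
#' @export
apply_filters <- function(dv, rules = names(filter_rules)) {
  rules <- match.arg(rules, names(filter_rules), several.ok = TRUE)
  dv <- as.data.frame(dv)
  out <- if ("id" %in% names(dv)) dv["id"]
         else data.frame(row = seq_len(nrow(dv)))
  for (r in rules) {
    res <- apply_rule(dv, r)
    out[[paste0(r, "_violations")]] <- res$violations
    out[[paste0(r, "_pass")]] <- res$passed
  }
  attr(out, "pass_pct") <- vapply(rules, function(r)
    100 * mean(out[[paste0(r, "_pass")]]), numeric(1))
  out
}

#' @export
print.filter_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$violated_criteria <- vapply(x$violated_criteria, function(v)
    if (length(v)) paste(v, collapse = ";") else "-", character(1))
  print(utils::head(y, 20))
  if (nrow(y) > 20) cat("  ...\n")
  invisible(x)
}
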