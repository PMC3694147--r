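## Molecular formulas restricted to the elements relevant for volatile
## organosulfur work: C, H, S always; O, N optionally.

.PIDK_ELEMENTS <- c("C", "H", "S", "O", "N")

## Integer mass of the most abundant isotope, used for nominal m/z.
.NOMINAL_MASS <- c(C = 12L, H = 1L, S = 32L, O = 16L, N = 14L)

## CODATA electron mass in u; subtracted once for a +1 cation.
.ELECTRON_MASS <- 0.000548579909

#' Molecular formula of an ion or neutral
#'
#' Element counts over C, H, S (and optionally O, N) plus an integer charge
#' (0 for a neutral, +1 for a cation).  All counts must be non-negative and
#' at least one must be positive.
#'
#' @slot counts named integer vector of element counts.
#' @slot charge integer scalar, 0 or 1.
#' @export
setClass("Formula",
  representation(counts = "integer", charge = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(names(object@counts) %in% .PIDK_ELEMENTS))
      msg <- c(msg, sprintf("unsupported element(s): %s",
        paste(setdiff(names(object@counts), .PIDK_ELEMENTS), collapse = ", ")))
    if (any(object@counts < 0))
      msg <- c(msg, "element counts must be non-negative")
    if (sum(object@counts) < 1L)
      msg <- c(msg, "formula must contain at least one atom")
    if (length(object@charge) != 1L || !object@charge %in% c(0L, 1L))
      msg <- c(msg, "charge must be 0 or +1")
    if (length(msg)) msg else TRUE
  })

#' Construct a molecular formula
#'
#' @param x either a formula string such as \code{"C2H7S"} (element symbols
#'   followed by optional counts), or a named numeric vector of counts.
#' @param charge integer charge, 0 (neutral) or 1 (cation).
#' @return a \code{\linkS4class{Formula}}.
#' @examples
#' chemFormula("C2H7S", charge = 1)
#' chemFormula(c(C = 1), charge = 0)
#' @export
chemFormula <- function(x, charge = 0L) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!nzchar(x)) stop("empty formula string", call. = FALSE)
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (!length(toks) || paste(toks, collapse = "") != x)
      stop("cannot parse formula string: ", x, call. = FALSE)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    bad <- setdiff(el, .PIDK_ELEMENTS)
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "),
        call. = FALSE)
    counts <- tapply(n, factor(el, levels = .PIDK_ELEMENTS), sum)
    counts[is.na(counts)] <- 0L
    counts <- setNames(as.integer(counts), .PIDK_ELEMENTS)
  } else {
    if (is.null(names(x))) stop("counts must be named", call. = FALSE)
    bad <- setdiff(names(x), .PIDK_ELEMENTS)
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "),
        call. = FALSE)
    counts <- setNames(integer(length(.PIDK_ELEMENTS)), .PIDK_ELEMENTS)
    counts[names(x)] <- as.integer(x)
  }
  counts <- counts[counts > 0L | names(counts) %in% c("C", "H", "S")]
  new("Formula", counts = counts, charge = as.integer(charge))
}

#' @describeIn chemFormula element counts of a formula.
#' @param object a \code{Formula}.
#' @export
elementCounts <- function(object) {
  stopifnot(is(object, "Formula"))
  object@counts
}

#' @describeIn chemFormula charge of a formula.
#' @export
formulaCharge <- function(object) {
  stopifnot(is(object, "Formula"))
  object@charge
}

#' Nominal (integer) mass of a formula
#'
#' Sum of element counts times the integer mass of each element's most
#' abundant isotope (C = 12, H = 1, S = 32, O = 16, N = 14).
#'
#' @param formula a \code{\linkS4class{Formula}}.
#' @return integer mass in u.
#' @export
nominalMass <- function(formula) {
  stopifnot(is(formula, "Formula"))
  sum(.NOMINAL_MASS[names(formula@counts)] * formula@counts)
}

## Rings-plus-double-bonds equivalent for an even-electron cation; divalent
## S and O contribute nothing, trivalent N adds 1/2 per atom.
.rdbe <- function(counts) {
  n <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  n("C") + n("N") / 2 - n("H") / 2 + 1
}

#' @export
setMethod("show", "Formula", function(object) {
  cc <- object@counts[object@counts > 0L]
  str <- paste0(names(cc), ifelse(cc > 1L, cc, ""), collapse = "")
  cat(sprintf("Formula: %s%s  (nominal mass %d)\n", str,
    if (object@charge == 1L) "+" else "", nominalMass(object)))
})
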