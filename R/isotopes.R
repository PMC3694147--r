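## Isotopologue pattern computation by per-element multinomial convolution,
## binned at integer nominal-mass shifts.

## IUPAC representative isotopic compositions; masses in u, abundances as
## fractions.  Override with readAbundanceTable().
.DEFAULT_ABUNDANCES <- data.frame(
  element = c("H", "H", "C", "C", "N", "N", "O", "O", "O",
    "S", "S", "S", "S"),
  isotope = c(1L, 2L, 12L, 13L, 14L, 15L, 16L, 17L, 18L,
    32L, 33L, 34L, 36L),
  mass = c(1.0078250319, 2.0141017779, 12.0, 13.0033548351,
    14.0030740052, 15.0001088984, 15.9949146221, 16.9991315,
    17.9991604, 31.97207069, 32.9714585, 33.96786683, 35.96708088),
  abundance = c(0.999885, 0.000115, 0.9893, 0.0107, 0.99636, 0.00364,
    0.99757, 0.00038, 0.00205, 0.9499, 0.0075, 0.0425, 0.0001),
  stringsAsFactors = FALSE)

#' Read an isotope abundance table
#'
#' CSV with columns \code{element}, \code{isotope} (mass number),
#' \code{mass} (exact mass in u), \code{abundance} (fraction).  Abundances
#' are renormalized per element.
#'
#' @param path path to the CSV file.
#' @return a data frame usable as the \code{abundances} argument of
#'   \code{\link{isotopePattern}}.
#' @export
readAbundanceTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "isotope", "mass", "abundance")
  if (!all(need %in% names(tab)))
    stop("abundance table needs columns: ", paste(need, collapse = ", "),
      call. = FALSE)
  tab$isotope <- as.integer(tab$isotope)
  for (el in unique(tab$element)) {
    i <- tab$element == el
    tab$abundance[i] <- tab$abundance[i] / sum(tab$abundance[i])
  }
  tab
}

#' Isotopologue pattern of a formula
#'
#' Relative intensities at integer mass shifts above the monoisotopic peak,
#' normalized so the all-light (shift 0) peak is exactly 100.
#'
#' @slot shifts integer mass shifts (0, 1, 2, ...).
#' @slot intensity intensities in percent of the base peak.
#' @slot monoMass monoisotopic mass in u (electron mass subtracted for a
#'   +1 cation).
#' @slot formula the \code{\linkS4class{Formula}} the pattern belongs to.
#' @export
setClass("IsotopePattern",
  representation(shifts = "integer", intensity = "numeric",
    monoMass = "numeric", formula = "Formula"),
  validity = function(object) {
    msg <- character()
    if (length(object@shifts) != length(object@intensity))
      msg <- c(msg, "shifts and intensity differ in length")
    if (!length(object@shifts) || object@shifts[1] != 0L)
      msg <- c(msg, "pattern must start at shift 0")
    if (length(object@intensity) &&
        abs(object@intensity[1] - 100) > 1e-9)
      msg <- c(msg, "base peak (shift 0) must be 100")
    if (any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

## Shift distribution of n atoms of one element: repeated self-convolution
## of the single-atom distribution over integer shifts.
.elementShiftDist <- function(n, shifts, probs) {
  dist <- 1.0   # probability mass by shift, index 1 = shift 0
  single <- numeric(max(shifts) + 1L)
  single[shifts + 1L] <- probs
  if (n == 0L) return(dist)
  for (i in seq_len(n)) {
    m <- length(dist) + length(single) - 1L
    out <- numeric(m)
    for (s in seq_along(single)) {
      if (single[s] > 0)
        out[seq_along(dist) + s - 1L] <-
          out[seq_along(dist) + s - 1L] + dist * single[s]
    }
    dist <- out
  }
  dist
}

#' Compute the isotopologue pattern of a molecular formula
#'
#' Convolves per-element isotope distributions (binomial/multinomial over
#' the atoms of each element), bins isotopologues by integer mass shift and
#' renormalizes to base peak = 100.  The monoisotopic mass is the exact mass
#' of the all-light isotopologue; for \code{charge = 1} the electron mass is
#' subtracted.
#'
#' @param formula a \code{\linkS4class{Formula}} (see
#'   \code{\link{chemFormula}}).
#' @param abundances isotope table as returned by
#'   \code{\link{readAbundanceTable}}; default IUPAC representative values.
#' @param minIntensity truncate the pattern after the last shift whose
#'   intensity reaches this percentage (default 0.01).
#' @return an \code{\linkS4class{IsotopePattern}}.
#' @examples
#' isotopePattern(chemFormula("C2H7S", charge = 1))
#' @export
isotopePattern <- function(formula, abundances = NULL, minIntensity = 0.01) {
  stopifnot(is(formula, "Formula"))
  if (is.null(abundances)) abundances <- .DEFAULT_ABUNDANCES
  counts <- formula@counts[formula@counts > 0L]
  if (!length(counts)) stop("empty formula", call. = FALSE)
  bad <- setdiff(names(counts), unique(abundances$element))
  if (length(bad))
    stop("element(s) missing from abundance table: ",
      paste(bad, collapse = ", "), call. = FALSE)

  dist <- 1.0
  mono <- 0.0
  for (el in names(counts)) {
    sub <- abundances[abundances$element == el, , drop = FALSE]
    sub <- sub[order(sub$isotope), , drop = FALSE]
    base <- sub$isotope[which.max(sub$abundance)]
    shifts <- sub$isotope - base
    if (any(shifts < 0))
      stop("most abundant isotope of ", el, " is not the lightest; ",
        "unsupported table", call. = FALSE)
    edist <- .elementShiftDist(counts[[el]], shifts, sub$abundance)
    m <- length(dist) + length(edist) - 1L
    out <- numeric(m)
    for (s in seq_along(edist)) {
      if (edist[s] > 0)
        out[seq_along(dist) + s - 1L] <-
          out[seq_along(dist) + s - 1L] + dist * edist[s]
    }
    dist <- out
    mono <- mono + counts[[el]] * sub$mass[sub$isotope == base]
  }
  if (formula@charge == 1L) mono <- mono - .ELECTRON_MASS

  rel <- 100 * dist / dist[1L]
  keep <- max(c(1L, which(rel >= minIntensity)))
  rel <- rel[seq_len(keep)]
  new("IsotopePattern", shifts = seq_along(rel) - 1L, intensity = rel,
    monoMass = mono, formula = formula)
}

#' @describeIn isotopePattern intensities (named by shift) of a pattern.
#' @param object an \code{IsotopePattern}.
#' @export
patternIntensity <- function(object) {
  stopifnot(is(object, "IsotopePattern"))
  setNames(object@intensity, object@shifts)
}

#' @describeIn isotopePattern monoisotopic mass of a pattern.
#' @export
monoisotopicMass <- function(object) {
  stopifnot(is(object, "IsotopePattern"))
  object@monoMass
}

#' @describeIn isotopePattern pattern as fractions summing to one
#'   (the split of one ion population across isotopologue m/z).
#' @export
patternFractions <- function(object) {
  stopifnot(is(object, "IsotopePattern"))
  setNames(object@intensity / sum(object@intensity), object@shifts)
}

#' @export
setMethod("show", "IsotopePattern", function(object) {
  show(object@formula)
  cat(sprintf("monoisotopic mass: %.4f u\n", object@monoMass))
  for (i in seq_along(object@shifts))
    cat(sprintf("  M+%d\t%8.2f\n", object@shifts[i], object@intensity[i]))
})

#' Element count bounds for the composition search
#'
#' @param C,H,S,O,N length-2 integer vectors \code{c(min, max)}.  Defaults
#'   follow the usual volatile-organosulfur search space: C 0--10, H 0--30,
#'   S 0--5, no O or N.
#' @return a named list of bounds.
#' @export
compositionBounds <- function(C = c(0L, 10L), H = c(0L, 30L), S = c(0L, 5L),
                              O = c(0L, 0L), N = c(0L, 0L)) {
  b <- list(C = as.integer(C), H = as.integer(H), S = as.integer(S),
    O = as.integer(O), N = as.integer(N))
  for (el in names(b)) {
    if (length(b[[el]]) != 2L || any(is.na(b[[el]])))
      stop("bounds for ", el, " must be c(min, max)", call. = FALSE)
    if (b[[el]][1] > b[[el]][2] || b[[el]][2] < 0L)
      stop("invalid bounds for ", el, call. = FALSE)
  }
  b
}

#' Elemental compositions matching a nominal mass
#'
#' Enumerates every formula inside the bounds whose nominal mass equals the
#' target.  With \code{valenceFilter = TRUE}, retains only formulas whose
#' rings-plus-double-bonds equivalent for an even-electron cation
#' (RDBE = C + N/2 - H/2 + 1; divalent S and O contribute 0) is
#' non-negative.
#'
#' @param mass target nominal mass (integer, >= 1).
#' @param bounds element bounds from \code{\link{compositionBounds}}.
#' @param valenceFilter apply the RDBE >= 0 filter (default FALSE).
#' @param charge charge assigned to the returned formulas (default 1).
#' @return list of \code{\linkS4class{Formula}}, ordered lexicographically
#'   by C, H, S (then O, N) counts.
#' @examples
#' candidateFormulas(47)
#' @export
candidateFormulas <- function(mass, bounds = compositionBounds(),
                              valenceFilter = FALSE, charge = 1L) {
  mass <- as.integer(mass)
  if (is.na(mass) || mass < 1L)
    stop("nominal mass must be an integer >= 1", call. = FALSE)
  grid <- expand.grid(
    N = seq(bounds$N[1], bounds$N[2]),
    O = seq(bounds$O[1], bounds$O[2]),
    S = seq(bounds$S[1], bounds$S[2]),
    H = seq(bounds$H[1], bounds$H[2]),
    C = seq(bounds$C[1], bounds$C[2]))
  m <- with(grid, 12L * C + H + 32L * S + 16L * O + 14L * N)
  grid <- grid[m == mass & rowSums(grid) > 0L, , drop = FALSE]
  if (valenceFilter) {
    rdbe <- with(grid, C + N / 2 - H / 2 + 1)
    grid <- grid[rdbe >= 0, , drop = FALSE]
  }
  grid <- grid[order(grid$C, grid$H, grid$S, grid$O, grid$N), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    chemFormula(c(C = grid$C[i], H = grid$H[i], S = grid$S[i],
      O = grid$O[i], N = grid$N[i]), charge = charge))
}
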