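## CSV I/O, transmission correction and normalization for TraceSets.
##
## CSV dialect: header mandatory; first column `cycle`, optional
## `e_over_n_td`, then one column per monitored m/z named `mz<integer>`;
## UTF-8, '.' decimal.  Values are written with 17 significant digits so a
## write/read round trip is bit-exact.

#' Read a TraceSet from CSV
#'
#' @param path path to a trace CSV in the documented dialect.
#' @return a \code{\linkS4class{TraceSet}} with provenance \code{"file"}.
#' @export
readTraceSet <- function(path) {
  nf <- count.fields(path, sep = ",")
  if (length(unique(nf)) != 1L)
    stop("ragged CSV: row(s) ",
      paste(which(nf != nf[1]), collapse = ", "),
      " have a different field count", call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cycle")
    stop("first column must be 'cycle'", call. = FALSE)
  mzcols <- grep("^mz[0-9]+$", names(df), value = TRUE)
  if (!length(mzcols)) stop("no mz<integer> columns found", call. = FALSE)
  if (anyDuplicated(mzcols))
    stop("duplicate m/z column(s): ",
      paste(unique(mzcols[duplicated(mzcols)]), collapse = ", "),
      call. = FALSE)
  extra <- setdiff(names(df), c("cycle", "e_over_n_td", mzcols))
  if (length(extra))
    stop("unrecognized column(s): ", paste(extra, collapse = ", "),
      call. = FALSE)
  for (cc in mzcols) {
    bad <- which(is.na(df[[cc]]) | df[[cc]] < 0)
    if (length(bad))
      stop("negative or missing cps in column ", cc, ", row ", bad[1],
        call. = FALSE)
  }
  cps <- t(as.matrix(df[, mzcols, drop = FALSE]))
  TraceSet(cps, monitoredMz = as.integer(sub("^mz", "", mzcols)),
    cycles = df$cycle,
    eOverN = if ("e_over_n_td" %in% names(df)) df$e_over_n_td else NULL,
    provenance = "file")
}

#' Write a TraceSet to CSV
#'
#' @param x a \code{\linkS4class{TraceSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTraceSet <- function(x, path) {
  stopifnot(is(x, "TraceSet"))
  fmt <- function(v) sprintf("%.17g", v)
  cps <- cpsMatrix(x)
  cols <- list(cycle = as.character(cycleIndex(x)))
  en <- eOverNPerCycle(x)
  if (!is.null(en)) cols$e_over_n_td <- fmt(en)
  for (i in seq_len(nrow(cps)))
    cols[[paste0("mz", monitoredMz(x)[i])]] <- fmt(cps[i, ])
  out <- do.call(cbind, cols)
  write.csv(as.data.frame(out, stringsAsFactors = FALSE), path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

.transmissionFun <- function(curve) {
  if (is.function(curve)) return(curve)
  if (is.data.frame(curve)) {
    if (!all(c("mz", "coefficient") %in% names(curve)))
      stop("transmission curve needs columns mz, coefficient", call. = FALSE)
    if (any(curve$coefficient <= 0 | curve$coefficient > 1))
      stop("transmission coefficients must lie in (0, 1]", call. = FALSE)
    return(function(mz) approx(curve$mz, curve$coefficient, xout = mz,
      rule = 2)$y)
  }
  stop("curve must be a data frame or a function of m/z", call. = FALSE)
}

#' Read a transmission curve CSV (`mz,coefficient`)
#'
#' @param path path to the CSV.
#' @return data frame with columns \code{mz}, \code{coefficient}.
#' @export
readTransmissionCurve <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .transmissionFun(df)  # validates
  df
}

#' Correct a TraceSet for instrumental transmission
#'
#' Each channel is divided by the (linearly interpolated) transmission
#' coefficient at its monitored m/z.  Correcting an already corrected set
#' is an error.
#'
#' @param x a \code{\linkS4class{TraceSet}}.
#' @param curve data frame (\code{mz}, \code{coefficient}) or a function
#'   of m/z returning coefficients in (0, 1].
#' @return the corrected \code{TraceSet}.
#' @export
transmissionCorrect <- function(x, curve) {
  stopifnot(is(x, "TraceSet"))
  if (isTRUE(metadata(x)$transmission_corrected))
    stop("TraceSet is already transmission-corrected", call. = FALSE)
  f <- .transmissionFun(curve)
  co <- f(monitoredMz(x))
  if (any(co <= 0 | co > 1))
    stop("transmission coefficients must lie in (0, 1]", call. = FALSE)
  assay(x, "cps") <- cpsMatrix(x) / co
  metadata(x)$transmission_corrected <- TRUE
  x
}

#' Per-cycle percentage of a parent trace
#'
#' Computes \code{100 * trace / parent} cycle by cycle, then averages the
#' percentages (cycle-wise averaging, not the ratio of averages).  Cycles
#' where the parent is zero are excluded with a warning.
#'
#' @param trace numeric vector (cps).
#' @param parent numeric vector (cps), same length.
#' @param window optional integer indices restricting the cycles used.
#' @return list with \code{percent} (per used cycle), \code{cycles}
#'   (indices used), \code{mean} and \code{sd}.
#' @export
percentOfParent <- function(trace, parent, window = NULL) {
  stopifnot(length(trace) == length(parent))
  idx <- if (is.null(window)) seq_along(trace) else as.integer(window)
  ok <- parent[idx] > 0
  if (!any(ok))
    stop("parent trace is zero on the whole window", call. = FALSE)
  if (!all(ok)) {
    warning(sum(!ok), " cycle(s) with zero parent excluded")
    idx <- idx[ok]
  }
  pct <- 100 * trace[idx] / parent[idx]
  list(percent = pct, cycles = idx, mean = mean(pct),
    sd = if (length(pct) > 1L) sd(pct) else 0)
}

#' Estimate the primary-ion trace from its monitored isotopologue
#'
#' Hydronium at m/z 19 saturates the detector and is monitored via its
#' heavy-oxygen isotopologue at m/z 21; this rescales the m/z 21 trace by
#' the inverse isotopologue abundance.  For reporting only -- analyses
#' operate on the m/z 21 trace directly.
#'
#' @param traceM21 numeric vector, the m/z 21 trace (cps).
#' @param scale multiplicative factor; the default is the inverse
#'   heavy-oxygen abundance ratio of hydronium
#'   (\eqn{\approx 487}).
#' @return numeric vector, estimated m/z 19 trace.
#' @export
primaryFromIsotopologue <- function(traceM21, scale = NULL) {
  if (is.null(scale)) {
    p <- patternFractions(isotopePattern(chemFormula("H3O", charge = 1)))
    scale <- unname(p["0"] / p["2"])
  }
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  traceM21 * scale
}
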