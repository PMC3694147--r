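## The PIDK analysis pipeline: phase segmentation of the primary-ion trace,
## three-way fragment classification, isotopologue-deviation analysis,
## composite-signal decomposition and reaction-order estimation.

#' Phase segmentation of a PIDK run
#'
#' Half-open, 0-based cycle intervals: depletion (primary ion below
#' \code{fDep} of its plateau), replenishment, and normal (primary ion
#' above \code{fNorm} of its plateau).
#'
#' @slot depletion,replenishment,normal integer \code{c(from, to)}
#'   half-open intervals.
#' @slot fDep,fNorm threshold fractions used.
#' @slot plateau plateau median of the primary-ion trace.
#' @export
setClass("PhaseSegmentation",
  representation(depletion = "integer", replenishment = "integer",
    normal = "integer", fDep = "numeric", fNorm = "numeric",
    plateau = "numeric"),
  validity = function(object) {
    iv <- rbind(object@depletion, object@replenishment, object@normal)
    if (ncol(iv) != 2L || any(iv[, 1] > iv[, 2]))
      return("intervals must be c(from, to) with from <= to")
    if (object@depletion[2] != object@replenishment[1] ||
        object@replenishment[2] != object@normal[1])
      return("intervals must be contiguous and ordered")
    TRUE
  })

#' @describeIn segmentPhases 1-based R indices of a segmentation interval
#'   (\code{phase} one of \code{"depletion"}, \code{"replenishment"},
#'   \code{"normal"}).
#' @param seg a \code{PhaseSegmentation}.
#' @param phase phase name.
#' @export
phaseCycles <- function(seg, phase) {
  stopifnot(is(seg, "PhaseSegmentation"))
  iv <- slot(seg, phase)
  if (iv[1] == iv[2]) return(integer())
  seq.int(iv[1] + 1L, iv[2])
}

#' @export
setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf(
    "PhaseSegmentation: depletion [%d,%d), replenishment [%d,%d), normal [%d,%d)\n",
    object@depletion[1], object@depletion[2],
    object@replenishment[1], object@replenishment[2],
    object@normal[1], object@normal[2]))
  cat(sprintf("  plateau %.4g, thresholds f_dep = %.2f, f_norm = %.2f\n",
    object@plateau, object@fDep, object@fNorm))
})

#' Segment a PIDK run into depletion / replenishment / normal phases
#'
#' The plateau level is the median of the last quartile of the primary-ion
#' trace (the run must end non-depleted: last-quartile coefficient of
#' variation below \code{plateauCV}).  Depletion is the maximal prefix
#' below \code{fDep} times the plateau; normal is the maximal suffix above
#' \code{fNorm} times the plateau; replenishment is the remainder.
#'
#' @param primary numeric vector, the primary-ion trace (typically the
#'   m/z 21 channel).
#' @param fDep depletion threshold fraction (default 0.10).
#' @param fNorm normal threshold fraction (default 0.90).
#' @param plateauCV maximal last-quartile CV for a valid plateau
#'   (default 0.20).
#' @param smooth odd running-median window applied to the trace before
#'   thresholding, for counting-noise robustness (default 5; 1 disables).
#' @return a \code{\linkS4class{PhaseSegmentation}}.
#' @export
segmentPhases <- function(primary, fDep = 0.10, fNorm = 0.90,
                          plateauCV = 0.20, smooth = 5L) {
  n <- length(primary)
  if (n < 8L) stop("trace too short to segment", call. = FALSE)
  lastq <- primary[seq.int(floor(3 * n / 4) + 1L, n)]
  if (mean(lastq) <= 0 || sd(lastq) / mean(lastq) >= plateauCV)
    stop("trace does not end in a non-depleted plateau", call. = FALSE)
  plateau <- median(lastq)
  sm <- if (smooth > 1L) runmed(primary, smooth) else primary
  below <- sm < fDep * plateau
  if (!below[1])
    stop("not a PIDK run: no depleted cycles at the start", call. = FALSE)
  dEnd <- if (all(below)) n else which(!below)[1] - 1L
  above <- sm > fNorm * plateau
  nStart <- if (all(above)) 0L else max(which(!above))
  if (nStart < dEnd) nStart <- dEnd
  ## recovery should be essentially monotone between the phases
  if (nStart > dEnd + 4L) {
    rep_sm <- runmed(primary[seq.int(dEnd + 1L, nStart)], 5)
    if (any(diff(rep_sm) < -0.1 * plateau))
      warning("non-monotone primary-ion recovery during replenishment")
  }
  new("PhaseSegmentation",
    depletion = c(0L, as.integer(dEnd)),
    replenishment = c(as.integer(dEnd), as.integer(nStart)),
    normal = c(as.integer(nStart), as.integer(n)),
    fDep = fDep, fNorm = fNorm, plateau = plateau)
}

#' Three-way fragment classification
#'
#' Result of \code{\link{classifyFragment}}: one of
#' \code{"parallel-isotopologue"} (tracks the protonated parent),
#' \code{"depletion-minimum"} (lowest under depletion, points to secondary
#' proton transfer), \code{"replenishment-peak"} (peaks during
#' replenishment, points to higher-order/adduct chemistry), or
#' \code{"unclassified"}.
#'
#' @slot label the class.
#' @slot stats supporting statistics (ratio CV, extremum location,
#'   prominence, phase means).
#' @export
setClass("FragmentClass",
  representation(label = "character", stats = "list"),
  validity = function(object) {
    ok <- c("parallel-isotopologue", "depletion-minimum",
      "replenishment-peak", "unclassified")
    if (!object@label %in% ok) return("unknown class label")
    TRUE
  })

#' @describeIn classifyFragment class label of a result.
#' @param object a \code{FragmentClass}.
#' @export
fragmentLabel <- function(object) {
  stopifnot(is(object, "FragmentClass"))
  object@label
}

#' @export
setMethod("show", "FragmentClass", function(object) {
  cat("FragmentClass:", object@label, "\n")
  s <- object@stats
  cat(sprintf("  ratio CV %.3f; argmax cycle %d; prominence %.3f\n",
    s$ratioCV, s$argmax, s$prominence))
  cat(sprintf("  phase means: depletion %.4g, replenishment %.4g, normal %.4g\n",
    s$phaseMeans[1], s$phaseMeans[2], s$phaseMeans[3]))
})

#' Classify a fragment trace against the protonated parent
#'
#' Decision rule, applied in order: (1) parallel-isotopologue when the
#' per-cycle ratio to the parent has CV below \code{c1} across all phases;
#' else (2) replenishment-peak when the global maximum (after a light
#' running-median smooth for noise robustness) lies inside the
#' replenishment interval and exceeds both phase-boundary values by a
#' relative prominence of at least \code{c2}; else (3) depletion-minimum
#' when the depletion-phase mean is the smallest of the three phase means.
#' Anything else is reported as unclassified with diagnostics rather than
#' force-assigned.
#'
#' @param trace numeric vector (cps) of the fragment channel.
#' @param parent numeric vector (cps) of the protonated parent channel.
#' @param seg a \code{\linkS4class{PhaseSegmentation}} of the same run.
#' @param c1 CV threshold for the parallel rule (default 0.10).
#' @param c2 relative prominence threshold for the peak rule
#'   (default 0.20).
#' @param smooth odd window for the running-median smooth (default 5;
#'   1 disables).
#' @return a \code{\linkS4class{FragmentClass}}.
#' @export
classifyFragment <- function(trace, parent, seg, c1 = 0.10, c2 = 0.20,
                             smooth = 5L) {
  stopifnot(is(seg, "PhaseSegmentation"))
  if (length(trace) != length(parent))
    stop("trace and parent differ in length", call. = FALSE)
  if (all(trace == 0)) stop("all-zero trace", call. = FALSE)
  n <- length(trace)
  if (seg@normal[2] != n)
    stop("segmentation does not cover the trace", call. = FALSE)

  ## noise robustness: all rules operate on lightly median-smoothed
  ## traces; medians commute with positive scaling, so scale invariance
  ## and exact proportionality are preserved
  sm <- if (smooth > 1L) runmed(trace, smooth) else trace
  smp <- if (smooth > 1L) runmed(parent, smooth) else parent
  ok <- smp > 0
  ratio <- sm[ok] / smp[ok]
  ratioCV <- if (mean(ratio) > 0) sd(ratio) / mean(ratio) else Inf
  imax <- which.max(sm)
  rep_iv <- seg@replenishment
  inRep <- (imax - 1L) >= rep_iv[1] && (imax - 1L) < rep_iv[2]
  bLow <- if (rep_iv[1] >= 1L) sm[rep_iv[1]] else sm[1]
  bHigh <- if (rep_iv[2] < n) sm[rep_iv[2] + 1L] else sm[n]
  prom <- sm[imax] / max(bLow, bHigh, .Machine$double.eps) - 1

  pm <- c(
    depletion = mean(trace[phaseCycles(seg, "depletion")]),
    replenishment = if (length(phaseCycles(seg, "replenishment")))
      mean(trace[phaseCycles(seg, "replenishment")]) else NA_real_,
    normal = mean(trace[phaseCycles(seg, "normal")]))

  stats <- list(ratioCV = ratioCV, argmax = imax - 1L, prominence = prom,
    phaseMeans = pm)
  label <-
    if (is.finite(ratioCV) && ratioCV < c1) "parallel-isotopologue"
    else if (inRep && sm[imax] >= (1 + c2) * bLow &&
             sm[imax] >= (1 + c2) * bHigh) "replenishment-peak"
    else if (!anyNA(pm) && pm[1] < pm[2] && pm[1] < pm[3])
      "depletion-minimum"
    else "unclassified"
  new("FragmentClass", label = label, stats = stats)
}

#' Isotopologue-deviation analysis
#'
#' For each trace of an isotopologue family (protonated parent plus its
#' heavy isotopologues), fits \eqn{\log_{10}} trace against
#' \eqn{\log_{10}} of a reference channel.  A well-behaved isotopologue
#' has slope 1 and an offset equal to \eqn{\log_{10}} of its theoretical
#' ratio to the reference.  A deviation is flagged when the mean absolute
#' residual over the top-decile reference cycles exceeds
#' \code{devFactor} times the residual SD of the remaining cycles --
#' the signature of an extra (e.g. concentration-dependent) drain at high
#' concentration.
#'
#' @param ref numeric vector, the reference channel (e.g. the
#'   dehydrogenation product used as x-axis).
#' @param family named list of numeric traces (parent and isotopologues).
#' @param window optional cycle indices (1-based) to analyze.
#' @param topFraction fraction of cycles counted as high-concentration
#'   (default 0.10).
#' @param devFactor deviation threshold factor (default 3).
#' @param minDeviation absolute floor (log10 units) below which a
#'   high-concentration residual is never flagged (default 0.01,
#'   about 2.3\%); deviations smaller than this are chemically
#'   meaningless and would otherwise trigger on noise-free inputs.
#' @return data frame with one row per family trace: \code{slope},
#'   \code{offset}, \code{highResidual}, \code{residualSD},
#'   \code{deviation}, \code{nUsed}.
#' @export
isotopologueDeviation <- function(ref, family, window = NULL,
                                  topFraction = 0.10, devFactor = 3,
                                  minDeviation = 0.01) {
  if (is.null(names(family)) || !length(family))
    stop("family must be a named list of traces", call. = FALSE)
  idx <- if (is.null(window)) seq_along(ref) else as.integer(window)
  res <- lapply(names(family), function(nm) {
    tr <- family[[nm]]
    ok <- idx[ref[idx] > 0 & tr[idx] > 0]
    if (length(ok) < length(idx))
      warning("trace ", nm, ": ", length(idx) - length(ok),
        " nonpositive cycle(s) trimmed")
    if (length(ok) < 10L)
      stop("trace ", nm, ": fewer than 10 usable cycles", call. = FALSE)
    lx <- log10(ref[ok]); ly <- log10(tr[ok])
    fit <- lm(ly ~ lx)
    r <- residuals(fit)
    top <- lx >= quantile(lx, 1 - topFraction)
    highRes <- mean(abs(r[top]))
    restSD <- sd(r[!top])
    data.frame(trace = nm, slope = unname(coef(fit)[2]),
      offset = unname(coef(fit)[1]), highResidual = highRes,
      residualSD = restSD,
      deviation = is.finite(restSD) && highRes > devFactor * restSD &&
        highRes > minDeviation,
      nUsed = length(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-component decomposition of a composite signal
#'
#' A channel fed by two unrelated sources -- a charge-transfer product
#' whose production mirrors the recovery of a parasitic reagent ion
#' (e.g. the molecular ion from O2+), and a constant-fraction satellite of
#' a reference channel (e.g. a dehydrogenation isotopologue) -- is
#' decomposed as
#' \deqn{target(t) = a \cdot \max(0, P - parasitic(t)) + b \cdot ref(t)}
#' where \eqn{P} is the parasitic plateau median (its "inverse" recovery),
#' \eqn{b} is fixed from the tail of the run (median target/ref over
#' \code{tailWindow}, inside the normal phase) and \eqn{a \ge 0} is fit by
#' least squares.
#'
#' @slot a charge-transfer amplitude (>= 0).
#' @slot b constant satellite fraction.
#' @slot components matrix with rows \code{charge_transfer},
#'   \code{satellite}, \code{residual}.
#' @slot residualRMS residual RMS as percent of the target mean.
#' @slot plateau the parasitic plateau level P.
#' @export
setClass("DecompositionResult",
  representation(a = "numeric", b = "numeric", components = "matrix",
    residualRMS = "numeric", plateau = "numeric"),
  validity = function(object) {
    if (object@a < 0) return("amplitude a must be >= 0")
    TRUE
  })

#' @export
setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf(
    "DecompositionResult: a = %.4g, b = %.4g, residual RMS = %.2f%% of target mean\n",
    object@a, object@b, object@residualRMS))
})

#' @describeIn decomposeSignal fitted component traces of a result.
#' @param object a \code{DecompositionResult}.
#' @export
componentTraces <- function(object) {
  stopifnot(is(object, "DecompositionResult"))
  object@components
}

#' Decompose a composite channel into charge-transfer and satellite parts
#'
#' @param target numeric vector, the composite channel (cps).
#' @param parasitic numeric vector, the parasitic reagent-ion channel
#'   (cps); must recover to a plateau over \code{tailWindow}.
#' @param ref numeric vector, the reference channel (cps).
#' @param tailWindow 1-based cycle indices inside the normal phase used to
#'   fix \code{P} and \code{b}.
#' @return a \code{\linkS4class{DecompositionResult}}.
#' @seealso \code{\linkS4class{DecompositionResult}}
#' @export
decomposeSignal <- function(target, parasitic, ref, tailWindow) {
  n <- length(target)
  stopifnot(length(parasitic) == n, length(ref) == n)
  tw <- as.integer(tailWindow)
  if (any(tw < 1L | tw > n)) stop("tailWindow out of range", call. = FALSE)
  tail_par <- parasitic[tw]
  if (mean(tail_par) <= 0 || sd(tail_par) / mean(tail_par) >= 0.2)
    stop("parasitic trace does not recover to a plateau over tailWindow",
      call. = FALSE)
  P <- median(tail_par)
  if (any(ref[tw] <= 0))
    stop("reference trace nonpositive in tailWindow", call. = FALSE)
  b <- median(target[tw] / ref[tw])
  x <- pmax(0, P - parasitic)
  y <- target - b * ref
  a <- if (sum(x^2) > 0) max(0, sum(x * y) / sum(x^2)) else 0
  ct <- a * x
  sat <- b * ref
  resid <- target - ct - sat
  rms <- 100 * sqrt(mean(resid^2)) / mean(target)
  new("DecompositionResult", a = a, b = b,
    components = rbind(charge_transfer = ct, satellite = sat,
      residual = resid),
    residualRMS = rms, plateau = P)
}

#' Estimate the reaction order of a fragment channel
#'
#' In the non-depleted (normal) phase the protonated parent is linear in
#' the analyte concentration, so the slope of \eqn{\log_{10}} fragment
#' against \eqn{\log_{10}} parent estimates the reaction order of the
#' fragment channel with respect to the analyte (2 for an adduct needing
#' two analyte molecules).
#'
#' @param fragment numeric vector (cps).
#' @param parent numeric vector (cps).
#' @param window 1-based cycle indices inside the normal phase
#'   (>= 10 cycles).
#' @return list with \code{order} and \code{stderr}.
#' @export
estimateReactionOrder <- function(fragment, parent, window) {
  w <- as.integer(window)
  if (anyNA(w) || any(w < 1L | w > length(fragment)))
    stop("window contains invalid cycle indices", call. = FALSE)
  if (length(w) < 10L) stop("window too short (< 10 cycles)", call. = FALSE)
  ok <- w[fragment[w] > 0 & parent[w] > 0]
  if (length(ok) < length(w))
    warning(length(w) - length(ok), " nonpositive cycle(s) excluded")
  if (length(ok) < 10L)
    stop("fewer than 10 usable cycles in window", call. = FALSE)
  fit <- lm(log10(fragment[ok]) ~ log10(parent[ok]))
  list(order = unname(coef(fit)[2]),
    stderr = unname(sqrt(diag(vcov(fit)))[2]))
}
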