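## Inert-gas-stripping / reduced-field study support.  When a volatile is
## stripped from solution its gas-phase concentration decays exponentially,
## so every true fragment must share the parent ion's log-linear slope;
## a calibrated z-test on two OLS slopes formalizes "identical slope".

#' Convert drift voltage and gas conditions to a reduced field
#'
#' \eqn{E/N = (U_D/L) / n} with \eqn{n = p/(k_B T)}, expressed in
#' Townsend (1 Td = 1e-17 V cm^2).
#'
#' @param voltage drift voltage U_D, V.
#' @param pressure drift pressure, mbar.
#' @param temperature drift temperature, K.
#' @param length drift length, cm (default 9.2; not printed on instrument
#'   spec sheets for this class, so make it explicit in any report).
#' @return reduced field in Td.
#' @examples
#' enFromVoltage(600, 2.1, 333.15)   # about 140 Td
#' @export
enFromVoltage <- function(voltage, pressure, temperature, length = 9.2) {
  if (any(c(voltage, pressure, temperature, length) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  .enTd(voltage, pressure, temperature, length)
}

#' Log-linear slope fit of a decaying trace
#'
#' @slot slope slope in log10(cps) per cycle.
#' @slot stderr standard error of the slope.
#' @slot intercept intercept (log10 cps at cycle 0).
#' @slot r2 coefficient of determination.
#' @slot window cycle indices used (1-based).
#' @export
setClass("SlopeFit",
  representation(slope = "numeric", stderr = "numeric",
    intercept = "numeric", r2 = "numeric", window = "integer"),
  validity = function(object) {
    if (length(object@window) < 10L)
      return("window must span at least 10 cycles")
    if (object@stderr < 0) return("stderr must be >= 0")
    TRUE
  })

#' @describeIn fitLogSlope the fitted slope.
#' @param object a \code{SlopeFit}.
#' @export
slopeValue <- function(object) {
  stopifnot(is(object, "SlopeFit"))
  object@slope
}

#' @export
setMethod("show", "SlopeFit", function(object) {
  cat(sprintf(
    "SlopeFit: slope %.5f +/- %.5f log10(cps)/cycle, R^2 = %.4f (%d cycles)\n",
    object@slope, object@stderr, object@r2, length(object@window)))
})

#' Fit the log-linear decay slope of a trace
#'
#' Ordinary least squares of \eqn{\log_{10}} cps against cycle; exact on
#' noiseless exponentials.
#'
#' @param trace numeric vector (cps).
#' @param window 1-based cycle indices to fit (>= 10 cycles); default all.
#' @return a \code{\linkS4class{SlopeFit}}.
#' @export
fitLogSlope <- function(trace, window = NULL) {
  w <- if (is.null(window)) seq_along(trace) else as.integer(window)
  if (anyNA(w) || any(w < 1L | w > length(trace)))
    stop("window contains invalid cycle indices", call. = FALSE)
  if (length(w) < 10L) stop("window too short (< 10 cycles)", call. = FALSE)
  ok <- w[trace[w] > 0]
  if (length(ok) < length(w))
    warning(length(w) - length(ok), " nonpositive cycle(s) trimmed")
  if (length(ok) < 10L)
    stop("fewer than 10 usable cycles after trimming", call. = FALSE)
  x <- ok - 1  # cycles are 0-based
  fit <- lm(log10(trace[ok]) ~ x)
  sm <- summary(fit)
  new("SlopeFit", slope = unname(coef(fit)[2]),
    stderr = unname(sm$coefficients[2, 2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared, window = as.integer(ok))
}

#' Slope-equality test for fragment confirmation
#'
#' A true fragment of a stripped volatile must decay with the same
#' log-linear slope as the protonated parent.  Two-sided z-test on the
#' slope difference with pooled standard error; the fragment is confirmed
#' when no slope difference is detectable (\eqn{p \ge \alpha}).  With two
#' degenerate noiseless fits (both stderr 0) an exact equality comparison
#' is used.
#'
#' @param candidate a \code{\linkS4class{SlopeFit}} for the candidate
#'   fragment.
#' @param parent a \code{\linkS4class{SlopeFit}} for the parent ion.
#' @param alpha significance level (default 0.05).
#' @return list with \code{confirmed}, \code{z}, \code{p}.
#' @export
confirmFragment <- function(candidate, parent, alpha = 0.05) {
  stopifnot(is(candidate, "SlopeFit"), is(parent, "SlopeFit"))
  se <- sqrt(candidate@stderr^2 + parent@stderr^2)
  if (se == 0) {
    eq <- candidate@slope == parent@slope
    return(list(confirmed = eq, z = if (eq) 0 else Inf,
      p = if (eq) 1 else 0))
  }
  z <- (candidate@slope - parent@slope) / se
  p <- 2 * pnorm(-abs(z))
  list(confirmed = p >= alpha, z = z, p = p)
}

#' Per-E/N relative-abundance profile
#'
#' Mean and SD of the per-E/N-step fragment abundance in percent of the
#' parent ion.
#'
#' @slot profile data frame: \code{e_over_n_td}, \code{mean_pct},
#'   \code{sd_pct}, \code{n_cycles}, ordered by increasing E/N.
#' @export
setClass("ENProfile", representation(profile = "data.frame"),
  validity = function(object) {
    p <- object@profile
    need <- c("e_over_n_td", "mean_pct", "sd_pct", "n_cycles")
    if (!all(need %in% names(p))) return("profile columns incomplete")
    if (any(p$n_cycles < 1L)) return("each step needs >= 1 cycle")
    if (nrow(p) > 1L && any(diff(p$e_over_n_td) <= 0))
      return("E/N values must be strictly increasing")
    TRUE
  })

#' @describeIn enProfile the profile data frame.
#' @param object an \code{ENProfile}.
#' @export
profileTable <- function(object) {
  stopifnot(is(object, "ENProfile"))
  object@profile
}

#' @export
setMethod("show", "ENProfile", function(object) {
  cat("ENProfile:\n")
  print(object@profile, row.names = FALSE)
})

#' Fragment abundance profile across stepped E/N values
#'
#' Groups cycles by the per-cycle E/N metadata of the TraceSet, computes
#' the fragment as percent of the parent at each cycle, then averages the
#' percentages within each step (cycle-wise averaging).
#'
#' @param x a \code{\linkS4class{TraceSet}} with \code{e_over_n_td}
#'   column metadata.
#' @param fragmentMz,parentMz monitored m/z of fragment and parent.
#' @return an \code{\linkS4class{ENProfile}}.
#' @export
enProfile <- function(x, fragmentMz, parentMz) {
  stopifnot(is(x, "TraceSet"))
  en <- eOverNPerCycle(x)
  if (is.null(en))
    stop("TraceSet has no per-cycle E/N metadata", call. = FALSE)
  frag <- getTrace(x, fragmentMz)
  par <- getTrace(x, parentMz)
  ok <- !is.na(en)
  if (!all(ok)) {
    warning(sum(!ok), " cycle(s) without E/N excluded")
    frag <- frag[ok]; par <- par[ok]; en <- en[ok]
  }
  steps <- sort(unique(en))
  rows <- lapply(steps, function(s) {
    i <- which(en == s)
    pp <- percentOfParent(frag, par, window = i)
    data.frame(e_over_n_td = s, mean_pct = pp$mean, sd_pct = pp$sd,
      n_cycles = length(pp$cycles))
  })
  new("ENProfile", profile = do.call(rbind, rows))
}
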